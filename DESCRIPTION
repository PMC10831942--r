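Package: trackdiff
Title: Single-Molecule Tracking, Diffusivity Mixtures, and Membrane-Lesion Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for single-molecule localization microscopy of
    membrane proteins around laser-induced plasma-membrane wounds. Generates
    ground-truth-annotated synthetic localization data, detects and filters
    single-molecule spots, links them into trajectories, estimates per-trajectory
    diffusion coefficients from mean-square-displacement regression with a
    localization-error offset, decomposes log-diffusivity distributions into
    global log-Gaussian mixtures shared across datasets, profiles diffusivity
    versus distance from the lesion in concentric annuli, corrects fluorescence
    kinetics for biexponential photobleaching, and provides the survival and
    multiple-comparison statistics used in membrane-repair studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    tiff
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
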