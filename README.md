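# trackdiff

Single-molecule tracking, diffusivity mixture decomposition, and
membrane-lesion kinetics for R.

## The problem

When a cell's plasma membrane is wounded, membrane-protein assemblies such
as caveolae (Caveolin/Cavin-scaffolded invaginations) reorganize within
seconds to minutes. Single-molecule localization microscopy (SMLM/PALM)
can watch this happen: sparse photoactivated fluorophores are localized
frame by frame, linked into trajectories, and each trajectory yields a
diffusion coefficient. Because photobleaching keeps trajectories short
(~8 frames), single estimates are noisy; the information lives in the
*distribution* of diffusivities and how its populations shift after
wounding. `trackdiff` implements that full analysis chain for people doing
membrane-repair and membrane-protein-dynamics experiments, plus a
ground-truth synthetic-data generator so every stage is testable without a
microscope.

## The model in brief

For 2-D Brownian motion observed with localization error
σ<sub>loc</sub>, the mean-square displacement at lag *t* = *n*Δ*t* is

MSD(*t*) = 4*D t* + 4σ<sub>loc</sub>²

so `estimate_D()` regresses MSD on *t* with an intercept and takes
*D* = |slope|/4 (the modulus keeps noise-dominated immobile molecules in
the analysis). Estimates are pooled on the log axis
D̃ = log₁₀(*D*/1 µm²s⁻¹) into area-normalized histograms (bin width 0.2)
and decomposed into *J* log-Gaussian populations,

PDF(D̃) = Σ<sub>j</sub> f<sub>j</sub>/(σ̃<sub>j</sub>√(2π)) ·
exp[−(D̃ − D̃<sub>j</sub>)²/(2σ̃<sub>j</sub>²)],

fitted *globally*: several datasets share centers and width, only the
fractional populations f<sub>j</sub> differ (`fit_mixture_global()`).
Around a lesion, trajectories are grouped into 2 µm annuli and the
geometric-mean diffusivity is fit against distance with
D(r) = D₀·exp(−r/r₀) + D<sub>∞</sub> (`fit_distance_profile()`).
Fluorescence kinetics are corrected as
I(t) = (I<sub>raw</sub>(t) − BG)/BL(t) with a biexponential bleaching
curve (`fit_bleach()`, `correct_intensity()`), and survival endpoints use
Fisher's exact test with Holm-adjusted Welch t-tests for grouped
comparisons.

## Worked example

Simulate three populations spanning the caveolar diffusivity range, run the
pipeline (filter → link → MSD → global mixture fit), and summarize:

```r
library(trackdiff)

cfg <- pipeline_config(
  sim = sim_config(list(population(0.0023, 0.45, "caveolae"),
                        population(0.014, 0.30, "mobilized"),
                        population(0.10, 0.25, "clusters")),
                   n_molecules = 8000, n_frames = 10000),
  J = 3, seed = 7)
res <- run_pipeline(cfg)
cat(res$log, sep = "\n")
#> simulate: 62979 localizations from 8000 molecules
#> filter: kept 61734, rejected 1245 (spot_sd) + 0 (precision)
#> link: 4771 trajectories (radius 500 nm, min length 5)
#> diffusion: 2550 eligible trajectories (>= 9 frames)
#> mixture: J = 3, centers -3.56, -2.47, -1.26

print(res$model)
#> Log-Gaussian mixture: 3 component(s), 1 dataset(s)
#>   centers (D-tilde): -3.559, -2.47, -1.258
#>   sigmas: 0.5161, 0.5161, 0.5161
#>   dataset1 fractions: 0.07987, 0.5968, 0.3233
#>   R^2: 0.985
```

The three fitted components are *apparent* diffusivity classes: the fast
population center (D̃ ≈ −1.26, i.e. ~0.06 µm²/s) sits close to its true
value, while the slowest population (true D = 0.0023 µm²/s) appears near
the measurement floor set by localization noise on 9–15-frame tracks —
exactly the behavior real SMLM data shows, and the reason the analysis
compares distributions rather than trusting single estimates.

Fraction tables from two conditions summarize into population shifts:

```r
shift <- population_shift(c(0.87, 0.00, 0.13),   # before wounding
                          c(0.57, 0.25, 0.18))   # after wounding
cat(sprintf("population-1 loss: %.0f%%; gain to population 2: %.0f%%\n",
            shift$loss_pop1_pct, shift$gain_pct["pop2"]))
#> population-1 loss: 34%; gain to population 2: 29%

fisher_exact_2x2(matrix(c(9, 0, 8, 9), 2, byrow = TRUE))
#> [1] 0.009396553
```

So 29% of the originally immobile pool was rendered mobile into
population 2, and a 9/0-versus-8/9 survival table is significant at
p = 0.009.

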