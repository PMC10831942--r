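#' Define a diffusing population
#'
#' @param D_true Diffusion coefficient, um^2/s (>= 0).
#' @param fraction Fraction of molecules drawn from this population.
#' @param label Population label.
#' @return A `population_spec` list.
#' @export
population <- function(D_true, fraction, label = NULL) {
  stopifnot(is.numeric(D_true), length(D_true) == 1, is.finite(D_true), D_true >= 0,
            is.numeric(fraction), length(fraction) == 1, is.finite(fraction), fraction >= 0)
  if (is.null(label)) label <- sprintf("D=%g", D_true)
  structure(list(D_true = D_true, fraction = fraction, label = label),
            class = "population_spec")
}

#' Simulation configuration
#'
#' Defaults reflect the imaging conditions the pipeline targets: 30 ms camera
#' dwell time, ~30 nm localization precision, photobleaching-limited tracks
#' of ~8 frames on average, and 109 nm pixels. Molecule starts are spread
#' uniformly over `n_frames` camera frames; with the default molecule count
#' and field of view the per-frame emitter density stays around 0.02
#' spots/um^2, low enough for unambiguous frame-to-frame linking.
#'
#' @param populations List of [population()] specs; fractions must sum to 1.
#'   Ignored when `gradient` is given.
#' @param sigma_loc Localization noise SD, nm.
#' @param dt Frame interval, s.
#' @param mean_track_len Expected trajectory length in frames before
#'   photobleaching (geometric survival; memoryless bleaching).
#' @param n_molecules Number of molecules to simulate.
#' @param n_frames Number of camera frames over which molecules appear.
#' @param fov Field of view `c(width, height)` in um.
#' @param seed Integer RNG seed; `NULL` uses the current stream.
#' @param lesion_center Optional lesion position `c(x, y)` in um.
#' @param gradient Optional `c(D0, r0, Dinf)` describing a lesion-centered
#'   diffusivity gradient D(r) = D0 * exp(-r / r0) + Dinf (um^2/s, um, um^2/s).
#'   Requires `lesion_center`. Each molecule's D is fixed at birth from its
#'   initial radial distance.
#' @param pixel_size Camera pixel size, nm.
#' @return A `sim_config` list.
#' @export
sim_config <- function(populations = list(population(0.1, 1)),
                       sigma_loc = 30, dt = 0.03, mean_track_len = 8,
                       n_molecules = 2000, n_frames = 2000,
                       fov = c(20, 20), seed = NULL,
                       lesion_center = NULL, gradient = NULL,
                       pixel_size = 109) {
  if (length(populations) == 0 && is.null(gradient))
    stop("empty population list", call. = FALSE)
  stopifnot(dt > 0, sigma_loc >= 0, mean_track_len >= 1, pixel_size > 0,
            n_molecules >= 1, n_frames >= 1, length(fov) == 2, all(fov > 0))
  stop_not_finite(c(sigma_loc, dt, mean_track_len, n_molecules, fov, pixel_size),
                  "sim_config parameters")
  if (is.null(gradient)) {
    fr <- vapply(populations, function(p) p$fraction, numeric(1))
    if (abs(sum(fr) - 1) > 1e-9)
      stop("population fractions must sum to 1 (got ", sum(fr), ")", call. = FALSE)
  } else {
    stopifnot(length(gradient) == 3, all(is.finite(gradient)),
              gradient[2] > 0, gradient[3] >= 0)
    if (is.null(lesion_center)) stop("gradient requires lesion_center", call. = FALSE)
  }
  structure(list(populations = populations, sigma_loc = sigma_loc, dt = dt,
                 mean_track_len = mean_track_len, n_molecules = n_molecules,
                 n_frames = n_frames, fov = fov, seed = seed,
                 lesion_center = lesion_center, gradient = gradient,
                 pixel_size = pixel_size),
            class = "sim_config")
}

#' Simulate single-molecule trajectories and their localization table
#'
#' Each molecule performs 2-D Brownian motion with per-axis per-frame
#' displacement variance 2 * D * dt. The observed position adds isotropic
#' Gaussian localization noise of SD `sigma_loc`. Trajectory lengths are
#' geometric with the configured mean (constant per-frame bleaching
#' probability); molecules that step outside the field of view are truncated
#' there, mimicking departure from the evanescent excitation field. In
#' gradient mode a molecule's D is evaluated once, at its birth distance from
#' the lesion center.
#'
#' The localization table carries synthetic per-spot quality columns
#' (precision drawn as |N(30, 8)| nm, spot width as N(140, 15) nm) so that the
#' quality filters have realistic work to do.
#'
#' @param config A [sim_config()].
#' @return List with `localizations` (data.frame: x_nm, y_nm, frame,
#'   sigma_loc_nm, spot_sd_nm, intensity, molecule_id, population) and
#'   `truth` (data.frame: molecule_id, population, D_true, frame, x_um, y_um).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_molecules
    # geometric (support 1,2,...) with mean m: success prob 1/m
    len <- 1L + stats::rgeom(n, prob = 1 / config$mean_track_len)
    start_frame <- sample.int(config$n_frames, n, replace = TRUE) - 1L

    if (!is.null(config$gradient)) {
      x0 <- stats::runif(n, 0, config$fov[1])
      y0 <- stats::runif(n, 0, config$fov[2])
      r <- sqrt((x0 - config$lesion_center[1])^2 + (y0 - config$lesion_center[2])^2)
      g <- config$gradient
      D_mol <- g[1] * exp(-r / g[2]) + g[3]
      pop_lab <- rep("gradient", n)
    } else {
      x0 <- stats::runif(n, 0, config$fov[1])
      y0 <- stats::runif(n, 0, config$fov[2])
      fr <- vapply(config$populations, function(p) p$fraction, numeric(1))
      pop_idx <- sample.int(length(fr), n, replace = TRUE, prob = fr)
      D_mol <- vapply(config$populations, function(p) p$D_true, numeric(1))[pop_idx]
      pop_lab <- vapply(config$populations, function(p) p$label, character(1))[pop_idx]
    }

    rows <- rep.int(seq_len(n), len)
    total <- length(rows)
    first <- c(TRUE, rows[-1] != rows[-total])
    step_sd <- sqrt(2 * D_mol * config$dt)[rows]
    dx <- stats::rnorm(total, 0, step_sd); dx[first] <- 0
    dy <- stats::rnorm(total, 0, step_sd); dy[first] <- 0
    csx <- cumsum(dx); csy <- cumsum(dy)
    off_x <- csx[first][rows]; off_y <- csy[first][rows]
    x <- x0[rows] + csx - off_x
    y <- y0[rows] + csy - off_y
    step_idx <- seq_len(total) - rep.int(cumsum(c(0L, len[-n]))[seq_len(n)], len) - 1L
    frame <- start_frame[rows] + step_idx

    inside <- x >= 0 & x <= config$fov[1] & y >= 0 & y <= config$fov[2]
    keep <- as.logical(stats::ave(inside, rows, FUN = cumprod))

    x <- x[keep]; y <- y[keep]; frame <- frame[keep]; mol <- rows[keep]
    n_obs <- length(x)
    obs_x <- x + stats::rnorm(n_obs, 0, config$sigma_loc / 1000)
    obs_y <- y + stats::rnorm(n_obs, 0, config$sigma_loc / 1000)

    locs <- data.frame(
      x_nm = obs_x * 1000,
      y_nm = obs_y * 1000,
      frame = as.integer(frame),
      sigma_loc_nm = abs(stats::rnorm(n_obs, 30, 8)),
      spot_sd_nm = stats::rnorm(n_obs, 140, 15),
      intensity = stats::rlnorm(n_obs, log(1000), 0.3),
      molecule_id = mol,
      population = pop_lab[mol],
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      molecule_id = mol,
      population = pop_lab[mol],
      D_true = D_mol[mol],
      frame = as.integer(frame),
      x_um = x,
      y_um = y,
      stringsAsFactors = FALSE
    )
    o <- order(locs$frame, locs$molecule_id)
    list(localizations = locs[o, , drop = FALSE], truth = truth[o, , drop = FALSE])
  })
}

#' Render localizations into a synthetic camera frame stack
#'
#' Each emitter becomes a 2-D Gaussian point-spread function (SD ~1.3 px) on
#' the pixel grid; Poisson shot noise is applied to signal plus a constant
#' camera offset.
#'
#' @param locs Localization data.frame with x_nm, y_nm, frame, intensity
#'   (expected photons per emitter).
#' @param config A [sim_config()] (provides fov and pixel size).
#' @param psf_sd_px PSF standard deviation in pixels.
#' @param offset Constant camera offset, counts.
#' @param n_frames Number of frames to render; defaults to max frame + 1.
#' @param seed Optional RNG seed for the shot noise.
#' @return Integer array `[ny, nx, n_frames]` of 16-bit-range counts.
#' @export
render_frames <- function(locs, config, psf_sd_px = 1.3, offset = 100,
                          n_frames = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  px_um <- config$pixel_size / 1000
  nx <- as.integer(ceiling(config$fov[1] / px_um))
  ny <- as.integer(ceiling(config$fov[2] / px_um))
  if (nx < 1 || ny < 1) stop("fov/pixel grid mismatch", call. = FALSE)
  if (nrow(locs) > 0) {
    xpx <- locs$x_nm / config$pixel_size
    ypx <- locs$y_nm / config$pixel_size
    if (any(xpx < 0 | xpx > nx | ypx < 0 | ypx > ny))
      stop("fov/pixel grid mismatch: localizations outside the pixel grid",
           call. = FALSE)
  }
  if (is.null(n_frames))
    n_frames <- if (nrow(locs) > 0) max(locs$frame) + 1L else 1L
  with_seed(seed, {
    stack <- array(0, dim = c(ny, nx, n_frames))
    w <- ceiling(4 * psf_sd_px)
    if (nrow(locs) > 0) {
      for (k in seq_len(nrow(locs))) {
        f <- locs$frame[k] + 1L
        if (f < 1L || f > n_frames) next
        x0 <- locs$x_nm[k] / config$pixel_size
        y0 <- locs$y_nm[k] / config$pixel_size
        jc <- ceiling(x0); ic <- ceiling(y0)
        js <- max(1L, jc - w):min(nx, jc + w)
        is <- max(1L, ic - w):min(ny, ic + w)
        gx <- exp(-((js - 0.5) - x0)^2 / (2 * psf_sd_px^2))
        gy <- exp(-((is - 0.5) - y0)^2 / (2 * psf_sd_px^2))
        psf <- outer(gy, gx) * locs$intensity[k] / (2 * pi * psf_sd_px^2)
        stack[is, js, f] <- stack[is, js, f] + psf
      }
    }
    counts <- array(stats::rpois(length(stack), lambda = stack + offset),
                    dim = dim(stack))
    counts[counts > 65535L] <- 65535L
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Simulate a raw fluorescence intensity trace with photobleaching
#'
#' The raw trace is `response_profile(t) * BL(t) + BG + noise`, with the
#' normalized biexponential bleaching curve
#' `BL(t) = A exp(-t/tau1) + (1 - A) exp(-t/tau2)` (so BL(0) = 1).
#'
#' @param A Fractional amplitude of the fast bleaching component, in `[0, 1]`.
#' @param tau1,tau2 Bleaching lifetimes, s (> 0).
#' @param response_profile Function of time (s) giving the underlying signal,
#'   or a numeric vector of length `n_frames`.
#' @param BG Constant background level.
#' @param noise_sd Gaussian noise SD added to the raw trace.
#' @param n_frames Number of time points.
#' @param dt Frame interval, s.
#' @param seed Optional RNG seed for the noise.
#' @return data.frame with t_s, I_raw; attributes `BL` (true bleaching curve)
#'   and `response` (noise-free signal).
#' @export
simulate_intensity_trace <- function(A, tau1, tau2, response_profile,
                                     BG = 0, noise_sd = 0,
                                     n_frames = 100, dt = 1, seed = NULL) {
  if (tau1 <= 0 || tau2 <= 0) stop("negative or zero tau", call. = FALSE)
  stopifnot(A >= 0, A <= 1, n_frames >= 1, dt > 0)
  t <- (seq_len(n_frames) - 1) * dt
  BL <- A * exp(-t / tau1) + (1 - A) * exp(-t / tau2)
  resp <- if (is.function(response_profile)) response_profile(t) else {
    stopifnot(length(response_profile) %in% c(1L, n_frames))
    rep_len(response_profile, n_frames)
  }
  with_seed(seed, {
    I_raw <- resp * BL + BG + stats::rnorm(n_frames, 0, noise_sd)
    out <- data.frame(t_s = t, I_raw = I_raw)
    attr(out, "BL") <- BL
    attr(out, "response") <- resp
    out
  })
}
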