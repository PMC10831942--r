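#' Assign trajectories to lesion-centered annuli
#'
#' Each trajectory is assigned by the radial distance of its mean position
#' (or first localization, see `by`) to 2 um-wide concentric annuli with
#' outer radii 2, 4, 6, 8, 10 um by default. Interval convention: an annulus
#' is (inner, outer], with the innermost including r = 0; trajectories beyond
#' the outermost radius are excluded (annulus is NA).
#'
#' @param estimates Diffusion-estimates data.frame from
#'   [estimate_diffusion()] (needs x_um/y_um, or a precomputed r_um column).
#' @param lesion_center `c(x, y)` lesion position, um (not needed when a
#'   r_um column is present).
#' @param outer_radii Outer annulus radii, um.
#' @param by Position used for assignment: trajectory `"mean"` position
#'   (default) or `"first"` localization (requires x0_um/y0_um columns).
#' @return The estimates with columns r_um, annulus (integer index),
#'   r_inner_um, r_outer_um.
#' @export
assign_annuli <- function(estimates, lesion_center = NULL,
                          outer_radii = c(2, 4, 6, 8, 10),
                          by = c("mean", "first")) {
  by <- match.arg(by)
  stopifnot(length(outer_radii) >= 1, all(diff(outer_radii) > 0))
  if (!"r_um" %in% names(estimates) || by == "first") {
    if (is.null(lesion_center)) stop("missing lesion center", call. = FALSE)
    xs <- if (by == "first") estimates$x0_um else estimates$x_um
    ys <- if (by == "first") estimates$y0_um else estimates$y_um
    if (is.null(xs) || is.null(ys))
      stop("estimates carry no positions for annulus assignment", call. = FALSE)
    estimates$r_um <- sqrt((xs - lesion_center[1])^2 +
                           (ys - lesion_center[2])^2)
  }
  breaks <- c(0, outer_radii)
  idx <- findInterval(estimates$r_um, breaks, left.open = TRUE)
  idx[estimates$r_um == 0] <- 1L
  idx[idx > length(outer_radii)] <- NA_integer_
  estimates$annulus <- idx
  estimates$r_inner_um <- breaks[idx]
  estimates$r_outer_um <- breaks[idx + 1L]
  estimates
}

#' Log-scale (geometric) average of diffusion coefficients
#'
#' @param D Diffusion coefficients, um^2/s (> 0).
#' @return 10^(mean of log10 D) — the geometric mean.
#' @export
log_average_D <- function(D) {
  if (length(D) == 0) stop("empty group", call. = FALSE)
  stopifnot(all(D > 0))
  10^mean(log10(D))
}

#' Diffusivity-versus-distance annulus profile
#'
#' @param assigned Output of [assign_annuli()].
#' @return data.frame: annulus, r_inner_um, r_outer_um, r_mid_um (outer - 1,
#'   the annulus midpoint used as fitting abscissa), D_geo_um2_s
#'   (log-averaged D), n (trajectories).
#' @export
annulus_profile <- function(assigned) {
  stopifnot(all(c("annulus", "D_um2_s") %in% names(assigned)))
  keep <- !is.na(assigned$annulus)
  parts <- split(assigned[keep, , drop = FALSE], assigned$annulus[keep])
  rows <- lapply(parts, function(g) data.frame(
    annulus = g$annulus[1],
    r_inner_um = g$r_inner_um[1],
    r_outer_um = g$r_outer_um[1],
    r_mid_um = (g$r_inner_um[1] + g$r_outer_um[1]) / 2,
    D_geo_um2_s = log_average_D(g$D_um2_s),
    n = nrow(g)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$annulus), , drop = FALSE]
}

#' Fit a diffusivity-distance profile
#'
#' Fits either the exponential recovery model
#' D(r) = D0 * exp(-r / r0) + Dinf (nonlinear least squares) or a straight
#' line D(r) = m * r + D0 (ordinary least squares) to the per-annulus
#' log-averaged diffusivities against the annulus midpoints. R^2 is
#' 1 - SS_res / SS_tot; a constant profile (SS_tot = 0) reports R^2 = 0 by
#' convention.
#'
#' @param profile [annulus_profile()] output (or any data.frame with
#'   r_mid_um and D_geo_um2_s).
#' @param model `"exponential"` or `"linear"`.
#' @return A `distance_fit`: list(model, parameters, R2, fitted, r).
#' @export
fit_distance_profile <- function(profile, model = c("exponential", "linear")) {
  model <- match.arg(model)
  r <- profile$r_mid_um; D <- profile$D_geo_um2_s
  stopifnot(length(r) == length(D))
  if (length(unique(r)) < 2) stop("degenerate abscissa", call. = FALSE)
  if (model == "exponential") {
    if (length(r) < 3) stop("need >= 3 annuli for the exponential fit",
                            call. = FALSE)
    Dinf0 <- min(D); D00 <- max(D) - min(D); r00 <- diff(range(r)) / 2
    fit <- minpack.lm::nlsLM(
      D ~ D0 * exp(-r / r0) + Dinf,
      data = data.frame(r = r, D = D),
      start = list(D0 = max(D00, 1e-6), r0 = max(r00, 1e-3), Dinf = Dinf0),
      lower = c(D0 = 0, r0 = 1e-6, Dinf = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    pars <- stats::coef(fit)
    fitted <- pars[["D0"]] * exp(-r / pars[["r0"]]) + pars[["Dinf"]]
    parameters <- c(D0 = pars[["D0"]], r0 = pars[["r0"]],
                    Dinf = pars[["Dinf"]])
  } else {
    if (length(r) < 2) stop("need >= 2 annuli for the line fit", call. = FALSE)
    fit <- stats::lm(D ~ r)
    co <- stats::coef(fit)
    fitted <- as.numeric(co[1] + co[2] * r)
    parameters <- c(m = as.numeric(co[2]), D0 = as.numeric(co[1]))
  }
  sst <- sum((D - mean(D))^2)
  R2 <- if (sst == 0) 0 else 1 - sum((D - fitted)^2) / sst
  structure(list(model = model, parameters = parameters, R2 = R2,
                 fitted = fitted, r = r),
            class = "distance_fit")
}

#' @export
print.distance_fit <- function(x, ...) {
  cat(sprintf("%s distance fit (R^2 = %.4f)\n", x$model, x$R2))
  print(signif(x$parameters, 4))
  invisible(x)
}
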