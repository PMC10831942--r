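#' Fit a normalized biexponential photobleaching curve
#'
#' The reference trace (a region far from the lesion, bleaching but otherwise
#' static) is divided by its t = 0 value and fit with
#' BL(t) = A exp(-t/tau1) + (1 - A) exp(-t/tau2), so BL(0) = 1 by
#' construction. Initialization is deterministic (A = 0.5, tau1 = duration /
#' 10, tau2 = duration); lifetimes are bounded to [dt, 100 * duration] and A
#' to [0, 1]. A constant trace drives both lifetimes to the upper bound and
#' the correction becomes the identity within tolerance.
#'
#' @param trace data.frame with t_s and I_raw (the reference ROI trace), or a
#'   numeric vector with `times` supplied separately.
#' @param times Time points, s (if `trace` is a numeric vector).
#' @return A `bleach_model`: list(A, tau1, tau2).
#' @export
fit_bleach <- function(trace, times = NULL) {
  if (is.data.frame(trace)) {
    t <- trace$t_s; I <- trace$I_raw
  } else {
    t <- times; I <- trace
  }
  stopifnot(length(t) == length(I), length(t) >= 6)
  if (!is.finite(I[1]) || I[1] <= 0)
    stop("non-positive initial value in reference trace", call. = FALSE)
  y <- I / I[1]
  dur <- max(t) - min(t)
  dt <- min(diff(sort(unique(t))))
  tt <- t - t[1]
  # raw Levenberg-Marquardt: degenerate traces (e.g. constant, where both
  # lifetimes run to the upper bound) still return a usable parameter set
  resid_fn <- function(p)
    y - (p[1] * exp(-tt / p[2]) + (1 - p[1]) * exp(-tt / p[3]))
  fit <- minpack.lm::nls.lm(
    par = c(A = 0.5, tau1 = dur / 10, tau2 = dur),
    lower = c(0, dt, dt), upper = c(1, 100 * dur, 100 * dur),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- fit$par
  structure(list(A = co[["A"]], tau1 = co[["tau1"]], tau2 = co[["tau2"]],
                 t0 = t[1]),
            class = "bleach_model")
}

#' Evaluate a bleaching model
#'
#' @param model A `bleach_model`.
#' @param t Time points, s.
#' @return BL(t) values (BL at the model's reference time is 1).
#' @export
bleach_curve <- function(model, t) {
  stopifnot(inherits(model, "bleach_model"))
  tt <- t - model$t0
  model$A * exp(-tt / model$tau1) + (1 - model$A) * exp(-tt / model$tau2)
}

#' Background- and bleach-correct an intensity trace
#'
#' Applies I(t) = (I_raw(t) - BG) / BL(t). Values below background are
#' passed through as negative intensities (noise can dip below the
#' background estimate).
#'
#' @param trace data.frame with t_s and I_raw.
#' @param BG Background: scalar, or per-frame vector matching the trace.
#' @param model A `bleach_model` from [fit_bleach()].
#' @return An `intensity_trace` data.frame: t_s, I_raw, BG, BL, I.
#' @export
correct_intensity <- function(trace, BG, model) {
  stopifnot(is.data.frame(trace), all(c("t_s", "I_raw") %in% names(trace)))
  stopifnot(length(BG) %in% c(1L, nrow(trace)))
  BL <- bleach_curve(model, trace$t_s)
  if (any(BL <= 0)) stop("bleaching curve non-positive over the trace",
                         call. = FALSE)
  out <- data.frame(t_s = trace$t_s, I_raw = trace$I_raw,
                    BG = rep_len(BG, nrow(trace)), BL = BL)
  out$I <- (out$I_raw - out$BG) / out$BL
  class(out) <- c("intensity_trace", "data.frame")
  out
}

#' Normalize a corrected intensity trace to 100
#'
#' Scales the corrected intensity so that the reference — the t = 0 value
#' (`mode = "t0"`) or an externally supplied reference intensity
#' (`mode = "reference"`, e.g. the pre-wound sarcolemma signal) — equals 100.
#'
#' @param trace An `intensity_trace` (or data.frame with t_s and I).
#' @param mode `"t0"` or `"reference"`.
#' @param ref_value Reference intensity for `mode = "reference"`.
#' @return The trace with I rescaled.
#' @export
normalize_trace <- function(trace, mode = c("t0", "reference"),
                            ref_value = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(trace), "I" %in% names(trace))
  ref <- if (mode == "t0") trace$I[which.min(trace$t_s)] else ref_value
  if (is.null(ref) || !is.finite(ref) || ref == 0)
    stop("zero or missing reference value", call. = FALSE)
  trace$I <- trace$I * 100 / ref
  trace
}

#' Z-line to sarcolemma fluorescence ratio
#'
#' The per-cell protocol samples the mean intensity of the Z-line and of the
#' sarcolemma at 10 positions each; the cell's ratio is the mean of the
#' Z-line means divided by the mean of the sarcolemma means.
#'
#' @param zline_means Per-position Z-line mean intensities.
#' @param sarcolemma_means Per-position sarcolemma mean intensities.
#' @return The ratio (scalar).
#' @export
zline_sarcolemma_ratio <- function(zline_means, sarcolemma_means) {
  stopifnot(length(zline_means) >= 1, length(sarcolemma_means) >= 1,
            all(is.finite(zline_means)), all(is.finite(sarcolemma_means)))
  denom <- mean(sarcolemma_means)
  if (denom == 0) stop("zero sarcolemma mean", call. = FALSE)
  mean(zline_means) / denom
}
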