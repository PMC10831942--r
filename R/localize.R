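#' Detect and fit single-molecule spots in a frame stack
#'
#' Local maxima exceeding `detection_threshold` counts above the frame
#' background (median) are fit with a 2-D Gaussian on a square window by
#' least squares, yielding subpixel centers, the fitted PSF SD, and a
#' localization-precision estimate proportional to spot_sd / sqrt(photons).
#' The precision proxy stands in for the uncertainty a full maximum-likelihood
#' localizer would report; downstream analysis only consumes positions and
#' precision, so the proxy is sufficient for synthetic ground-truth work.
#'
#' Coordinates: origin at the top-left pixel corner, x rightward, y downward,
#' positions in nm, frames 0-based.
#'
#' @param stack Array `[ny, nx, n_frames]` (or a single 2-D frame) of counts.
#' @param detection_threshold Counts above background required for a maximum.
#' @param pixel_size Pixel size, nm.
#' @param window Half-width of the fit window in pixels (window is
#'   `2*window+1` squared).
#' @return Localization data.frame: x_nm, y_nm, frame, sigma_loc_nm,
#'   spot_sd_nm, intensity (fitted photons).
#' @export
localize_spots <- function(stack, detection_threshold, pixel_size = 109,
                           window = 3L) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (length(stack) == 0 || length(dim(stack)) != 3)
    stop("empty or non 2-D+time stack", call. = FALSE)
  stopifnot(is.finite(detection_threshold))
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nf <- dim(stack)[3]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- stack[, , f]
    bg <- stats::median(fr)
    cand <- which(fr - bg > detection_threshold, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (i <= window || i > ny - window || j <= window || j > nx - window) next
      nb <- fr[(i - 1):(i + 1), (j - 1):(j + 1)]
      keep[k] <- fr[i, j] == max(nb) && sum(nb == max(nb)) == 1
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    fits <- lapply(seq_len(nrow(cand)), function(k) {
      i <- cand[k, 1]; j <- cand[k, 2]
      is <- (i - window):(i + window); js <- (j - window):(j + window)
      .fit_gaussian_2d(fr[is, js], x_off = js[1] - 1, y_off = is[1] - 1)
    })
    fits <- do.call(rbind, fits)
    fits$frame <- f - 1L
    out[[f]] <- fits
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      frame = integer(0), sigma_loc_nm = numeric(0),
                      spot_sd_nm = numeric(0), intensity = numeric(0))
    return(out)
  }
  data.frame(
    x_nm = out$x_px * pixel_size,
    y_nm = out$y_px * pixel_size,
    frame = out$frame,
    sigma_loc_nm = out$sd_px * pixel_size / sqrt(pmax(out$photons, 1)),
    spot_sd_nm = out$sd_px * pixel_size,
    intensity = out$photons
  )
}

# Least-squares 2-D Gaussian fit on a small window.
# Pixel (row i, col j) of the window (1-based, plus offsets) has its center
# at x = x_off + j - 0.5, y = y_off + i - 0.5 (pixel units).
.fit_gaussian_2d <- function(win, x_off, y_off) {
  ny <- nrow(win); nx <- ncol(win)
  xs <- x_off + seq_len(nx) - 0.5
  ys <- y_off + seq_len(ny) - 0.5
  X <- matrix(rep(xs, each = ny), ny, nx)
  Y <- matrix(rep(ys, times = nx), ny, nx)
  b0 <- min(win)
  w <- pmax(win - b0, 0)
  tot <- sum(w)
  x0 <- if (tot > 0) sum(X * w) / tot else mean(xs)
  y0 <- if (tot > 0) sum(Y * w) / tot else mean(ys)
  a0 <- max(win) - b0
  obj <- function(p) {
    a <- p[1]; mx <- p[2]; my <- p[3]; s <- exp(p[4]); b <- p[5]
    mu <- a * exp(-((X - mx)^2 + (Y - my)^2) / (2 * s^2)) + b
    sum((win - mu)^2)
  }
  fit <- stats::optim(c(a0, x0, y0, log(1.3), b0), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  a <- fit$par[1]; s <- exp(fit$par[4])
  data.frame(x_px = fit$par[2], y_px = fit$par[3], sd_px = s,
             photons = max(2 * pi * a * s^2, 0))
}

#' Apply single-molecule quality filters to a localization table
#'
#' Keeps localizations whose fitted spot SD is at least one camera pixel
#' (109 nm) and whose localization precision is at most 70 nm; spots failing
#' either rule are rejected (inequalities strict, matching the published
#' rejection rules: SD < 109 nm rejected, precision > 70 nm rejected). Order
#' is preserved and per-rule rejection counts are attached as the
#' `"rejections"` attribute.
#'
#' @param locs Localization data.frame with columns spot_sd_nm and
#'   sigma_loc_nm.
#' @param max_precision_nm Precision ceiling, nm.
#' @param min_spot_sd_nm Spot-SD floor, nm.
#' @return Filtered data.frame with attribute `rejections`
#'   (named counts: spot_sd, precision).
#' @export
filter_localizations <- function(locs, max_precision_nm = 70,
                                 min_spot_sd_nm = 109) {
  req <- c("spot_sd_nm", "sigma_loc_nm")
  miss <- setdiff(req, names(locs))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_sd <- locs$spot_sd_nm < min_spot_sd_nm
  bad_prec <- locs$sigma_loc_nm > max_precision_nm
  keep <- !bad_sd & !bad_prec
  out <- locs[keep, , drop = FALSE]
  attr(out, "rejections") <- c(spot_sd = sum(bad_sd),
                               precision = sum(bad_prec & !bad_sd))
  out
}
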