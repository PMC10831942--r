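#' Compute the mean-square-displacement curve of one trajectory
#'
#' For each time lag t = n * dt the MSD is the average, over all position
#' pairs (i, i + n) in the trajectory, of the squared 2-D displacement.
#' Only lags averaged over at least `min_pairs` pairs are retained, so a
#' trajectory of length L contributes lags n = 1 ... L - min_pairs.
#'
#' @param traj data.frame with x_nm, y_nm (one trajectory, time-ordered).
#' @param dt Frame interval, s.
#' @param min_pairs Minimum number of displacement pairs per retained lag.
#' @return An `msd_curve`: list with `lags` (data.frame n, t, msd, pairs;
#'   msd in um^2), `dt`, and `n_loc` (trajectory length).
#' @export
compute_msd <- function(traj, dt, min_pairs = 4) {
  L <- nrow(traj)
  if (is.null(L) || L < 2) stop("trajectory has fewer than 2 localizations",
                                call. = FALSE)
  stopifnot(dt > 0)
  x <- traj$x_nm / 1000; y <- traj$y_nm / 1000
  n_max <- L - min_pairs
  if (n_max < 1) {
    lags <- data.frame(n = integer(0), t = numeric(0),
                       msd = numeric(0), pairs = integer(0))
  } else {
    ns <- seq_len(n_max)
    msd <- vapply(ns, function(n) {
      dx <- x[(n + 1):L] - x[1:(L - n)]
      dy <- y[(n + 1):L] - y[1:(L - n)]
      mean(dx^2 + dy^2)
    }, numeric(1))
    lags <- data.frame(n = ns, t = ns * dt, msd = msd, pairs = L - ns)
  }
  structure(list(lags = lags, dt = dt, n_loc = L), class = "msd_curve")
}

#' Estimate a diffusion coefficient from an MSD curve
#'
#' Fits the ordinary least-squares line msd = 4 D t + c over the retained
#' lags. Localization error inflates the MSD by a constant 4 sigma_loc^2, so
#' the intercept c is reported as-is (it may be negative for noisy curves).
#' Because short trajectories of slow molecules frequently yield negative
#' slopes, the modulus of the slope is taken: D = |slope| / 4, which keeps
#' immobile molecules in the analysis. Trajectories shorter than
#' `min_traj_len` frames, or with fewer than `min_points` retained lags, are
#' ineligible and return `NULL`; an exactly zero slope (D-tilde undefined)
#' also returns `NULL`.
#'
#' @param msd_curve An [compute_msd()] result.
#' @param min_traj_len Minimum trajectory length, frames.
#' @param min_points Minimum number of lag points for the regression.
#' @param max_lag Optional cap on the largest lag index used.
#' @return A one-row data.frame (D_um2_s, D_log, intercept_um2, traj_len,
#'   n_lags) or `NULL` if the trajectory is ineligible.
#' @export
estimate_D <- function(msd_curve, min_traj_len = 9, min_points = 4,
                       max_lag = NULL) {
  stopifnot(inherits(msd_curve, "msd_curve"))
  lags <- msd_curve$lags
  if (!is.null(max_lag)) lags <- lags[lags$n <= max_lag, , drop = FALSE]
  if (msd_curve$n_loc < min_traj_len || nrow(lags) < min_points) return(NULL)
  fit <- stats::.lm.fit(cbind(1, lags$t), lags$msd)
  slope <- fit$coefficients[2]
  if (slope == 0) return(NULL)
  D <- abs(slope) / 4
  data.frame(D_um2_s = D, D_log = log10(D),
             intercept_um2 = fit$coefficients[1],
             traj_len = msd_curve$n_loc, n_lags = nrow(lags))
}

#' Per-trajectory diffusion estimates for a trajectory table
#'
#' Applies [compute_msd()] and [estimate_D()] to every trajectory and,
#' when a lesion center is supplied, records each trajectory's radial
#' distance (of its mean position) from it.
#'
#' @param trajs Trajectory data.frame (traj_id, frame, x_nm, y_nm; a
#'   molecule_id column, if present, is carried through).
#' @param dt Frame interval, s.
#' @param lesion_center Optional `c(x, y)` lesion position, um.
#' @param min_traj_len,min_points,max_lag Passed to [estimate_D()].
#' @param min_pairs Passed to [compute_msd()].
#' @return data.frame: traj_id, D_um2_s, D_log, intercept_um2, traj_len,
#'   n_lags, x_um, y_um (mean position), r_um (if lesion_center given).
#' @export
estimate_diffusion <- function(trajs, dt, lesion_center = NULL,
                               min_traj_len = 9, min_points = 4,
                               max_lag = NULL, min_pairs = 4) {
  stopifnot(all(c("traj_id", "x_nm", "y_nm") %in% names(trajs)))
  parts <- split(trajs, trajs$traj_id)
  rows <- lapply(parts, function(tr) {
    if (nrow(tr) < 2) return(NULL)
    est <- estimate_D(compute_msd(tr, dt, min_pairs = min_pairs),
                      min_traj_len = min_traj_len, min_points = min_points,
                      max_lag = max_lag)
    if (is.null(est)) return(NULL)
    est$traj_id <- tr$traj_id[1]
    est$x_um <- mean(tr$x_nm) / 1000
    est$y_um <- mean(tr$y_nm) / 1000
    if ("molecule_id" %in% names(tr)) est$molecule_id <- tr$molecule_id[1]
    est
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(traj_id = integer(0), D_um2_s = numeric(0),
                      D_log = numeric(0), intercept_um2 = numeric(0),
                      traj_len = integer(0), n_lags = integer(0),
                      x_um = numeric(0), y_um = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    front <- c("traj_id", "D_um2_s", "D_log", "intercept_um2",
               "traj_len", "n_lags", "x_um", "y_um")
    out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  }
  if (!is.null(lesion_center)) {
    stopifnot(length(lesion_center) == 2)
    out$r_um <- sqrt((out$x_um - lesion_center[1])^2 +
                     (out$y_um - lesion_center[2])^2)
  }
  out
}
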