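#' Area-normalized log-diffusivity histogram
#'
#' Compiles D-tilde = log10(D / 1 um^2/s) values into a histogram with fixed
#' bin width on the log axis (default 0.2 decades), normalized so that
#' sum(density * bin_width) = 1 — a probability density function over
#' D-tilde. Bin edges are anchored at integer multiples of the bin width
#' (..., -0.4, -0.2, 0, ...), so histograms of different datasets share the
#' same binning and are directly comparable.
#'
#' @param d_log Numeric vector of D-tilde values.
#' @param bin_width Bin width on the D-tilde axis.
#' @param label Optional dataset label.
#' @return A `histogram_pdf`: list with edges, mids, counts, density, n,
#'   bin_width, label.
#' @export
build_pdf <- function(d_log, bin_width = 0.2, label = NULL) {
  d_log <- d_log[is.finite(d_log)]
  if (length(d_log) == 0) stop("no finite D_log values", call. = FALSE)
  stopifnot(bin_width > 0)
  # eps guards against 0.2-grid floating-point edge effects; values sitting
  # exactly on an edge belong to the bin above: [edge, edge + w)
  eps <- 1e-9
  lo <- floor(min(d_log) / bin_width + eps)
  hi <- ceiling(max(d_log) / bin_width - eps)
  if (hi == lo) hi <- lo + 1
  edges <- (lo:hi) * bin_width
  idx <- pmin(floor(d_log / bin_width + eps) - lo + 1, length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  n <- length(d_log)
  structure(list(edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 density = counts / (n * bin_width),
                 n = n, bin_width = bin_width, label = label),
            class = "histogram_pdf")
}

#' Construct a log-Gaussian mixture model
#'
#' @param centers Component centers on the D-tilde axis (length J).
#' @param sigmas Component SDs on the D-tilde axis (length J or 1, recycled).
#' @param fractions Fractional populations: numeric vector (one dataset) or
#'   matrix with one row per dataset; rows must sum to 1.
#' @param datasets Optional dataset labels.
#' @return A `mixture_model`.
#' @export
mixture_model <- function(centers, sigmas, fractions, datasets = NULL) {
  J <- length(centers)
  sigmas <- rep_len(sigmas, J)
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1)
  stopifnot(ncol(fractions) == J, all(sigmas > 0), all(fractions >= -1e-12))
  if (any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("fractions must sum to 1 per dataset", call. = FALSE)
  if (is.null(datasets)) datasets <- paste0("dataset", seq_len(nrow(fractions)))
  structure(list(centers = centers, sigmas = sigmas,
                 fractions = fractions, datasets = datasets),
            class = "mixture_model")
}

#' Evaluate a log-Gaussian mixture density
#'
#' PDF(D-tilde) = sum_j f_j / (sigma_j sqrt(2 pi)) *
#' exp(-(D-tilde - center_j)^2 / (2 sigma_j^2)); each component is a
#' normalized Gaussian on the log axis weighted by its fractional area, so
#' the mixture integrates to 1.
#'
#' @param model A `mixture_model`.
#' @param d_log Points on the D-tilde axis.
#' @param dataset Dataset index or label selecting the fraction row.
#' @return Density values.
#' @export
eval_mixture <- function(model, d_log, dataset = 1) {
  stopifnot(inherits(model, "mixture_model"))
  if (is.character(dataset)) dataset <- match(dataset, model$datasets)
  f <- model$fractions[dataset, ]
  if (abs(sum(f) - 1) > 1e-9)
    stop("fractions do not sum to 1", call. = FALSE)
  out <- numeric(length(d_log))
  for (j in seq_along(model$centers))
    out <- out + f[j] * stats::dnorm(d_log, model$centers[j], model$sigmas[j])
  out
}

# softmax with first logit pinned at 0
.softmax <- function(z) { e <- exp(c(0, z) - max(c(0, z))); e / sum(e) }

#' Global fit of log-Gaussian mixtures to one or more histograms
#'
#' Least-squares fit of a J-component log-Gaussian mixture to the bin
#' densities of one or several histograms simultaneously. Component centers
#' and widths are shared across datasets (the parameter-parsimony device that
#' makes before/after comparisons meaningful: the same classes of moving
#' entities, different fractional weights); per-dataset fractions are
#' constrained to the simplex by a softmax reparameterization. With
#' `single_width = TRUE` (default) all components share one SD, reflecting
#' that the width mostly encodes the statistical uncertainty of
#' short-trajectory MSD estimates rather than population heterogeneity.
#'
#' Optimization uses `nlminb` from a deterministic quantile-spread start plus
#' `n_starts` seeded random restarts; the best objective wins, ties going to
#' the first found. Centers are box-constrained to the pooled data range
#' plus one bin.
#'
#' @param pdfs A `histogram_pdf` or list of them.
#' @param J Number of components.
#' @param single_width Share one SD across all components?
#' @param loss `"density"` (unweighted least squares on bin densities) or
#'   `"counts"` (residuals on bin counts, weighting datasets by size).
#' @param init Optional list(centers, sigma) overriding the deterministic
#'   start.
#' @param n_starts Number of random restarts.
#' @param seed Seed for the restarts.
#' @return A `mixture_model` with additional elements: `gof` (per-dataset
#'   R^2), `sse`, `se` (asymptotic SEs for centers, sigmas and fractions,
#'   when the Hessian is invertible), `loss`, `convergence`.
#' @export
fit_mixture_global <- function(pdfs, J, single_width = TRUE,
                               loss = c("density", "counts"),
                               init = NULL, n_starts = 10, seed = 1) {
  loss <- match.arg(loss)
  if (inherits(pdfs, "histogram_pdf")) pdfs <- list(pdfs)
  stopifnot(length(pdfs) >= 1, J >= 1)
  lapply(pdfs, function(p) stopifnot(inherits(p, "histogram_pdf")))
  n_occ <- min(vapply(pdfs, function(p) sum(p$counts > 0), integer(1)))
  if (J > n_occ)
    stop("J exceeds the number of occupied bins (", n_occ, ")", call. = FALSE)
  nd <- length(pdfs)
  labels <- vapply(seq_len(nd), function(i) {
    if (is.null(pdfs[[i]]$label)) paste0("dataset", i) else pdfs[[i]]$label
  }, character(1))

  all_mids <- unlist(lapply(pdfs, function(p) p$mids))
  all_w <- unlist(lapply(pdfs, function(p) p$density))
  bw <- pdfs[[1]]$bin_width
  rng <- range(all_mids) + c(-bw, bw)
  n_sig <- if (single_width) 1L else J

  unpack <- function(theta) {
    centers <- theta[seq_len(J)]
    sigmas <- rep_len(exp(theta[J + seq_len(n_sig)]), J)
    fr <- matrix(0, nd, J)
    off <- J + n_sig
    for (d in seq_len(nd)) {
      fr[d, ] <- if (J == 1) 1 else .softmax(theta[off + seq_len(J - 1)])
      off <- off + (J - 1)
    }
    list(centers = centers, sigmas = sigmas, fractions = fr)
  }
  objective <- function(theta) {
    p <- unpack(theta)
    sse <- 0
    for (d in seq_len(nd)) {
      h <- pdfs[[d]]
      mu <- numeric(length(h$mids))
      for (j in seq_len(J))
        mu <- mu + p$fractions[d, j] *
          stats::dnorm(h$mids, p$centers[j], p$sigmas[j])
      res <- if (loss == "density") h$density - mu
             else h$counts - mu * h$n * h$bin_width
      sse <- sse + sum(res^2)
    }
    sse
  }

  # weighted quantile-spread deterministic start
  wq <- function(q) {
    cw <- cumsum(all_w) / sum(all_w)
    all_mids[pmax(1, findInterval(q, cw) + 1)]
  }
  m1 <- sum(all_mids * all_w) / sum(all_w)
  s_pool <- sqrt(max(sum((all_mids - m1)^2 * all_w) / sum(all_w), bw^2))
  start0 <- list(centers = sort(wq((seq_len(J) - 0.5) / J)),
                 sigma = max(s_pool / max(J - 1, 1), bw))
  if (!is.null(init)) {
    start0$centers <- rep_len(init$centers, J)
    if (!is.null(init$sigma)) start0$sigma <- init$sigma[1]
  }
  make_theta <- function(centers, sigma, jitter = 0) {
    c(pmin(pmax(centers + jitter * stats::rnorm(J, 0, bw), rng[1]), rng[2]),
      rep(log(sigma), n_sig),
      rep(0, nd * (J - 1)))
  }
  lower <- c(rep(rng[1], J), rep(log(1e-3), n_sig), rep(-20, nd * (J - 1)))
  upper <- c(rep(rng[2], J), rep(log(10), n_sig), rep(20, nd * (J - 1)))

  starts <- with_seed(seed, {
    s <- list(make_theta(start0$centers, start0$sigma))
    for (k in seq_len(n_starts)) {
      cs <- sort(stats::runif(J, rng[1], rng[2]))
      sg <- stats::runif(1, bw / 2, 2 * s_pool)
      s[[k + 1]] <- make_theta(cs, sg)
    }
    s
  })

  best <- NULL
  for (th in starts) {
    fit <- tryCatch(
      stats::nlminb(th, objective, lower = lower, upper = upper,
                    control = list(iter.max = 2000, eval.max = 4000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed to converge from all starts",
                          call. = FALSE)

  p <- unpack(best$par)
  ord <- order(p$centers)
  model <- mixture_model(p$centers[ord], p$sigmas[ord],
                         p$fractions[, ord, drop = FALSE], datasets = labels)
  model$sse <- best$objective
  model$loss <- loss
  model$convergence <- best$convergence
  model$gof <- vapply(seq_len(nd), function(d) {
    h <- pdfs[[d]]
    mu <- eval_mixture(model, h$mids, d)
    obs <- if (loss == "density") h$density else h$counts
    fitv <- if (loss == "density") mu else mu * h$n * h$bin_width
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) 0 else 1 - sum((obs - fitv)^2) / sst
  }, numeric(1))
  nobs <- sum(vapply(pdfs, function(p) length(p$mids), integer(1)))
  model$se <- .mixture_se(best$par, objective, unpack, ord, J, n_sig, nd, nobs)
  model
}

# Asymptotic SEs from the numerical Hessian of the SSE surface; fractions
# get delta-method SEs through the softmax Jacobian.
.mixture_se <- function(theta, objective, unpack, ord, J, n_sig, nd, nobs) {
  tryCatch({
    H <- stats::optimHess(theta, objective)
    npar <- length(theta)
    # residual-variance scaling: objective is the SSE itself
    s2 <- objective(theta) / max(nobs - npar, 1)
    cv <- tryCatch(solve(H) * 2 * s2, error = function(e) NULL)
    if (is.null(cv)) return(NULL)
    eps <- 1e-6
    se_all <- sqrt(pmax(diag(cv), 0))
    centers_se <- se_all[seq_len(J)][ord]
    sig_se <- (se_all[J + seq_len(n_sig)] * unpack(theta)$sigmas[seq_len(n_sig)])
    frac_se <- matrix(NA_real_, nd, J)
    off <- J + n_sig
    for (d in seq_len(nd)) {
      if (J > 1) {
        idx <- off + seq_len(J - 1)
        Jac <- matrix(0, J, J - 1)
        z0 <- theta[idx]
        f0 <- .softmax(z0)
        for (k in seq_len(J - 1)) {
          z <- z0; z[k] <- z[k] + eps
          Jac[, k] <- (.softmax(z) - f0) / eps
        }
        cvz <- cv[idx, idx, drop = FALSE]
        frac_se[d, ] <- sqrt(pmax(diag(Jac %*% cvz %*% t(Jac)), 0))[ord]
        off <- off + (J - 1)
      } else frac_se[d, ] <- 0
    }
    list(centers = centers_se, sigmas = sig_se, fractions = frac_se)
  }, error = function(e) NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mixture_model <- function(x, ...) {
  cat("Log-Gaussian mixture:", length(x$centers), "component(s),",
      nrow(x$fractions), "dataset(s)\n")
  cat("  centers (D-tilde):", paste(signif(x$centers, 4), collapse = ", "), "\n")
  cat("  sigmas:", paste(signif(x$sigmas, 4), collapse = ", "), "\n")
  for (d in seq_len(nrow(x$fractions)))
    cat(sprintf("  %s fractions: %s\n", x$datasets[d],
                paste(signif(x$fractions[d, ], 4), collapse = ", ")))
  if (!is.null(x$gof))
    cat("  R^2:", paste(signif(x$gof, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Peak diffusivity of the dominant population
#'
#' Fits a Gaussian on the D-tilde axis to the histogram bins whose density
#' exceeds half the global maximum — restricted to the contiguous lobe
#' containing the maximum, so a secondary mode does not contaminate the fit —
#' and reports D_pk = 10^(fitted center).
#'
#' @param pdf A `histogram_pdf`.
#' @return A `peak_fit`: list(D_pk, center, width, amplitude, points_used).
#' @export
find_peak_D <- function(pdf) {
  stopifnot(inherits(pdf, "histogram_pdf"))
  dmax <- max(pdf$density)
  qual <- pdf$density > 0.5 * dmax
  imax <- which.max(pdf$density)
  lo <- imax; while (lo > 1 && qual[lo - 1]) lo <- lo - 1
  hi <- imax; while (hi < length(qual) && qual[hi + 1]) hi <- hi + 1
  idx <- lo:hi
  if (length(idx) < 3)
    stop("fewer than 3 histogram points above half maximum", call. = FALSE)
  df <- data.frame(x = pdf$mids[idx], y = pdf$density[idx])
  fit <- minpack.lm::nlsLM(
    y ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
    start = list(a = dmax, mu = pdf$mids[imax], s = pdf$bin_width),
    lower = c(a = 0, mu = min(df$x) - 1, s = 1e-3),
    upper = c(a = Inf, mu = max(df$x) + 1, s = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(list(D_pk = 10^co[["mu"]], center = co[["mu"]],
                 width = abs(co[["s"]]), amplitude = co[["a"]],
                 points_used = length(idx)),
            class = "peak_fit")
}

#' Population shifts between two fitted fraction vectors
#'
#' Expresses redistribution relative to the pre-lesion population-1
#' fraction: the loss of population 1 is 100 * (f1_before - f1_after) /
#' f1_before percent, and the gain routed to each population k > 1 is
#' 100 * (fk_after - fk_before) / f1_before percent — i.e., what share of
#' the originally immobile pool was rendered mobile, and where it went.
#'
#' @param fractions_before,fractions_after Fraction vectors summing to 1.
#' @return list(loss_pop1_pct, gain_pct) where gain_pct is named by
#'   population index for k = 2 ... J.
#' @export
population_shift <- function(fractions_before, fractions_after) {
  stopifnot(length(fractions_before) == length(fractions_after),
            length(fractions_before) >= 2)
  if (abs(sum(fractions_before) - 1) > 1e-6 ||
      abs(sum(fractions_after) - 1) > 1e-6)
    stop("fractions must sum to 1", call. = FALSE)
  f1b <- fractions_before[1]
  if (f1b == 0) stop("pre-lesion population-1 fraction is zero", call. = FALSE)
  k <- seq_along(fractions_before)[-1]
  gain <- 100 * (fractions_after[k] - fractions_before[k]) / f1b
  names(gain) <- paste0("pop", k)
  list(loss_pop1_pct = 100 * (f1b - fractions_after[1]) / f1b,
       gain_pct = gain)
}
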