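# Independent brute-force oracles used across test files. These are written
# against the definitions, not against the package's code paths.

# MSD by explicit double loop over all (i, i+n) pairs, positions in um.
msd_double_loop <- function(x_um, y_um, n) {
  L <- length(x_um)
  acc <- 0; cnt <- 0
  for (i in 1:(L - n)) {
    acc <- acc + (x_um[i + n] - x_um[i])^2 + (y_um[i + n] - y_um[i])^2
    cnt <- cnt + 1
  }
  acc / cnt
}

# Exhaustive max-gain matching between two spot sets: every A-spot maps to a
# B-spot within radius or to nothing; all injective choice vectors are
# enumerated via a mixed-radix counter. Returns the first-optimum assignment
# (choices explored with B ascending, "none" coded 0 explored last within the
# lexicographic sweep) as an integer vector of B indices (NA = unmatched).
bf_match <- function(ax, ay, bx, by, radius) {
  nA <- length(ax); nB <- length(bx)
  if (nA == 0) return(integer(0))
  r2 <- radius^2
  best_gain <- -Inf; best <- rep(NA_integer_, nA)
  choices <- rep(0L, nA)  # 0 = unmatched, else B index
  repeat {
    used <- choices[choices > 0L]
    if (!anyDuplicated(used)) {
      gain <- 0; ok <- TRUE
      for (a in seq_len(nA)) {
        b <- choices[a]
        if (b > 0L) {
          d2 <- (ax[a] - bx[b])^2 + (ay[a] - by[b])^2
          if (d2 > r2) { ok <- FALSE; break }
          gain <- gain + r2 - d2
        }
      }
      if (ok && gain > best_gain) {
        best_gain <- gain
        best <- ifelse(choices == 0L, NA_integer_, choices)
      }
    }
    k <- nA
    while (k >= 1) {
      choices[k] <- choices[k] + 1L
      if (choices[k] <= nB) break
      choices[k] <- 0L; k <- k - 1
    }
    if (k < 1) break
  }
  best
}

# Two-sided Fisher p by full hypergeometric enumeration (minimum-likelihood
# convention; 1e-7 relative tolerance absorbs floating-point ties, as is
# standard for this test).
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random short 2-D trajectory (nm columns) for oracle comparisons
random_traj <- function(L, D = 0.1, dt = 0.03, sigma_nm = 20) {
  x <- cumsum(c(0, rnorm(L - 1, 0, sqrt(2 * D * dt))))
  y <- cumsum(c(0, rnorm(L - 1, 0, sqrt(2 * D * dt))))
  data.frame(x_nm = x * 1000 + rnorm(L, 0, sigma_nm),
             y_nm = y * 1000 + rnorm(L, 0, sigma_nm),
             frame = seq_len(L) - 1L)
}
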