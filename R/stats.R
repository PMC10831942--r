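#' Fisher's exact test on a 2x2 survival table
#'
#' Two-sided exact p-value for association in a 2x2 contingency table
#' (rows: genotype; columns: alive/dead), using the minimum-likelihood
#' convention: with margins fixed, the p-value sums the hypergeometric
#' probabilities of all tables no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) {
    stopifnot(length(table) == 4)
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  stopifnot(dim(table) == c(2, 2))
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Holm step-down multiple-testing adjustment
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  stopifnot(is.numeric(p), length(p) >= 1)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Welch two-sample t-tests across groups
#'
#' Two-sided Welch (unequal-variance) t-tests for every pairwise comparison
#' among the supplied groups; feed the p column to [holm_adjust()] for
#' family-wise error control. Set `var_equal = TRUE` for the pooled-variance
#' flavor.
#'
#' @param groups Named list of numeric vectors (>= 2 observations each).
#' @param var_equal Assume equal variances?
#' @return data.frame: group1, group2, t, df, p.
#' @export
welch_t <- function(groups, var_equal = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, function(g) stopifnot(length(g) >= 2))
  cmb <- utils::combn(length(groups), 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    x <- groups[[i]]; y <- groups[[j]]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y))
        return(data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
                          t = 0, df = NA_real_, p = 1))
      stop("zero variance in both groups with unequal means", call. = FALSE)
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
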