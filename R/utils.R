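#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#' A `NULL` seed evaluates the code with the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Convert a log10 diffusivity to a diffusion coefficient
#'
#' The analysis works on the dimensionless axis D-tilde = log10(D / 1 um^2/s).
#' This helper maps fitted centers back to um^2/s.
#'
#' @param d_log Numeric vector of log10 diffusivities.
#' @return Diffusion coefficients in um^2/s.
#' @examples
#' D_from_log(-2.63)  # ~2.3e-3 um^2/s
#' @export
D_from_log <- function(d_log) {
  stopifnot(is.numeric(d_log))
  10^d_log
}

stop_not_finite <- function(x, name) {
  if (!all(is.finite(x))) stop("non-finite values in ", name, call. = FALSE)
}
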