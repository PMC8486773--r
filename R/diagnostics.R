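#' Gelman-Rubin potential scale reduction factor
#'
#' Standard PSRF from the within-chain variance `W` and between-chain
#' variance `B`: with `m` chains of length `n`,
#' `PSRF = sqrt(((n - 1)/n * W + B/n) / W)` where `B/n` is the variance of
#' the chain means. Values near 1 indicate that the chains have mixed over
#' the same distribution; values above about 1.2 indicate non-convergence.
#'
#' @param traces List of numeric vectors (one scalar trace per chain), all
#'   of equal length of at least 10.
#' @return The PSRF, truncated below at 1 (the raw estimator can dip
#'   marginally under 1 through its finite-sample `(n - 1)/n` factor, so
#'   identical chains report exactly 1). Fully degenerate traces (zero
#'   within- and between-chain variance) also return 1.
#' @export
gelman_rubin <- function(traces) {
  m <- length(traces)
  if (m < 2) stop("PSRF requires at least 2 chains")
  n <- unique(vapply(traces, length, integer(1)))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains too short for a meaningful diagnostic")
  means <- vapply(traces, mean, numeric(1))
  W <- mean(vapply(traces, var, numeric(1)))
  B_over_n <- var(means)
  if (W == 0 && B_over_n == 0) return(1)
  if (W == 0) return(Inf)
  max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
}
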