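#' Sum-normalise protein profiles onto the unit simplex
#'
#' Divides each row by its row total so that fractionation profiles become
#' compositions summing to 1; the operation is invariant to positive row
#' scaling. All-zero rows are dropped with a warning.
#'
#' @param m Non-negative matrix, proteins x channels.
#' @param condition Optional condition tag stored as an attribute.
#' @return Row-normalised matrix.
#' @export
sum_normalise <- function(m, condition = NULL) {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stop("negative intensities")
  if (anyNA(m)) stop("missing values; impute before normalising")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warning(sum(rs == 0), " all-zero row(s) dropped")
    m <- m[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  out <- m / rs
  if (!is.null(condition)) attr(out, "condition") <- condition
  out
}

#' Variance-stabilising transform with robust affine calibration
#'
#' Brings the columns of one replicate's intensity matrix onto a common
#' scale and applies a generalised-log transform. Each column is calibrated
#' to a reference column by median/MAD matching (an affine map fitted
#' robustly, removing technical between-column scale and offset
#' differences); the calibrated intensities are then passed through
#' `glog2(x) = log2((x + sqrt(x^2 + c^2)) / 2)`, which behaves like `log2`
#' for large intensities while remaining defined and smooth near and below
#' zero. The offset `c` governs where the transform switches from linear
#' (additive-noise-dominated low intensities) to logarithmic
#' (multiplicative-noise-dominated high intensities); it is chosen by a
#' coarse grid search minimising the absolute Spearman correlation between
#' per-row mean and standard deviation of the transformed matrix, i.e. the
#' residual mean-variance dependence.
#'
#' @param m Positive intensity matrix (proteins x channels) for one
#'   replicate.
#' @param reference Either a column index used as calibration reference, or
#'   `"pseudo"` for a row-median pseudo-reference (default).
#' @return Matrix on the glog2 scale, same shape and dimnames.
#' @export
vstab_normalise <- function(m, reference = "pseudo") {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing values; impute before normalising")
  ref <- if (identical(reference, "pseudo")) apply(m, 1, median)
         else m[, reference]
  ref_med <- median(ref)
  ref_mad <- mad(ref)
  cal <- m
  for (j in seq_len(ncol(m))) {
    sj <- mad(m[, j])
    if (sj == 0) sj <- sd(m[, j])
    b <- if (is.na(sj) || sj == 0 || ref_mad == 0) 1 else ref_mad / sj
    a <- ref_med - b * median(m[, j])
    cal[, j] <- a + b * m[, j]
  }
  glog2 <- function(x, cc) log2((x + sqrt(x^2 + cc^2)) / 2)
  base <- median(abs(cal))
  if (!is.finite(base) || base <= 0) base <- 1
  cand <- base * 2^seq(-8, 12)
  mean_sd_rho <- function(v) {
    s <- apply(v, 1, sd)
    if (all(s == 0)) return(0)
    abs(cor(rowMeans(v), s, method = "spearman"))
  }
  score <- vapply(cand, function(cc) mean_sd_rho(glog2(cal, cc)),
                  numeric(1))
  out <- glog2(cal, cand[which.min(score)])
  if (any(!is.finite(out))) stop("non-finite values after transformation")
  out
}

#' Subset two matrices to their common protein accessions
#'
#' @param a,b Matrices with accession rownames.
#' @return List with elements `a` and `b`, both restricted to the shared
#'   accessions in identical row order.
#' @export
intersect_conditions <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (!length(common)) stop("no shared accessions between the conditions")
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}
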