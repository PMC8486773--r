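#' Within-replicate log ratios against the baseline timepoint
#'
#' For a paired design, the difference of each protein's log2 abundance at
#' `timepoint` and at 0 h within the same replicate.
#'
#' @param tc Array proteins x timepoints x replicates (log2 scale), with
#'   timepoint dimnames in hours.
#' @param timepoint Non-baseline timepoint (hours).
#' @param baseline Baseline timepoint (default 0).
#' @return Matrix proteins x replicates of paired differences.
#' @export
paired_log_ratios <- function(tc, timepoint, baseline = 0) {
  tps <- dimnames(tc)[[2]]
  tp <- as.character(timepoint)
  b <- as.character(baseline)
  if (!(tp %in% tps) || !(b %in% tps))
    stop("timepoint not present in the time course")
  if (tp == b) stop("timepoint must differ from the baseline")
  tc[, tp, , drop = TRUE] - tc[, b, , drop = TRUE]
}

#' Estimate empirical-Bayes variance-shrinkage hyperparameters
#'
#' Fits the scaled-F model of the moderated t framework to the observed
#' sample variances: the prior degrees of freedom `d0` and prior variance
#' `s0_sq` are obtained by moment matching on the log variances (digamma /
#' trigamma inversion, as implemented in limma's `fitFDist`). When the
#' spread of the log variances does not exceed its expected sampling
#' variability, `d0` is infinite and all variances shrink to the common
#' value.
#'
#' @param s2 Per-protein sample variances.
#' @param df Residual degrees of freedom (scalar or per-protein vector).
#' @return List with elements `d0` and `s0_sq` (class `ebayes_hyper`).
#' @export
estimate_ebayes <- function(s2, df) {
  if (length(s2) < 2) stop("too few variances for hyperparameter estimation")
  fit <- limma::fitFDist(s2, df1 = df)
  structure(list(d0 = fit$df2, s0_sq = fit$scale), class = "ebayes_hyper")
}

#' Moderated one-sample t-test on paired differences
#'
#' Shrinks each protein's variance toward the prior:
#' `s2_post = (d0 * s0_sq + d * s2) / (d0 + d)` with `d = n - 1`, and tests
#' the mean paired difference with `t = mean / sqrt(s2_post / n)` on
#' `d0 + d` degrees of freedom. With `d0 = 0` this is the ordinary paired
#' t-test; as `d0` grows all variances approach `s0_sq`.
#'
#' @param differences Matrix proteins x replicates of paired log2 ratios
#'   (at least two replicates).
#' @param hyper An `ebayes_hyper` list from [estimate_ebayes()], or `NULL`
#'   to estimate it from `differences`.
#' @return Data frame: `accession`, `log2fc`, `s2`, `s2_post`, `t_mod`,
#'   `df_total`, `p`, `p_adj` (BH-adjusted).
#' @export
moderated_t <- function(differences, hyper = NULL) {
  differences <- as.matrix(differences)
  n <- ncol(differences)
  if (n < 2) stop("moderated test requires at least 2 replicates")
  d <- n - 1
  m <- rowMeans(differences)
  s2 <- apply(differences, 1, var)
  if (is.null(hyper)) hyper <- estimate_ebayes(s2, d)
  d0 <- hyper$d0
  s0 <- hyper$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2))
             else (d0 * s0 + d * s2) / (d0 + d)
  t_mod <- m / sqrt(s2_post / n)
  # total df capped at the summed residual df, as in the limma convention
  df_total <- min(d0 + d, d * length(s2))
  p <- 2 * pt(-abs(t_mod), df = df_total)
  data.frame(accession = rownames(differences) %||%
               sprintf("row%05d", seq_along(m)),
             log2fc = m, s2 = s2, s2_post = s2_post, t_mod = t_mod,
             df_total = df_total, p = p, p_adj = adjust_bh(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call significantly changed proteins
#'
#' A protein is called up- (down-)regulated at a timepoint when its
#' BH-adjusted p-value is at most `p_cut` and its log2 fold change is at
#' least `lfc_cut` in magnitude; both boundaries are inclusive.
#'
#' @param results Data frame from [moderated_t()].
#' @param p_cut Adjusted p-value cutoff (default 0.01, i.e. 1% FDR).
#' @param lfc_cut Absolute log2 fold-change cutoff (default 0.6).
#' @return `results` with an added `call` column in `{"up", "down", "ns"}`.
#' @export
call_significant <- function(results, p_cut = 0.01, lfc_cut = 0.6) {
  call <- rep("ns", nrow(results))
  sig <- results$p_adj <= p_cut & abs(results$log2fc) >= lfc_cut
  call[sig & results$log2fc > 0] <- "up"
  call[sig & results$log2fc < 0] <- "down"
  results$call <- call
  results
}

#' Differential abundance across all timepoints
#'
#' Runs the paired moderated t-test of every non-baseline timepoint against
#' 0 h, with per-timepoint empirical-Bayes shrinkage, BH adjustment and the
#' significance call.
#'
#' @param tc Array proteins x timepoints x replicates (log2 scale).
#' @inheritParams call_significant
#' @return Named list of result data frames, one per non-baseline
#'   timepoint.
#' @export
moderated_de <- function(tc, p_cut = 0.01, lfc_cut = 0.6) {
  tps <- dimnames(tc)[[2]]
  out <- lapply(setdiff(tps, "0"), function(tp) {
    call_significant(moderated_t(paired_log_ratios(tc, tp)),
                     p_cut = p_cut, lfc_cut = lfc_cut)
  })
  names(out) <- setdiff(tps, "0")
  out
}
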