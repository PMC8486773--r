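#' Posterior similarity matrix
#'
#' Entry (i, j) is the fraction of posterior partition samples in which
#' proteins i and j are allocated to the same cluster. (This "posterior
#' similarity matrix" from the clustering literature is unrelated to
#' peptide-spectrum matches.)
#'
#' @param samples A `gp_partition_samples` object, or an integer matrix of
#'   partitions (samples x items).
#' @return Symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
posterior_similarity <- function(samples) {
  P <- if (inherits(samples, "gp_partition_samples")) samples$partitions
       else as.matrix(samples)
  if (nrow(P) < 1) stop("at least one partition sample required")
  n <- ncol(P)
  psm <- matrix(0, n, n)
  for (s in seq_len(nrow(P)))
    psm <- psm + outer(P[s, ], P[s, ], "==")
  psm <- psm / nrow(P)
  if (inherits(samples, "gp_partition_samples"))
    dimnames(psm) <- list(samples$accessions, samples$accessions)
  psm
}

#' Posterior expected adjusted Rand index of a candidate partition
#'
#' The Fritsch-Ickstadt estimator: the expected adjusted Rand index between
#' a candidate partition and the unknown true partition, computed from the
#' pairwise co-clustering probabilities of the posterior similarity matrix.
#'
#' @param partition Integer vector of cluster labels.
#' @param psm Posterior similarity matrix.
#' @return The PEAR score (1 when the candidate matches a point-mass
#'   posterior exactly; 0 defined for degenerate denominators).
#' @export
pear <- function(partition, psm) {
  n <- length(partition)
  up <- upper.tri(psm)
  I <- outer(partition, partition, "==")[up]
  p <- psm[up]
  nb <- n * (n - 1) / 2
  exp_term <- sum(I) * sum(p) / nb
  denom <- 0.5 * (sum(I) + sum(p)) - exp_term
  if (denom == 0) return(0)
  (sum(I * p) - exp_term) / denom
}

#' Summarise posterior partition samples into one clustering
#'
#' Generates candidate partitions by average-linkage hierarchical
#' clustering on one minus the posterior similarity matrix, cut at every
#' number of clusters, and returns the candidate maximising the posterior
#' expected adjusted Rand index ([pear()]); ties go to fewer clusters.
#'
#' @param psm Posterior similarity matrix.
#' @param max_k Largest candidate cluster count (default: number of items).
#' @return Integer vector of cluster labels (canonical: numbered by first
#'   appearance), with the PEAR score as attribute `"pear"`.
#' @export
summarise_partition <- function(psm, max_k = nrow(psm)) {
  n <- nrow(psm)
  if (n == 1) return(structure(1L, pear = 1))
  h <- hclust(stats::as.dist(1 - psm), method = "average")
  ks <- seq_len(min(max_k, n))
  cand <- cutree(h, k = ks)
  scores <- apply(cand, 2, pear, psm = psm)
  best <- which.max(scores)  # which.max takes the first (smallest k) tie
  part <- match(cand[, best], unique(cand[, best]))
  names(part) <- rownames(psm)
  structure(part, pear = unname(scores[best]))
}

## Adjusted Rand index between two partitions (pair-counting form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  nb <- choose(length(a), 2)
  expected <- sum_a * sum_b / nb
  mx <- 0.5 * (sum_a + sum_b)
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Replicate-consensus clusters
#'
#' Fuses the per-replicate posterior similarity matrices by element-wise
#' averaging, summarises the fused matrix into one partition, and retains
#' only proteins whose allocation is consistent across replicates: a
#' protein is kept iff, in every replicate, its posterior similarity to the
#' medoid of its fused cluster exceeds 0.5. Cluster profiles are reported
#' as the mean and the 0.05/0.95 quantile band over retained members.
#'
#' @param sample_list List of `gp_partition_samples` (one per replicate)
#'   over an identical protein index.
#' @param profiles Optional list of standardised profile matrices (one per
#'   replicate) used for the cluster summaries; profiles are averaged
#'   across replicates per protein.
#' @return List with `clusters` (data frame `accession`, `cluster_id`,
#'   `retained`), `summary` (data frame `cluster_id`, `timepoint`, `mean`,
#'   `q05`, `q95`; `NULL` without profiles), `fused_psm` and `partition`.
#' @export
consensus_across_replicates <- function(sample_list, profiles = NULL) {
  if (length(sample_list) < 1) stop("at least one replicate required")
  accs <- sample_list[[1]]$accessions
  for (s in sample_list)
    if (!identical(s$accessions, accs))
      stop("replicates must share an identical protein index")
  psms <- lapply(sample_list, posterior_similarity)
  fused <- Reduce(`+`, psms) / length(psms)
  part <- summarise_partition(fused)
  n <- length(part)

  ## medoid of each fused cluster: member with the highest mean fused
  ## similarity to its cluster
  medoid <- vapply(sort(unique(part)), function(cl) {
    idx <- which(part == cl)
    idx[which.max(rowMeans(fused[idx, idx, drop = FALSE]))]
  }, integer(1))
  med_of <- medoid[part]
  retained <- rep(TRUE, n)
  for (psm_r in psms)
    retained <- retained & psm_r[cbind(seq_len(n), med_of)] > 0.5

  clusters <- data.frame(accession = accs %||% as.character(seq_len(n)),
                         cluster_id = as.integer(part),
                         retained = retained, stringsAsFactors = FALSE)
  summary <- NULL
  if (!is.null(profiles)) {
    avg <- Reduce(`+`, lapply(profiles, as.matrix)) / length(profiles)
    tp <- colnames(avg)
    rows <- lapply(sort(unique(part)), function(cl) {
      idx <- which(part == cl & retained)
      if (!length(idx)) return(NULL)
      sub <- avg[idx, , drop = FALSE]
      data.frame(cluster_id = cl, timepoint = as.numeric(tp),
                 mean = colMeans(sub),
                 q05 = apply(sub, 2, quantile, 0.05),
                 q95 = apply(sub, 2, quantile, 0.95),
                 row.names = NULL)
    })
    summary <- do.call(rbind, rows)
  }
  list(clusters = clusters, summary = summary, fused_psm = fused,
       partition = part)
}
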