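#' Fisher's exact association between two protein sets
#'
#' Two-sided Fisher's exact test of the 2x2 table formed by membership in
#' `set_a` and `set_b` over a finite universe, as used to associate
#' temporal clusters with spatial compartments. The reported odds ratio is
#' the sample (cross-product) odds ratio; when a cell is zero a 0.5
#' continuity correction is applied and flagged.
#'
#' @param set_a,set_b Character vectors of accessions, subsets of
#'   `universe`.
#' @param universe Character vector defining the tested population.
#' @return One-row data frame: `n11`, `n12`, `n21`, `n22`, `odds_ratio`,
#'   `continuity`, `p`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  set_a <- unique(intersect(set_a, universe))
  set_b <- unique(intersect(set_b, universe))
  n11 <- length(intersect(set_a, set_b))
  n12 <- length(set_a) - n11
  n21 <- length(set_b) - n11
  n22 <- length(universe) - n11 - n12 - n21
  tab <- matrix(c(n11, n21, n12, n22), 2)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  continuity <- any(tab == 0)
  cc <- if (continuity) 0.5 else 0
  or <- ((n11 + cc) * (n22 + cc)) / ((n12 + cc) * (n21 + cc))
  data.frame(n11 = n11, n12 = n12, n21 = n21, n22 = n22,
             odds_ratio = or, continuity = continuity, p = p)
}

#' Associate temporal clusters with spatial compartments
#'
#' Runs [fisher_overlap()] for every cluster/compartment pair over the
#' universe of proteins present in both analyses, with BH adjustment
#' across all pairs.
#'
#' @param clusters Data frame with `accession` and `cluster_id` (e.g. the
#'   `clusters` element of [consensus_across_replicates()]; only retained
#'   members are used when a `retained` column is present).
#' @param allocation Allocation data frame from [allocate()] (`accession`,
#'   `label`).
#' @param universe Universe of accessions; default: intersection of the
#'   two inputs.
#' @return Data frame: `cluster_id`, `compartment`, contingency counts,
#'   `odds_ratio`, `p`, `p_adj`.
#' @export
cluster_compartment_association <- function(clusters, allocation,
                                            universe = NULL) {
  if (!is.null(clusters$retained))
    clusters <- clusters[clusters$retained, , drop = FALSE]
  if (is.null(universe))
    universe <- intersect(clusters$accession, allocation$accession)
  alloc <- allocation[allocation$label != "unknown", , drop = FALSE]
  rows <- list()
  for (cl in sort(unique(clusters$cluster_id))) {
    set_cl <- clusters$accession[clusters$cluster_id == cl]
    for (comp in unique(alloc$label)) {
      set_c <- alloc$accession[alloc$label == comp]
      r <- fisher_overlap(set_cl, set_c, universe)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(cluster_id = cl, compartment = comp), r)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p)
  out
}

#' Hypergeometric term enrichment over an annotation table
#'
#' One-sided (upper-tail) hypergeometric test of over-representation of
#' each annotation term in a query set, with BH adjustment across terms —
#' an offline, annotation-source-agnostic enrichment test. Terms with no
#' annotated accession in the universe are skipped with a warning.
#'
#' @param query Character vector of accessions (the gene/protein list of
#'   interest), subset of `universe`.
#' @param annotation Long-format data frame with columns `term_id`,
#'   `term_name` (optional), `accession`.
#' @param universe Character vector of accessions defining the population.
#' @param p_adj_cutoff Significance flag threshold on the adjusted p-value
#'   (default 0.05, strict `<`).
#' @return Data frame per term: `term_id`, `term_name`, `n_term`,
#'   `overlap`, `expected`, `p`, `p_adj`, `significant`.
#' @export
term_enrichment <- function(query, annotation, universe,
                            p_adj_cutoff = 0.05) {
  if (!all(c("term_id", "accession") %in% names(annotation)))
    stop("annotation needs columns term_id and accession")
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  N <- length(universe)
  q <- length(query)
  terms <- unique(annotation$term_id)
  rows <- lapply(terms, function(tm) {
    hits <- unique(intersect(
      annotation$accession[annotation$term_id == tm], universe))
    if (!length(hits)) {
      warning("term ", tm, " has no annotated accession in the universe; ",
              "skipped")
      return(NULL)
    }
    m <- length(hits)
    ov <- length(intersect(query, hits))
    nm <- annotation$term_name[annotation$term_id == tm][1] %||% NA_character_
    data.frame(term_id = tm,
               term_name = if (is.null(nm)) NA_character_ else nm,
               n_term = m, overlap = ov, expected = q * m / N,
               p = phyper(ov - 1, m, N - m, q, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adj <- adjust_bh(out$p)
  out$significant <- out$p_adj < p_adj_cutoff
  out[order(out$p), , drop = FALSE]
}
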