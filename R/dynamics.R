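#' Normalised L2 distance between compartment posterior vectors
#'
#' The Euclidean norm between a protein's compartment posterior
#' probabilities in two conditions, divided by `sqrt(2)` so that the value
#' lies in `[0, 1]` and equals 1 exactly when all certainty moves from one
#' compartment to another (the raw Euclidean norm between two one-hot
#' vectors is `sqrt(2)`). The outlier mass is excluded: the inputs are the
#' per-compartment joint posterior probabilities, whose total may be below
#' one.
#'
#' @param x,y Compartment probability vectors of equal length with
#'   non-negative entries summing to at most 1 (within rounding).
#' @return The normalised distance in `[0, 1]`.
#' @export
#' @examples
#' l2_distance(c(1, 0, 0), c(0, 1, 0))  # 1: complete reallocation
l2_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("posterior vectors differ in length")
  if (any(x < 0) || any(y < 0))
    stop("posterior probabilities must be non-negative")
  sqrt(sum((x - y)^2)) / sqrt(2)
}

#' Classify a translocation event
#'
#' Types: 1 = organelle to (different) organelle; 2 = unknown to organelle;
#' 3 = organelle to unknown; 4 = unassigned in both conditions but with a
#' (near-)maximal shift of the posterior distribution; 0 = no movement.
#' The default type-4 threshold `1 - 1e-9` keeps only events whose
#' normalised L2 distance is maximal up to floating point, reproducing the
#' rule that only proteins at the maximum distance are extracted; a softer
#' cut may be supplied for exploratory screens.
#'
#' @param label_a,label_b Compartment label or `"unknown"`, per condition.
#' @param l2 Normalised L2 distance from [l2_distance()].
#' @param schema Compartment schema the labels must belong to.
#' @param l2_type4_threshold Minimum distance for a type-4 call.
#' @return Integer type in `0:4`.
#' @export
classify_translocation <- function(label_a, label_b, l2,
                                   schema = lopit_compartments(),
                                   l2_type4_threshold = 1 - 1e-9) {
  ok <- c(schema, "unknown")
  if (!(label_a %in% ok) || !(label_b %in% ok))
    stop("label not in schema: ",
         paste(setdiff(c(label_a, label_b), ok), collapse = ", "))
  if (l2 < 0 || l2 > 1 + 1e-12) stop("l2 must lie in [0, 1]")
  a_known <- label_a != "unknown"
  b_known <- label_b != "unknown"
  if (a_known && b_known && label_a != label_b) return(1L)
  if (!a_known && b_known) return(2L)
  if (a_known && !b_known) return(3L)
  if (!a_known && !b_known && l2 >= l2_type4_threshold) return(4L)
  0L
}

#' Detect and type translocation events between two conditions
#'
#' Compares pooled TAGM posteriors for the same proteins in two conditions:
#' computes each protein's normalised L2 posterior distance, applies the
#' allocation thresholds per condition, and classifies the event type.
#'
#' @param post_a,post_b `tagm_posterior` objects sharing accessions and
#'   schema.
#' @param p_threshold,outlier_threshold Allocation thresholds, see
#'   [allocate()].
#' @param l2_type4_threshold Type-4 distance cut, see
#'   [classify_translocation()].
#' @return Data frame (`translocation_records`): `accession`, `label_A`,
#'   `label_B`, `type`, `l2`.
#' @export
detect_translocations <- function(post_a, post_b,
                                  p_threshold = 0.999,
                                  outlier_threshold = 1e-6,
                                  l2_type4_threshold = 1 - 1e-9) {
  if (!identical(rownames(post_a$pi), rownames(post_b$pi)))
    stop("posteriors must share an identical protein index")
  if (!identical(post_a$schema, post_b$schema))
    stop("posteriors must share the compartment schema")
  lab_a <- allocate(post_a, p_threshold, outlier_threshold)$label
  lab_b <- allocate(post_b, p_threshold, outlier_threshold)$label
  l2 <- vapply(seq_len(nrow(post_a$pi)), function(i)
    l2_distance(post_a$pi[i, ], post_b$pi[i, ]), numeric(1))
  type <- vapply(seq_along(l2), function(i)
    classify_translocation(lab_a[i], lab_b[i], min(l2[i], 1),
                           schema = post_a$schema,
                           l2_type4_threshold = l2_type4_threshold),
    integer(1))
  data.frame(accession = rownames(post_a$pi),
             label_A = lab_a, label_B = lab_b,
             type = type, l2 = l2, stringsAsFactors = FALSE)
}

#' Rank candidate movers by posterior distance
#'
#' Orders the non-type-0 records by decreasing L2 distance; ties are broken
#' lexicographically by accession so the ranking is stable.
#'
#' @param records Translocation record data frame
#'   (see [detect_translocations()]).
#' @return The mover subset with a `rank` column, sorted.
#' @export
rank_movers <- function(records) {
  movers <- records[records$type != 0, , drop = FALSE]
  ord <- order(-movers$l2, movers$accession)
  movers <- movers[ord, , drop = FALSE]
  movers$rank <- seq_len(nrow(movers))
  rownames(movers) <- NULL
  movers
}

#' Summarise organelle-to-organelle flows
#'
#' Tallies the typed translocation records into a from/to count matrix
#' (type-1 events) and per-compartment entering/leaving counts (types 1-3).
#'
#' @param records Translocation record data frame.
#' @param schema Compartment schema.
#' @return List with `matrix` (from x to counts over the schema), `flows`
#'   (long-format data frame `from`, `to`, `count` for plotting, type-1
#'   only) and `per_compartment` (`compartment`, `entering`, `leaving`).
#' @export
summarise_flows <- function(records, schema = lopit_compartments()) {
  t1 <- records[records$type == 1, , drop = FALSE]
  mat <- matrix(0L, length(schema), length(schema),
                dimnames = list(from = schema, to = schema))
  if (nrow(t1))
    for (i in seq_len(nrow(t1)))
      mat[t1$label_A[i], t1$label_B[i]] <- mat[t1$label_A[i], t1$label_B[i]] + 1L
  entering <- colSums(mat) +
    vapply(schema, function(s)
      sum(records$type == 2 & records$label_B == s), numeric(1))
  leaving <- rowSums(mat) +
    vapply(schema, function(s)
      sum(records$type == 3 & records$label_A == s), numeric(1))
  flows <- which(mat > 0, arr.ind = TRUE)
  flows <- data.frame(from = schema[flows[, 1]], to = schema[flows[, 2]],
                      count = mat[flows], stringsAsFactors = FALSE)
  list(matrix = mat, flows = flows,
       per_compartment = data.frame(compartment = schema,
                                    entering = as.integer(entering),
                                    leaving = as.integer(leaving),
                                    stringsAsFactors = FALSE))
}

#' Score detected movers against planted ground truth
#'
#' For synthetic runs: per-type recall and precision of the detected
#' translocation events against the generator's truth record.
#'
#' @param records Translocation record data frame.
#' @param truth Truth data frame from [generate_spatial_pair()] with
#'   columns `accession` and `true_mover_type`.
#' @return Data frame per type 1-4: planted and detected counts, true
#'   positives, recall, precision.
#' @export
recover_planted_movers <- function(records, truth) {
  if (!all(records$accession %in% truth$accession))
    stop("accession mismatch between records and truth")
  tt <- truth$true_mover_type[match(records$accession, truth$accession)]
  out <- lapply(1:4, function(ty) {
    planted <- sum(tt == ty)
    detected <- sum(records$type == ty)
    tp <- sum(records$type == ty & tt == ty)
    data.frame(type = ty, planted = planted, detected = detected, tp = tp,
               recall = if (planted) tp / planted else NA_real_,
               precision = if (detected) tp / detected else NA_real_)
  })
  do.call(rbind, out)
}
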