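#' PSM quality-filter policy
#'
#' Thresholds applied to PSM-level search output before quantitation. All
#' thresholds are inclusive: a row passing a boundary exactly (for instance
#' Isolation Interference of exactly 50) is retained. The spatial
#' (fractionation) and temporal (time-course) presets differ only in the
#' minimum ion score (20 vs 25).
#'
#' @param preset `"spatial"` or `"temporal"`.
#' @param max_isolation_interference Maximum co-isolation percentage
#'   (default 50).
#' @param min_avg_sn Minimum average reporter signal-to-noise (default 10).
#' @param min_ion_score Minimum search-engine ion score; defaults to 20 for
#'   the spatial preset and 25 for the temporal preset.
#' @param max_missing Maximum missing reporter values per PSM (default 2).
#' @param require_unique Keep only PSMs with `quan_info == "Unique"`.
#' @param require_rank1 Keep only `rank == 1` and `search_engine_rank == 1`.
#' @param require_single_group Keep only `n_protein_groups == 1`.
#' @param drop_contaminants Drop rows flagged as contaminants.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(preset = c("spatial", "temporal"),
                          max_isolation_interference = 50,
                          min_avg_sn = 10,
                          min_ion_score = NULL,
                          max_missing = 2,
                          require_unique = TRUE,
                          require_rank1 = TRUE,
                          require_single_group = TRUE,
                          drop_contaminants = TRUE) {
  preset <- match.arg(preset)
  if (is.null(min_ion_score))
    min_ion_score <- if (preset == "spatial") 20 else 25
  stopifnot(is.finite(max_isolation_interference), is.finite(min_avg_sn),
            is.finite(min_ion_score), max_missing >= 0)
  structure(list(preset = preset,
                 max_isolation_interference = max_isolation_interference,
                 min_avg_sn = min_avg_sn,
                 min_ion_score = min_ion_score,
                 max_missing = as.integer(max_missing),
                 require_unique = require_unique,
                 require_rank1 = require_rank1,
                 require_single_group = require_single_group,
                 drop_contaminants = drop_contaminants),
            class = "filter_policy")
}

psm_quality_columns <- function() {
  c("accession", "n_protein_groups", "rank", "search_engine_rank",
    "isolation_interference", "avg_reporter_sn", "ion_score",
    "quan_info", "is_contaminant")
}

reporter_columns <- function(table) {
  grep("^tmt_", names(table), value = TRUE)
}

psm_keep_mask <- function(table, policy) {
  need <- psm_quality_columns()
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("PSM table is missing required column(s): ",
         paste(miss, collapse = ", "))
  rep_cols <- reporter_columns(table)
  if (!length(rep_cols))
    stop("PSM table is missing required column(s): tmt_*")
  keep <- table$isolation_interference <= policy$max_isolation_interference &
    table$avg_reporter_sn >= policy$min_avg_sn &
    table$ion_score >= policy$min_ion_score
  if (policy$require_single_group)
    keep <- keep & table$n_protein_groups == 1
  if (policy$require_rank1)
    keep <- keep & table$rank == 1 & table$search_engine_rank == 1
  if (policy$require_unique)
    keep <- keep & table$quan_info == "Unique"
  if (policy$drop_contaminants)
    keep <- keep & !table$is_contaminant
  n_missing <- rowSums(is.na(as.matrix(table[, rep_cols])))
  keep & n_missing <= policy$max_missing
}

#' Filter a PSM table by quality thresholds
#'
#' Retains exactly the rows satisfying every enabled predicate of the
#' policy, including the cap on missing reporter values per PSM. Row order
#' is preserved and the operation is idempotent.
#'
#' @param table PSM data frame (see [generate_psm_table()] for the schema).
#' @param policy A [filter_policy()].
#' @return The filtered data frame.
#' @export
filter_psms <- function(table, policy = filter_policy("spatial")) {
  table[psm_keep_mask(table, policy), , drop = FALSE]
}

#' Classify the mechanism of each missing reporter value
#'
#' A missing cell is labelled MNAR (missing not at random, i.e. attributable
#' to low ion abundance) when the mean of its row's observed intensities
#' falls below the `low_quantile` quantile of all row means; every other
#' missing cell is labelled MAR.
#'
#' @param intensities Numeric matrix (PSMs x channels) containing `NA`
#'   holes.
#' @param low_quantile Quantile of row mean intensity below which holes are
#'   considered intensity-dependent (default 0.2).
#' @return Character matrix of the same shape: `NA` for observed cells,
#'   `"MAR"` or `"MNAR"` for holes. Rows with no observed value are flagged
#'   in the `"drop_rows"` attribute and a warning is raised.
#' @export
classify_missingness <- function(intensities, low_quantile = 0.2) {
  m <- as.matrix(intensities)
  row_means <- rowMeans(m, na.rm = TRUE)
  empty <- !is.finite(row_means)
  if (any(empty)) {
    warning(sum(empty), " fully missing row(s) flagged for removal")
    row_means[empty] <- -Inf
  }
  cut <- quantile(row_means[!empty], low_quantile, names = FALSE)
  lab <- matrix(NA_character_, nrow(m), ncol(m), dimnames = dimnames(m))
  holes <- is.na(m)
  low <- row_means < cut | empty
  lab[holes] <- ifelse(low[row(m)[holes]], "MNAR", "MAR")
  attr(lab, "drop_rows") <- which(empty)
  lab
}

#' Impute missing reporter intensities by mechanism
#'
#' MAR cells are imputed by k-nearest-neighbour averaging: the k rows
#' closest in Euclidean distance over jointly observed channels (among rows
#' observed in the target channel) contribute the mean of their values in
#' that channel. MNAR cells are imputed with the left-censored deterministic
#' minimum of the observed values in their channel.
#'
#' @param intensities Numeric matrix with `NA` holes; every row must retain
#'   at least one observed value.
#' @param mechanism Character matrix as returned by
#'   [classify_missingness()].
#' @param k Number of neighbours for MAR imputation (default 10). When
#'   fewer eligible neighbours exist, all available are used with a
#'   warning.
#' @return The completed matrix; observed cells are never altered.
#' @export
impute_missing <- function(intensities, mechanism, k = 10) {
  m <- as.matrix(intensities)
  if (any(rowSums(!is.na(m)) == 0))
    stop("rows with no observed value cannot be imputed; drop them first")
  if (!all(dim(m) == dim(mechanism)))
    stop("mechanism matrix does not match the intensity matrix")
  out <- m
  ## MNAR: per-channel observed minimum
  mnar <- which(mechanism == "MNAR" & is.na(m), arr.ind = TRUE)
  if (nrow(mnar)) {
    col_min <- apply(m, 2, function(x) suppressWarnings(min(x, na.rm = TRUE)))
    out[mnar] <- col_min[mnar[, 2]]
  }
  ## MAR: kNN on jointly observed channels
  mar_rows <- unique(which(mechanism == "MAR" & is.na(m), arr.ind = TRUE)[, 1])
  warned <- FALSE
  for (i in mar_rows) {
    obs_i <- !is.na(m[i, ])
    dists <- vapply(seq_len(nrow(m)), function(j) {
      if (j == i) return(Inf)
      shared <- obs_i & !is.na(m[j, ])
      if (!any(shared)) return(Inf)
      sqrt(sum((m[i, shared] - m[j, shared])^2) / sum(shared) * ncol(m))
    }, numeric(1))
    for (jcol in which(mechanism[i, ] == "MAR" & is.na(m[i, ]))) {
      donor <- which(is.finite(dists) & !is.na(m[, jcol]))
      if (!length(donor))
        stop("no donor rows observed in channel ", jcol)
      if (length(donor) < k && !warned) {
        warning("fewer than k eligible neighbours; using all available")
        warned <- TRUE
      }
      nn <- donor[order(dists[donor])][seq_len(min(k, length(donor)))]
      out[i, jcol] <- mean(m[nn, jcol])
    }
  }
  out
}

#' Aggregate PSM intensities to protein level
#'
#' Combines PSMs to one row per protein accession by taking the channel-wise
#' median of all PSM intensities for that accession.
#'
#' @param table Filtered, imputed PSM data frame with `accession` and
#'   `tmt_*` columns.
#' @return Numeric matrix proteins x channels, rownames = accessions
#'   (sorted).
#' @export
aggregate_to_proteins <- function(table) {
  rep_cols <- reporter_columns(table)
  if (!nrow(table))
    return(matrix(numeric(0), 0, length(rep_cols),
                  dimnames = list(NULL, rep_cols)))
  accs <- sort(unique(table$accession))
  m <- as.matrix(table[, rep_cols])
  out <- vapply(accs, function(a) {
    apply(m[table$accession == a, , drop = FALSE], 2, median)
  }, numeric(length(rep_cols)))
  t(out)
}
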