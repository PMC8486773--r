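#' Generate a synthetic PSM-level table with quality columns
#'
#' Emulates the PSM export of a database-search engine: each peptide-spectrum
#' match carries a parent protein accession, search-quality columns, and a
#' vector of TMT reporter intensities with missing values of two mechanisms.
#' A chosen proportion of rows violates each quality filter; missing values
#' are either missing at random (uniformly placed) or missing not at random
#' (placed only in PSMs whose mean intensity lies below the 20th percentile,
#' emulating the drop-out of low-abundance ions).
#'
#' @param n_psms Number of PSM rows.
#' @param violation_rates Named numeric vector of per-filter violation
#'   proportions; recognised names: `isolation_interference`,
#'   `avg_reporter_sn`, `ion_score`, `rank`, `search_engine_rank`,
#'   `n_protein_groups`, `quan_info`, `contaminant`, `missing` (more than
#'   `policy$max_missing` holes in a row).
#' @param missing_rates Named numeric vector with elements `MAR` and `MNAR`,
#'   each the proportion of reporter cells made missing by that mechanism.
#' @param n_channels Reporter channels per PSM (default 10, one TMT
#'   10-plex).
#' @param psms_per_protein Average PSMs per parent protein.
#' @param policy [filter_policy()] used to evaluate the ground-truth
#'   keep-mask.
#' @param seed Integer seed.
#' @return List with `table` (data frame in the PSM TSV schema),
#'   `keep_mask` (logical; row passes every filter), and `mechanism`
#'   (character matrix, `""` observed, `"MAR"`/`"MNAR"` for holes).
#' @export
generate_psm_table <- function(n_psms, violation_rates = c(),
                               missing_rates = c(MAR = 0, MNAR = 0),
                               n_channels = 10, psms_per_protein = 4,
                               policy = filter_policy("spatial"),
                               seed = 1L) {
  rates <- c(isolation_interference = 0, avg_reporter_sn = 0, ion_score = 0,
             rank = 0, search_engine_rank = 0, n_protein_groups = 0,
             quan_info = 0, contaminant = 0, missing = 0)
  if (length(violation_rates)) {
    unknown <- setdiff(names(violation_rates), names(rates))
    if (length(unknown))
      stop("unknown filter name(s): ", paste(unknown, collapse = ", "))
    rates[names(violation_rates)] <- violation_rates
  }
  mr <- c(MAR = 0, MNAR = 0)
  mr[names(missing_rates)] <- missing_rates
  if (any(c(rates, mr) < 0) || any(c(rates, mr) > 1))
    stop("rates must lie in [0, 1]")
  withr::with_seed(seed, {
    generate_psm_table_impl(n_psms, rates, mr, n_channels,
                            psms_per_protein, policy)
  })
}

generate_psm_table_impl <- function(n, rates, mr, d, ppp, policy) {
  viol <- function(rate) runif(n) < rate
  n_prot <- max(1L, ceiling(n / ppp))
  tab <- data.frame(
    accession = sample(sprintf("P%05d", seq_len(n_prot)), n, replace = TRUE),
    n_protein_groups = ifelse(viol(rates["n_protein_groups"]),
                              sample(2:4, n, TRUE), 1L),
    rank = ifelse(viol(rates["rank"]), 2L, 1L),
    search_engine_rank = ifelse(viol(rates["search_engine_rank"]), 2L, 1L),
    isolation_interference = ifelse(viol(rates["isolation_interference"]),
                                    runif(n, 55, 100), runif(n, 0, 45)),
    avg_reporter_sn = ifelse(viol(rates["avg_reporter_sn"]),
                             runif(n, 0, 9.5), runif(n, 12, 120)),
    ion_score = ifelse(viol(rates["ion_score"]),
                       runif(n, 0, 19.5), runif(n, 30, 100)),
    quan_info = ifelse(viol(rates["quan_info"]), "Shared", "Unique"),
    is_contaminant = viol(rates["contaminant"]),
    stringsAsFactors = FALSE)

  ## log-normal PSM abundance with mild channel effects
  abundance <- exp(rnorm(n, log(1e5), 1))
  chan_eff <- exp(rnorm(d, 0, 0.1))
  inten <- abundance %o% chan_eff *
    matrix(exp(rnorm(n * d, 0, 0.15)), n, d)

  mech <- matrix("", n, d)
  n_cells <- n * d
  ## MAR holes: uniform over cells
  n_mar <- round(mr["MAR"] * n_cells)
  if (n_mar > 0) {
    idx <- sample.int(n_cells, n_mar)
    mech[idx] <- "MAR"
  }
  ## MNAR holes: only in low-intensity rows (bottom 20% of row means)
  n_mnar <- round(mr["MNAR"] * n_cells)
  if (n_mnar > 0) {
    low_rows <- which(rowMeans(inten) <= quantile(rowMeans(inten), 0.2))
    pool <- as.vector(outer(low_rows, (seq_len(d) - 1) * n, "+"))
    pool <- pool[mech[pool] == ""]
    if (length(pool) < n_mnar) {
      warning("fewer low-intensity cells than requested MNAR holes; capping")
      n_mnar <- length(pool)
    }
    mech[sample(pool, n_mnar)] <- "MNAR"
  }
  inten[mech != ""] <- NA_real_

  ## force extra holes on rows chosen to violate the missingness filter
  over <- viol(rates["missing"])
  for (i in which(over)) {
    need <- policy$max_missing + 1L - sum(is.na(inten[i, ]))
    if (need > 0) {
      cols <- sample(which(!is.na(inten[i, ])), min(need, d))
      inten[i, cols] <- NA_real_
      mech[i, cols] <- "MAR"
    }
  }

  colnames(inten) <- sprintf("tmt_%02d", seq_len(d))
  tab <- cbind(tab, as.data.frame(inten))
  keep <- psm_keep_mask(tab, policy)
  list(table = tab, keep_mask = keep, mechanism = mech)
}
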