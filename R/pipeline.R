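#' End-to-end pipeline settings
#'
#' Collects the tunable parameters of the spatial and temporal analyses in
#' one validated list. Every component function can also be called
#' directly; this object exists for the orchestrated runs
#' ([run_spatial()], [run_temporal()]) and for run manifests.
#'
#' @param tagm_chains,tagm_iter,tagm_burn_in,tagm_thin,tagm_keep MCMC
#'   settings of the spatial classifier.
#' @param p_threshold,outlier_threshold Allocation thresholds.
#' @param l2_type4_threshold Type-4 translocation distance cut.
#' @param impute_k Neighbours for MAR imputation.
#' @param mnar_quantile Row-mean intensity quantile below which missing
#'   values are treated as intensity-dependent.
#' @param p_cut,lfc_cut Differential-abundance cutoffs.
#' @param cluster_iter,cluster_chains GP-mixture sampler settings.
#' @param seed Base seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tagm_chains = 4, tagm_iter = 2000,
                            tagm_burn_in = round(0.4 * tagm_iter),
                            tagm_thin = 5, tagm_keep = 3,
                            p_threshold = 0.999, outlier_threshold = 1e-6,
                            l2_type4_threshold = 1 - 1e-9,
                            impute_k = 10, mnar_quantile = 0.2,
                            p_cut = 0.01, lfc_cut = 0.6,
                            cluster_iter = 2000, cluster_chains = 2,
                            seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            outlier_threshold >= 0, outlier_threshold <= 1,
            l2_type4_threshold >= 0, l2_type4_threshold <= 1,
            p_cut > 0, p_cut <= 1, lfc_cut >= 0, impute_k >= 1,
            mnar_quantile >= 0, mnar_quantile <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

write_manifest <- function(outdir, config, files) {
  cfg_path <- file.path(outdir, "config.txt")
  scal <- Filter(function(x) is.atomic(x) && length(x) == 1,
                 unclass(config))
  write_config_file(scal, cfg_path)
  manifest <- list(config = scal,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   files = files,
                   package_version =
                     as.character(utils::packageVersion("lopitdyn")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the spatial (two-condition) analysis end to end
#'
#' Classifies both conditions with the TAGM MCMC classifier, detects and
#' types translocation events, ranks them by posterior distance and
#' summarises compartment flows. Inputs are sum-normalised on entry;
#' results and a run manifest are written as TSV/JSON when `outdir` is
#' given.
#'
#' @param expr_a,expr_b Intensity or profile matrices (proteins x
#'   channels, accession rownames) for the two conditions.
#' @param markers A [marker_map()].
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (created if needed).
#' @return List with `allocation_a`, `allocation_b` (with per-compartment
#'   posterior columns), `movers`, `flows`, `records`.
#' @export
run_spatial <- function(expr_a, expr_b, markers,
                        config = pipeline_config(), outdir = NULL) {
  both <- intersect_conditions(expr_a, expr_b)
  prof_a <- sum_normalise(both$a, condition = "A")
  prof_b <- sum_normalise(both$b, condition = "B")
  keep <- markers$accession %in% rownames(prof_a)
  mk <- marker_map(markers$accession[keep], markers$compartment[keep],
                   schema = attr(markers, "schema"))

  res_a <- tagm_classify(prof_a, mk, n_chains = config$tagm_chains,
                         n_iter = config$tagm_iter,
                         burn_in = config$tagm_burn_in,
                         thin = config$tagm_thin, n_keep = config$tagm_keep,
                         seed = config$seed,
                         p_threshold = config$p_threshold,
                         outlier_threshold = config$outlier_threshold)
  res_b <- tagm_classify(prof_b, mk, n_chains = config$tagm_chains,
                         n_iter = config$tagm_iter,
                         burn_in = config$tagm_burn_in,
                         thin = config$tagm_thin, n_keep = config$tagm_keep,
                         seed = config$seed + 1000L,
                         p_threshold = config$p_threshold,
                         outlier_threshold = config$outlier_threshold)

  records <- detect_translocations(res_a$posterior, res_b$posterior,
                                   p_threshold = config$p_threshold,
                                   outlier_threshold = config$outlier_threshold,
                                   l2_type4_threshold = config$l2_type4_threshold)
  movers <- rank_movers(records)
  flows <- summarise_flows(records, schema = attr(mk, "schema"))

  alloc_tab <- function(res) {
    cbind(res$allocation, as.data.frame(res$posterior$pi))
  }
  out <- list(allocation_a = alloc_tab(res_a),
              allocation_b = alloc_tab(res_b),
              movers = movers, flows = flows, records = records,
              posterior_a = res_a$posterior, posterior_b = res_b$posterior,
              convergence = list(A = res_a$convergence,
                                 B = res_b$convergence))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(allocation_A = "allocation_A.tsv",
               allocation_B = "allocation_B.tsv",
               movers = "movers.tsv", flows = "flows.tsv")
    write.table(out$allocation_a, file.path(outdir, files[1]), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$allocation_b, file.path(outdir, files[2]), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$movers, file.path(outdir, files[3]), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$flows$flows, file.path(outdir, files[4]), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_manifest(outdir, config, as.list(files))
  }
  out
}

#' Run the temporal analysis end to end
#'
#' Differential abundance (paired moderated t against 0 h at every
#' timepoint), per-replicate DP-GP clustering of standardised profiles,
#' replicate-consensus cluster extraction, and (optionally) association of
#' the consensus clusters with a spatial allocation.
#'
#' @param tc Array proteins x timepoints x replicates of log2 abundances
#'   (at least two replicates).
#' @param config A [pipeline_config()].
#' @param allocation Optional allocation data frame from the spatial
#'   branch; triggers the cluster-compartment Fisher association.
#' @param outdir Optional output directory.
#' @return List with `de` (per-timepoint result tables), `replicate_fits`,
#'   `consensus`, and `association` (or `NULL`).
#' @export
run_temporal <- function(tc, config = pipeline_config(),
                         allocation = NULL, outdir = NULL) {
  if (length(dim(tc)) != 3 || dim(tc)[3] < 2)
    stop("paired design requires at least two replicates")
  de <- moderated_de(tc, p_cut = config$p_cut, lfc_cut = config$lfc_cut)

  profs <- lapply(seq_len(dim(tc)[3]), function(r)
    standardise_profiles(tc[, , r]))
  fits <- lapply(seq_along(profs), function(r)
    fit_gp_mixture(profs[[r]],
                   gp_mixture_config(n_iter = config$cluster_iter,
                                     seed = config$seed + 100L + r)))
  consensus <- consensus_across_replicates(fits, profiles = profs)

  association <- NULL
  if (!is.null(allocation))
    association <- cluster_compartment_association(consensus$clusters,
                                                   allocation)
  out <- list(de = de, replicate_fits = fits, consensus = consensus,
              association = association)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (tp in names(de)) {
      f <- sprintf("de_%sh.tsv", tp)
      write.table(de[[tp]], file.path(outdir, f), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      files[[paste0("de_", tp)]] <- f
    }
    write.table(consensus$clusters, file.path(outdir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files$clusters <- "clusters.tsv"
    if (!is.null(consensus$summary)) {
      write.table(consensus$summary, file.path(outdir, "cluster_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      files$cluster_summary <- "cluster_summary.tsv"
    }
    if (!is.null(association)) {
      write.table(association, file.path(outdir, "association.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      files$association <- "association.tsv"
    }
    write_manifest(outdir, config, files)
  }
  out
}

#' Preprocess a PSM-level table to a protein matrix
#'
#' The standard PSM-to-protein path: quality filtering, mechanism-aware
#' imputation (dropping fully missing rows), and median aggregation.
#'
#' @param table PSM data frame.
#' @param policy A [filter_policy()].
#' @param impute_k Neighbours for MAR imputation.
#' @param mnar_quantile Low-intensity quantile for the MNAR call.
#' @return Protein x channel intensity matrix.
#' @export
preprocess_psms <- function(table, policy = filter_policy("spatial"),
                            impute_k = 10, mnar_quantile = 0.2) {
  table <- filter_psms(table, policy)
  rep_cols <- reporter_columns(table)
  m <- as.matrix(table[, rep_cols])
  if (anyNA(m)) {
    mech <- classify_missingness(m, low_quantile = mnar_quantile)
    drop <- attr(mech, "drop_rows")
    if (length(drop)) {
      table <- table[-drop, , drop = FALSE]
      m <- m[-drop, , drop = FALSE]
      mech <- mech[-drop, , drop = FALSE]
    }
    m <- impute_missing(m, mech, k = impute_k)
    table[, rep_cols] <- m
  }
  aggregate_to_proteins(table)
}
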