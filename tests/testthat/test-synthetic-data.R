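test_that("spatial generator is deterministic and respects the simplex", {
  cfg <- spatial_sim_config(n_markers_per_class = 5, n_unknown = 60,
                            seed = 42)
  sim1 <- generate_spatial_pair(cfg)
  sim2 <- generate_spatial_pair(cfg)
  expect_identical(sim1, sim2)
  for (m in list(sim1$expr_a, sim1$expr_b)) {
    expect_true(all(m >= 0))
    expect_equal(rowSums(m), setNames(rep(1, nrow(m)), rownames(m)),
                 tolerance = 1e-9)
  }
  expect_identical(rownames(sim1$expr_a), rownames(sim1$expr_b))
  # generator does not disturb the global RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_spatial_pair(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("planted roles are consistent and mutually exclusive", {
  sim <- generate_spatial_pair(spatial_sim_config(
    n_markers_per_class = 5, n_unknown = 80, seed = 1))
  tr <- sim$truth
  schema <- attr(sim$markers, "schema")
  expect_true(all(table(tr$accession) == 1))  # one role per protein
  expect_true(all(tr$true_mover_type %in% 0:4))
  t1 <- tr[tr$true_mover_type == 1, ]
  expect_true(all(t1$true_label_A %in% schema & t1$true_label_B %in% schema &
                    t1$true_label_A != t1$true_label_B))
  expect_true(all(tr$true_label_A[tr$true_mover_type == 2] == "unassigned"))
  expect_true(all(tr$true_label_B[tr$true_mover_type == 2] %in% schema))
  expect_true(all(tr$true_label_B[tr$true_mover_type == 3] == "unassigned"))
  expect_true(all(tr$true_label_A[tr$true_mover_type == 4] == "unassigned" &
                    tr$true_label_B[tr$true_mover_type == 4] == "unassigned"))
})

test_that("degenerate spatial configs behave as constructed", {
  no_out <- generate_spatial_pair(spatial_sim_config(
    n_markers_per_class = 4, n_unknown = 30, outlier_fraction = 0,
    mover_counts = c(), seed = 2))
  expect_false(any(no_out$truth$true_label_A == "outlier"))
  expect_true(all(no_out$truth$true_label_A == no_out$truth$true_label_B))
  expect_error(spatial_sim_config(n_unknown = 5,
                                  mover_counts = c("1" = 10)),
               "configuration error")
  expect_error(spatial_sim_config(outlier_fraction = 1.2),
               "configuration error")
})

test_that("per-class marker means recover the generating mean profiles", {
  cfg <- spatial_sim_config(seed = 5)
  sim <- generate_spatial_pair(cfg)
  means <- attr(sim, "class_means")
  tol <- 3 * cfg$within_class_sd / sqrt(cfg$n_markers_per_class)
  for (k in seq_len(cfg$n_classes)) {
    acc <- sim$markers$accession[sim$markers$compartment ==
                                   attr(sim$markers, "schema")[k]]
    emp <- colMeans(sim$expr_a[acc, , drop = FALSE])
    expect_true(all(abs(emp - means[k, ]) < tol),
                info = paste("class", k))
  }
})

test_that("time-course generator is deterministic with stated structure", {
  cfg <- temporal_sim_config(n_proteins = 40, seed = 9)
  sim1 <- generate_timecourse(cfg)
  expect_identical(sim1, generate_timecourse(cfg))
  expect_equal(dim(sim1$tc), c(40, 6, 3))
  # noiseless single cluster: identical profiles within a replicate
  flat <- generate_timecourse(temporal_sim_config(
    n_proteins = 10, n_clusters = 1, noise_sd = 0, baseline_sd = 0,
    de_fraction = 0, seed = 1))
  expect_equal(max(apply(flat$tc[, , 1], 2, sd)), 0)
  # invalid configs
  expect_error(temporal_sim_config(n_proteins = 2, n_clusters = 5),
               "configuration error")
  expect_error(temporal_sim_config(timepoints = c(0, 2, 2)),
               "configuration error")
  expect_error(temporal_sim_config(de_log2fc = 0), "configuration error")
})

test_that("null time course has centred log ratios and grouping is exact on noiseless curves", {
  # de_fraction = 0, flat GP: expected log ratio vs 0 h is 0 at every tp
  null <- generate_timecourse(temporal_sim_config(
    n_proteins = 300, gp_amplitude = 1e-8, de_fraction = 0, seed = 21))
  for (tp in c("2", "6", "24")) {
    d <- paired_log_ratios(null$tc, tp)
    expect_lt(abs(mean(d)), 3 * 0.2 * sqrt(2) / sqrt(length(d)))
  }
  # brute-force grouping of the stored noiseless curves recovers the truth
  sim <- generate_timecourse(temporal_sim_config(
    n_proteins = 60, n_clusters = 3, gp_amplitude = 3, de_fraction = 0,
    seed = 6))
  noiseless <- sim$cluster_curves[sim$truth_clusters, ]
  km <- kmeans(noiseless, centers = 3, nstart = 10)
  expect_equal(lopitdyn:::adjusted_rand(km$cluster, sim$truth_clusters), 1)
})

test_that("PSM generator rates and truth masks follow the filter predicates", {
  # no violations, no missing: everything kept
  clean <- generate_psm_table(200, seed = 1)
  expect_true(all(clean$keep_mask))
  expect_false(anyNA(as.matrix(clean$table[, grep("^tmt_",
                                                  names(clean$table))])))
  # certain ion-score violation: nothing kept
  bad <- generate_psm_table(100, violation_rates = c(ion_score = 1),
                            seed = 2)
  expect_false(any(bad$keep_mask))
  # mixed rates: mask equals an independent row-wise predicate check
  mix <- generate_psm_table(
    400,
    violation_rates = c(isolation_interference = 0.1, avg_reporter_sn = 0.1,
                        ion_score = 0.1, rank = 0.05, quan_info = 0.1,
                        contaminant = 0.05, missing = 0.1),
    missing_rates = c(MAR = 0.02, MNAR = 0.02), seed = 3)
  tab <- mix$table
  pol <- filter_policy("spatial")
  inten <- as.matrix(tab[, grep("^tmt_", names(tab))])
  manual <- tab$isolation_interference <= 50 & tab$avg_reporter_sn >= 10 &
    tab$ion_score >= 20 & tab$n_protein_groups == 1 & tab$rank == 1 &
    tab$search_engine_rank == 1 & tab$quan_info == "Unique" &
    !tab$is_contaminant & rowSums(is.na(inten)) <= 2
  expect_identical(mix$keep_mask, manual)
  # MNAR holes sit in the low-intensity tail by construction
  mnar_rows <- unique(which(mix$mechanism == "MNAR", arr.ind = TRUE)[, 1])
  rm_all <- rowMeans(inten, na.rm = TRUE)
  expect_true(all(rm_all[mnar_rows] <= quantile(rm_all, 0.35)))
})
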