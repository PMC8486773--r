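# A small, well-separated 3-class dataset in 4 channels for fast checks.
toy_spatial <- function(n_per = 15, n_unknown = 12, sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    centres <- rbind(c(0.7, 0.1, 0.1, 0.1),
                     c(0.1, 0.7, 0.1, 0.1),
                     c(0.1, 0.1, 0.7, 0.1))
    schema <- c("A", "B", "C")
    draw <- function(k) {
      p <- pmax(centres[k, ] + rnorm(4, 0, sd), 1e-8); p / sum(p)
    }
    X <- t(cbind(sapply(rep(1:3, each = n_per), draw),
                 sapply(rep(1:3, length.out = n_unknown), draw)))
    rownames(X) <- sprintf("P%03d", seq_len(nrow(X)))
    markers <- marker_map(rownames(X)[1:(3 * n_per)],
                          schema[rep(1:3, each = n_per)], schema)
    truth <- schema[c(rep(1:3, each = n_per),
                      rep(1:3, length.out = n_unknown))]
    list(X = X, markers = markers, truth = truth)
  })
}

test_that("default priors follow the stated empirical construction", {
  toy <- toy_spatial()
  pr <- default_priors(toy$X, toy$markers)
  d <- ncol(toy$X)
  expect_equal(pr$nu0, d + 2)
  expect_equal(pr$beta0, colMeans(toy$X))
  ev <- eigen(pr$S0, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_true(isSymmetric(pr$V))
  expect_true(all(eigen(pr$V, only.values = TRUE)$values > 0))
  # outlier dispersion tracks half the population covariance
  set.seed(4)
  Sig <- diag(c(2, 1, 0.5))
  Z <- matrix(rnorm(6000), 2000, 3) %*% chol(Sig)
  colnames(Z) <- paste0("c", 1:3)
  rownames(Z) <- sprintf("Q%04d", 1:2000)
  mk <- marker_map(rownames(Z)[1:20], rep(c("A", "B"), 10), c("A", "B"))
  prZ <- default_priors(Z, mk)
  expect_equal(unname(diag(prZ$V)), diag(Sig) / 2, tolerance = 0.1)
  # a compartment with fewer than 2 markers is refused by name
  bad <- marker_map(rownames(Z)[1:3], c("A", "A", "B"), c("A", "B"))
  expect_error(default_priors(Z, bad), "B")
})

test_that("the collapsed Gibbs sampler recovers a well-separated toy and is seed-deterministic", {
  toy <- toy_spatial()
  fit <- fit_tagm_mcmc(toy$X, toy$markers, n_chains = 2, n_iter = 600,
                       seed = 3)
  fit2 <- fit_tagm_mcmc(toy$X, toy$markers, n_chains = 2, n_iter = 600,
                        seed = 3)
  expect_identical(fit$chains, fit2$chains)
  post <- pool_posteriors(fit, retained = 1:2)
  # every unknown's modal allocation equals its generating class
  unk <- setdiff(rownames(toy$X), toy$markers$accession)
  modal <- post$schema[max.col(post$pi[unk, ])]
  expect_identical(modal, toy$truth[match(unk, rownames(toy$X))])
  # probabilities conserve mass
  expect_equal(unname(rowSums(post$pi) + post$outlier),
               rep(1, nrow(toy$X)), tolerance = 1e-9)
  # markers are clamped: probability one on their label, never "unknown"
  al <- allocate(post)
  mk_rows <- match(toy$markers$accession, al$accession)
  expect_identical(al$label[mk_rows], toy$markers$compartment)
  expect_equal(al$best_prob[mk_rows], rep(1, length(mk_rows)))
})

test_that("collapsed posterior evaluation is equivariant under label permutation", {
  toy <- toy_spatial()
  pr <- default_priors(toy$X, toy$markers)
  schema <- attr(toy$markers, "schema")
  stats <- lopitdyn:::collapsed_class_stats(
    toy$X[toy$markers$accession, ], toy$markers$compartment, schema)
  x <- toy$X[nrow(toy$X), ]
  p <- lopitdyn:::collapsed_posterior_probs(x, stats, pr, 0.1)
  perm <- c(3, 1, 2)
  p_perm <- lopitdyn:::collapsed_posterior_probs(x, stats[perm], pr, 0.1)
  expect_equal(p_perm[1:3], p[perm], tolerance = 1e-12)
  expect_equal(p_perm[4], p[4], tolerance = 1e-12)
})

test_that("chain selection minimises the pooled PSRF with log-density tie-breaks", {
  mk_chain <- function(nout, lj = rep(0, length(nout)))
    list(z = matrix(1L, length(nout), 1), phi = matrix(1L, length(nout), 1),
         n_outlier = nout, log_joint = lj)
  base <- sin(seq_len(50)) * 2 + 10
  fit <- structure(list(chains = list(mk_chain(base), mk_chain(base + 0.01),
                                      mk_chain(base - 0.01),
                                      mk_chain(base + 40)),
                        accessions = "P1", unknown = "P1",
                        marker_z = 0L, schema = c("A", "B"),
                        meta = list()), class = "tagm_chains")
  conv <- assess_convergence(fit, n_keep = 3)
  expect_identical(sort(conv$retained), 1:3)  # the shifted chain is dropped
  expect_lt(conv$psrf_retained, 1.2)
  expect_gt(conv$psrf, 1.2)
  expect_error(assess_convergence(structure(list(chains = fit$chains[1]),
                                            class = "tagm_chains")),
               "2 chains")
})

test_that("pooled posteriors match a brute-force tally of the samples", {
  set.seed(7)
  z <- matrix(sample(1:3, 40, TRUE), 20, 2)
  phi <- matrix(rbinom(40, 1, 0.8), 20, 2)
  fit <- structure(list(
    chains = list(list(z = z, phi = phi,
                       n_outlier = rowSums(phi == 0),
                       log_joint = rep(0, 20))),
    accessions = c("M1", "U1", "U2"), unknown = c("U1", "U2"),
    marker_z = c(2L, 0L, 0L), schema = c("A", "B", "C"),
    meta = list()), class = "tagm_chains")
  post <- pool_posteriors(fit, retained = 1)
  for (j in 1:2) {
    for (k in 1:3)
      expect_equal(post$pi[j + 1, k], mean(z[, j] == k & phi[, j] == 1))
    expect_equal(unname(post$outlier[j + 1]), mean(phi[, j] == 0))
  }
  expect_equal(unname(post$pi[1, ]), c(0, 1, 0))  # clamped marker
})

test_that("allocation thresholds are strict exactly as quoted", {
  pi_mat <- rbind(c(0.999, 0.001, 0),    # at the threshold: unassigned
                  c(0.9995, 0.0005, 0),  # above, tiny outlier: assigned
                  c(0.9999, 0, 0))       # above, but outlier too large
  out <- c(0, 1e-7, 1e-3)
  pi_mat[3, ] <- pi_mat[3, ] * (1 - out[3])
  rownames(pi_mat) <- c("P1", "P2", "P3")
  post <- structure(list(pi = pi_mat, outlier = setNames(out, rownames(pi_mat)),
                         schema = c("A", "B", "C")),
                    class = "tagm_posterior")
  lab <- allocate(post)$label
  expect_identical(lab, c("unknown", "A", "unknown"))
})

test_that("allocation accuracy does not fall as class separation grows", {
  accs <- sapply(c(2, 3.2, 4.5), function(sep) {
    sim <- generate_spatial_pair(spatial_sim_config(
      n_classes = 6, n_channels = 12, n_markers_per_class = 8,
      n_unknown = 40, outlier_fraction = 0.1, class_separation = sep,
      mover_counts = c(), seed = 31))
    res <- tagm_classify(sim$expr_a, sim$markers, n_chains = 2,
                         n_iter = 800, seed = 17)
    al <- res$allocation
    unk <- setdiff(al$accession, sim$markers$accession)
    tr <- sim$truth$true_label_A[match(unk, sim$truth$accession)]
    lab <- al$label[match(unk, al$accession)]
    ok <- lab != "unknown" & tr %in% attr(sim$markers, "schema")
    if (!any(ok)) return(0)
    mean(lab[ok] == tr[ok])
  })
  expect_true(all(diff(accs) >= 0))
  expect_gte(accs[3], 0.95)
})
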