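test_that("profile standardisation centres, scales and rescales time", {
  m <- matrix(rnorm(40, 10, 3), 8, 5,
              dimnames = list(NULL, c(0, 2, 4, 12, 24)))
  s <- standardise_profiles(m)
  expect_equal(unname(rowMeans(s)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(s, 1, sd)), rep(1, 8), tolerance = 1e-12)
  expect_equal(attr(s, "t01"), c(0, 2, 4, 12, 24) / 24)
  # constant profile: centred only, warned
  expect_warning(sc <- standardise_profiles(
    rbind(m, 7)[, , drop = FALSE]), "zero-variance")
  expect_equal(unname(sc[9, ]), rep(0, 5))
  # two-point profile is antisymmetric around its mean
  two <- matrix(c(0, 1), 1, 2, dimnames = list(NULL, c(0, 24)))
  s2 <- standardise_profiles(two)
  expect_equal(unname(s2[1, 1]), unname(-s2[1, 2]))
})

test_that("the shared-latent GP marginal equals a dense multivariate normal oracle", {
  set.seed(8)
  t01 <- c(0, 2, 4, 6, 12, 24) / 24
  theta <- c(log(1.3), log(0.4), log(0.3))
  Y <- matrix(rnorm(4 * 6), 4, 6)
  attr(Y, "t01") <- t01
  ours <- gp_cluster_marginal(Y, theta)
  K <- lopitdyn:::sqexp_cov(t01, amplitude = exp(theta[1]),
                            lengthscale = exp(theta[2]))
  Sigma <- kronecker(matrix(1, 4, 4), K) + exp(2 * theta[3]) * diag(24)
  expect_equal(ours, dense_mvn_logpdf(as.vector(t(Y)), Sigma),
               tolerance = 1e-8)
  # smoothness: a flat profile prefers a long length-scale
  flat <- matrix(0.01 * sin(t01), 1); attr(flat, "t01") <- t01
  expect_gt(gp_cluster_marginal(flat, c(0, log(1), log(0.05))),
            gp_cluster_marginal(flat, c(0, log(0.02), log(0.05))))
  # two identical profiles: the shared-latent model beats independence
  prof <- matrix(rep(sin(2 * pi * t01), 2), 2, byrow = TRUE)
  attr(prof, "t01") <- t01
  one <- prof[1, , drop = FALSE]; attr(one, "t01") <- t01
  th <- c(0, log(0.3), log(0.1))
  expect_gt(gp_cluster_marginal(prof, th), 2 * gp_cluster_marginal(one, th))
})

test_that("posterior similarity matrices are exact co-clustering tallies", {
  P <- rbind(c(1, 1, 2, 2), c(1, 2, 2, 2), c(1, 1, 1, 2))
  psm <- posterior_similarity(P)
  expect_equal(diag(psm), rep(1, 4))
  expect_true(isSymmetric(psm))
  for (i in 1:4) for (j in 1:4)
    expect_equal(psm[i, j], mean(P[, i] == P[, j]))
  # identical partitions in all samples: entries are 0/1
  rep_psm <- posterior_similarity(P[c(1, 1, 1), ])
  expect_true(all(rep_psm %in% c(0, 1)))
})

test_that("partition summarisation maximises PEAR, checked by exhaustive search", {
  # posterior concentrated on one partition: returned exactly
  P <- matrix(rep(c(1, 1, 2, 2, 3), 20), 20, 5, byrow = TRUE)
  part <- summarise_partition(posterior_similarity(P))
  expect_equal(unname(part), c(1, 1, 2, 2, 3), ignore_attr = TRUE)
  # 4 items: compare with brute force over all 15 set partitions
  set.seed(9)
  samples <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 1, 1, 2),
                   c(1, 2, 2, 2), c(1, 1, 2, 3))
  psm <- posterior_similarity(samples)
  cand <- all_set_partitions(4)
  expect_length(cand, 15)
  scores <- vapply(cand, pear, numeric(1), psm = psm)
  best <- cand[[which.max(scores)]]
  got <- summarise_partition(psm)
  expect_equal(lopitdyn:::adjusted_rand(got, best), 1)
  expect_equal(attr(got, "pear"), max(scores), tolerance = 1e-12)
  # block-diagonal similarity: the two blocks are recovered
  blocks <- matrix(0.05, 8, 8)
  blocks[1:4, 1:4] <- 0.95; blocks[5:8, 5:8] <- 0.95
  diag(blocks) <- 1
  got_b <- summarise_partition(blocks)
  expect_equal(unname(got_b), rep(1:2, each = 4), ignore_attr = TRUE)
  # invariance to item reordering (up to labels)
  ord <- c(3, 1, 4, 2)
  re <- summarise_partition(psm[ord, ord])
  expect_equal(lopitdyn:::adjusted_rand(re, got[ord]), 1)
})

test_that("the DP-GP sampler is deterministic and recovers planted clusters", {
  sim <- generate_timecourse(temporal_sim_config(
    n_proteins = 60, gp_amplitude = 3, de_fraction = 0, seed = 6))
  Y <- standardise_profiles(sim$tc[, , 1])
  cfg <- gp_mixture_config(n_iter = 1000, seed = 5)
  fit <- fit_gp_mixture(Y, cfg)
  expect_identical(fit$partitions, fit_gp_mixture(Y, cfg)$partitions)
  part <- summarise_partition(posterior_similarity(fit))
  expect_equal(lopitdyn:::adjusted_rand(part, sim$truth_clusters), 1)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(mclust::adjustedRandIndex(part, sim$truth_clusters), 1)
})

test_that("the posterior cluster count concentrates at one on single-GP data", {
  k_mode <- function(noise) {
    sim <- generate_timecourse(temporal_sim_config(
      n_proteins = 40, n_clusters = 1, noise_sd = noise, de_fraction = 0,
      seed = 14))
    fit <- fit_gp_mixture(standardise_profiles(sim$tc[, , 1]),
                          gp_mixture_config(n_iter = 800, seed = 2))
    ks <- fit$k_trace[321:800]
    c(mode = as.integer(names(which.max(table(ks)))), frac1 = mean(ks == 1))
  }
  low <- k_mode(0.05)
  high <- k_mode(0.5)
  expect_equal(unname(low["mode"]), 1)
  expect_gte(low["frac1"], high["frac1"])
})

test_that("the Gelman-Rubin diagnostic matches its formula and edge cases", {
  x <- sin(seq_len(40)) + seq_len(40) / 40
  expect_equal(gelman_rubin(list(x, x, x)), 1)
  y <- x + 10 * sd(x)
  m <- 2; n <- length(x)
  W <- mean(c(var(x), var(y)))
  B_over_n <- var(c(mean(x), mean(y)))
  expect_equal(gelman_rubin(list(x, y)),
               sqrt(((n - 1) / n * W + B_over_n) / W))
  expect_gt(gelman_rubin(list(x, y)), 1.2)
  expect_equal(gelman_rubin(list(rep(1, 20), rep(1, 20))), 1)
  expect_error(gelman_rubin(list(x)), "2 chains")
  expect_error(gelman_rubin(list(x, x[1:10])), "equal length")
})

test_that("replicate consensus keeps concordant proteins and drops discordant ones", {
  base <- rep(1:3, each = 6)
  concordant <- fake_partition_samples(
    matrix(rep(base, 30), 30, 18, byrow = TRUE))
  out <- consensus_across_replicates(list(concordant, concordant,
                                          concordant))
  expect_true(all(out$clusters$retained))
  expect_equal(lopitdyn:::adjusted_rand(out$partition, base), 1)
  expect_equal(out$fused_psm, posterior_similarity(concordant))
  # one replicate of pure noise shrinks the retained set
  set.seed(11)
  noisy <- fake_partition_samples(
    t(replicate(30, sample(1:3, 18, TRUE))))
  out_noisy <- consensus_across_replicates(list(concordant, concordant,
                                                noisy))
  expect_lt(sum(out_noisy$clusters$retained), 18)
  # adding another concordant replicate never removes retained proteins
  out4 <- consensus_across_replicates(list(concordant, concordant, noisy,
                                           concordant))
  expect_true(all(out_noisy$clusters$retained <= out4$clusters$retained |
                    !out_noisy$clusters$retained))
  expect_error(consensus_across_replicates(list(
    concordant, fake_partition_samples(concordant$partitions,
                                       accessions = paste0("X", 1:18)))),
    "identical protein index")
})
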