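# Shared fixtures. Expensive MCMC runs are computed once per test session
# and cached, then reused by the module and acceptance tests.

.fixtures <- new.env(parent = emptyenv())

# Full-scale two-condition spatial study: 11 compartments, 19 channels,
# 500 proteins, 12 planted movers of each type; classified with the
# default 4-chain sampler in both conditions.
spatial_recovery_run <- function() {
  if (is.null(.fixtures$spatial)) {
    sim <- generate_spatial_pair(spatial_sim_config(seed = 7))
    res <- run_spatial(sim$expr_a, sim$expr_b, sim$markers,
                       pipeline_config(l2_type4_threshold = 0.5, seed = 11))
    .fixtures$spatial <- list(sim = sim, res = res)
  }
  .fixtures$spatial
}

# Two-chain DP-GP mixture run on 200 proteins with 3 planted co-regulation
# clusters (no differential-abundance shifts, so the planted clusters are
# the only temporal structure), 2000 sweeps per chain.
gp_reference_fits <- function() {
  if (is.null(.fixtures$gp)) {
    sim <- generate_timecourse(temporal_sim_config(de_fraction = 0,
                                                   seed = 3))
    Y <- standardise_profiles(sim$tc[, , 1])
    fits <- lapply(c(5L, 6L), function(s)
      fit_gp_mixture(Y, gp_mixture_config(seed = s)))
    .fixtures$gp <- list(sim = sim, profiles = Y, fits = fits)
  }
  .fixtures$gp
}

# Construct a gp_partition_samples object directly from a partition matrix
# (used to exercise the summarisation layer without running the sampler).
fake_partition_samples <- function(partitions, accessions = NULL) {
  partitions <- as.matrix(partitions)
  if (is.null(accessions))
    accessions <- sprintf("P%03d", seq_len(ncol(partitions)))
  structure(list(partitions = partitions, accessions = accessions),
            class = "gp_partition_samples")
}

# Dense multivariate normal log density via Cholesky (oracle helper).
dense_mvn_logpdf <- function(x, Sigma) {
  R <- chol(Sigma)
  z <- backsolve(R, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z * z)
}

# All set partitions of 1..n (restricted growth strings).
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    mx <- if (length(prefix)) max(prefix) else 0L
    for (v in seq_len(mx + 1L)) grow(c(prefix, v))
  }
  grow(integer(0))
  out
}
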