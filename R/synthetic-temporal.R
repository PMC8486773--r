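#' Configuration for the synthetic time-course generator
#'
#' Describes a multi-replicate whole-proteome time course on the log2 scale:
#' co-regulated clusters whose mean curves are drawn from a squared-
#' exponential Gaussian process over the (rescaled) sampling times, i.i.d.
#' measurement noise per replicate, and a subset of differentially abundant
#' proteins receiving an additive log2 shift at late timepoints.
#'
#' @param n_proteins Number of proteins.
#' @param timepoints Ordered sampling times in hours (default
#'   `c(0, 2, 4, 6, 12, 24)`).
#' @param n_replicates Biological replicates (default 3).
#' @param n_clusters Number of co-regulated clusters.
#' @param gp_lengthscale GP length-scale on the unit-rescaled time axis.
#' @param gp_amplitude GP amplitude (log2 units).
#' @param noise_sd Residual noise standard deviation (log2 units).
#' @param baseline_mean,baseline_sd Per-protein baseline abundance (log2).
#' @param de_fraction Proportion of proteins that are differentially
#'   abundant.
#' @param de_log2fc Absolute log2 fold change of DE proteins (must be > 0).
#' @param de_timepoints Hours at which the DE shift applies (default the two
#'   late timepoints, 12 and 24 h).
#' @param seed Integer seed; the generator uses its own stream.
#' @return A `temporal_sim_config` list.
#' @export
temporal_sim_config <- function(n_proteins = 200,
                                timepoints = c(0, 2, 4, 6, 12, 24),
                                n_replicates = 3, n_clusters = 3,
                                gp_lengthscale = 0.3, gp_amplitude = 2,
                                noise_sd = 0.2,
                                baseline_mean = 10, baseline_sd = 1.5,
                                de_fraction = 0.1, de_log2fc = 1.5,
                                de_timepoints = c(12, 24), seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              timepoints = as.numeric(timepoints),
              n_replicates = as.integer(n_replicates),
              n_clusters = as.integer(n_clusters),
              gp_lengthscale = gp_lengthscale,
              gp_amplitude = gp_amplitude,
              noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              de_timepoints = as.numeric(de_timepoints),
              seed = as.integer(seed))
  validate_temporal_config(cfg)
  class(cfg) <- "temporal_sim_config"
  cfg
}

validate_temporal_config <- function(cfg) {
  if (is.unsorted(cfg$timepoints, strictly = TRUE))
    stop("configuration error: timepoints must be strictly increasing")
  if (cfg$n_clusters > cfg$n_proteins)
    stop("configuration error: more clusters than proteins")
  if (cfg$de_log2fc <= 0)
    stop("configuration error: de_log2fc must be positive")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("configuration error: de_fraction must lie in [0, 1]")
  stopifnot(cfg$n_replicates >= 1, cfg$noise_sd >= 0,
            cfg$gp_lengthscale > 0, cfg$gp_amplitude >= 0)
  invisible(cfg)
}

## Squared-exponential covariance on a time vector.
sqexp_cov <- function(t1, t2 = t1, amplitude, lengthscale) {
  D <- outer(t1, t2, "-")
  amplitude^2 * exp(-D^2 / (2 * lengthscale^2))
}

#' Generate a synthetic multi-replicate time course
#'
#' Cluster mean curves are drawn from a zero-mean squared-exponential GP on
#' the timepoints rescaled to `[0, 1]`; each protein's profile is its
#' cluster curve plus a per-protein baseline and i.i.d. Gaussian noise per
#' replicate. Differentially abundant proteins receive an additive signed
#' `de_log2fc` shift at `de_timepoints` in every replicate.
#'
#' @param config A [temporal_sim_config()].
#' @return A list with `tc` (array proteins x timepoints x replicates, log2
#'   scale), `truth_clusters` (integer vector), `truth_de` (data frame with
#'   `accession`, `true_shift` — signed log2 shift, 0 for non-DE) and
#'   `cluster_curves` (matrix clusters x timepoints, the noiseless
#'   generating curves, baseline excluded).
#' @export
generate_timecourse <- function(config) {
  validate_temporal_config(config)
  withr::with_seed(config$seed, generate_timecourse_impl(config))
}

generate_timecourse_impl <- function(cfg) {
  n <- cfg$n_proteins
  tp <- cfg$timepoints
  T_ <- length(tp)
  R <- cfg$n_replicates
  t01 <- (tp - min(tp)) / diff(range(tp))
  Kmat <- sqexp_cov(t01, amplitude = cfg$gp_amplitude,
                    lengthscale = cfg$gp_lengthscale)
  L <- chol(Kmat + diag(1e-10, T_))
  curves <- matrix(rnorm(cfg$n_clusters * T_), cfg$n_clusters) %*% L
  ## anchor each curve at 0 for t = 0 so DE shifts are interpretable
  curves <- curves - curves[, 1]

  cl <- sort(rep_len(seq_len(cfg$n_clusters), n))
  cl <- sample(cl)
  acc <- sprintf("P%05d", seq_len(n))

  n_de <- round(cfg$de_fraction * n)
  de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
  shift <- numeric(n)
  if (n_de > 0)
    shift[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * cfg$de_log2fc
  de_cols <- tp %in% cfg$de_timepoints

  baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  tc <- array(0, dim = c(n, T_, R),
              dimnames = list(acc, as.character(tp), paste0("rep", 1:R)))
  for (r in seq_len(R)) {
    noise <- matrix(rnorm(n * T_, 0, cfg$noise_sd), n, T_)
    sig <- curves[cl, , drop = FALSE] + baseline + noise
    sig[, de_cols] <- sig[, de_cols] + shift
    tc[, , r] <- sig
  }

  list(tc = tc,
       truth_clusters = cl,
       truth_de = data.frame(accession = acc, true_shift = shift,
                             stringsAsFactors = FALSE),
       cluster_curves = curves)
}
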