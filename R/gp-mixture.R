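#' Standardise temporal profiles
#'
#' Centres and scales each protein's profile over timepoints to zero mean
#' and unit variance, and rescales the timepoint axis (hours) affinely to
#' `[0, 1]`. Zero-variance profiles are centred only, with a warning.
#'
#' @param m Matrix proteins x timepoints with timepoint (hours) colnames.
#' @return Standardised matrix with attribute `"t01"`, the rescaled
#'   timepoints.
#' @export
standardise_profiles <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("at least two timepoints required")
  tp <- as.numeric(colnames(m))
  if (anyNA(tp)) stop("column names must be numeric timepoints (hours)")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " zero-variance profile(s) centred but not scaled")
    s[s == 0] <- 1
  }
  out <- (m - mu) / s
  attr(out, "t01") <- (tp - min(tp)) / diff(range(tp))
  out
}

## Eigendecomposition of the squared-exponential kernel at theta =
## (log amplitude, log length-scale, log noise sd). Values are clamped at a
## small floor so downstream solves are stable.
gp_kernel_eigen <- function(theta, t01) {
  a <- exp(theta[1]); l <- exp(theta[2])
  Kmat <- sqexp_cov(t01, amplitude = a, lengthscale = l)
  e <- eigen(Kmat, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

## Log marginal likelihood of cluster member profiles sharing one latent GP
## curve, from cached sufficient statistics. The stacked covariance
## (ones %o% ones) %x% K + sigma2 * I block-diagonalises in the member
## basis: one block sigma2*I + m*K for the averaged direction and m - 1
## noise-only blocks.
gp_marginal_stats <- function(m, S1q, ssq, S1_norm2, sigma2, lambda) {
  if (m == 0) return(0)
  T_ <- length(lambda)
  v <- sigma2 + m * lambda
  quad <- sum(S1q^2 / v) / m + (ssq - S1_norm2 / m) / sigma2
  logdet <- sum(log(v)) + (m - 1) * T_ * log(sigma2)
  -0.5 * (m * T_ * log(2 * pi) + logdet + quad)
}

#' Log marginal likelihood of a GP cluster
#'
#' The joint log density of `m` member profiles under a shared latent
#' function drawn from a zero-mean GP with squared-exponential kernel
#' `k(t, t') = a^2 exp(-(t - t')^2 / (2 l^2))` plus i.i.d. Gaussian noise
#' with standard deviation `sigma` — the component model of the temporal
#' mixture, in which co-regulated proteins share one underlying curve.
#'
#' @param Y Matrix members x timepoints (standardised profiles).
#' @param theta Numeric vector `(log a, log l, log sigma)`.
#' @param t01 Timepoints rescaled to `[0, 1]`
#'   (defaults to attribute `"t01"` of `Y`).
#' @return Log marginal likelihood (scalar).
#' @export
gp_cluster_marginal <- function(Y, theta, t01 = attr(Y, "t01")) {
  force(t01)
  Y <- rbind(Y)
  if (is.null(t01)) stop("timepoints required (t01)")
  e <- gp_kernel_eigen(theta, t01)
  S1 <- colSums(Y)
  gp_marginal_stats(nrow(Y), crossprod(e$vectors, S1), sum(Y^2),
                    sum(S1^2), exp(2 * theta[3]), e$values)
}

#' Configuration of the Dirichlet-process GP mixture sampler
#'
#' @param n_iter Gibbs sweeps (default 2000).
#' @param burn_in Burn-in sweeps (default 40% of `n_iter`).
#' @param thin Thinning interval for recorded partitions (default 5).
#' @param n_aux Auxiliary (empty) components offered at each allocation
#'   update (Neal's algorithm 8; default 3).
#' @param step Metropolis random-walk step on each log-hyperparameter
#'   (default 0.1).
#' @param alpha_shape,alpha_rate Gamma prior on the Dirichlet-process mass
#'   parameter (default shape 2, rate 4).
#' @param init_clusters Number of clusters in the random initial partition.
#' @param seed Integer seed; the sampler is deterministic given the seed.
#' @return A `gp_mixture_config` list.
#' @export
gp_mixture_config <- function(n_iter = 2000, burn_in = round(0.4 * n_iter),
                              thin = 5, n_aux = 3, step = 0.1,
                              alpha_shape = 2, alpha_rate = 4,
                              init_clusters = 8, seed = 1L) {
  stopifnot(n_aux >= 1, n_iter > burn_in, thin >= 1, step > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_aux = as.integer(n_aux),
                 step = step, alpha_shape = alpha_shape,
                 alpha_rate = alpha_rate,
                 init_clusters = as.integer(init_clusters),
                 seed = as.integer(seed)),
            class = "gp_mixture_config")
}

#' Fit a Dirichlet-process mixture of GP regression models
#'
#' Bayesian nonparametric clustering of standardised temporal profiles.
#' Each mixture component is a shared latent GP curve with squared-
#' exponential kernel plus i.i.d. noise; standard normal priors are placed
#' on the log of each kernel hyperparameter. Allocations are sampled by
#' Gibbs with auxiliary components (Neal's algorithm 8), per-cluster
#' hyperparameters by Metropolis random walks, and the Dirichlet-process
#' mass parameter by the usual Beta augmentation under its Gamma prior.
#' The number of clusters is thereby inferred rather than fixed.
#'
#' @param profiles Standardised profile matrix from
#'   [standardise_profiles()].
#' @param config A [gp_mixture_config()].
#' @return A `gp_partition_samples` object: `partitions` (samples x
#'   proteins integer matrix, canonical labels), `k_trace` and
#'   `alpha_trace` (per sweep), `accessions`, `t01` and `meta`.
#' @export
fit_gp_mixture <- function(profiles, config = gp_mixture_config()) {
  withr::with_seed(config$seed, fit_gp_mixture_impl(profiles, config))
}

fit_gp_mixture_impl <- function(Y, cfg) {
  t01 <- attr(Y, "t01")
  if (is.null(t01)) stop("profiles must come from standardise_profiles()")
  n <- nrow(Y)
  T_ <- ncol(Y)
  y_norm2 <- rowSums(Y^2)

  new_cluster <- function(theta) {
    e <- gp_kernel_eigen(theta, t01)
    list(theta = theta, Q = e$vectors, lambda = e$values,
         sigma2 = exp(2 * theta[3]),
         m = 0L, S1 = numeric(T_), S1q = numeric(T_), ssq = 0)
  }
  clus_marg <- function(cl) {
    gp_marginal_stats(cl$m, cl$S1q, cl$ssq, sum(cl$S1^2), cl$sigma2,
                      cl$lambda)
  }
  add_member <- function(cl, i) {
    cl$m <- cl$m + 1L
    cl$S1 <- cl$S1 + Y[i, ]
    cl$S1q <- cl$S1q + crossprod(cl$Q, Y[i, ])[, 1]
    cl$ssq <- cl$ssq + y_norm2[i]
    cl
  }
  drop_member <- function(cl, i) {
    cl$m <- cl$m - 1L
    cl$S1 <- cl$S1 - Y[i, ]
    cl$S1q <- cl$S1q - crossprod(cl$Q, Y[i, ])[, 1]
    cl$ssq <- cl$ssq - y_norm2[i]
    cl
  }
  ## predictive log weight of adding protein i to cluster cl
  pred_logw <- function(cl, i) {
    yq <- crossprod(cl$Q, Y[i, ])[, 1]
    m1 <- cl$m + 1L
    v <- cl$sigma2 + m1 * cl$lambda
    S1q_new <- cl$S1q + yq
    quad_new <- sum(S1q_new^2 / v) / m1 +
      (cl$ssq + y_norm2[i] - (sum((cl$S1 + Y[i, ])^2)) / m1) / cl$sigma2
    logdet_new <- sum(log(v)) + (m1 - 1) * T_ * log(cl$sigma2)
    new_marg <- -0.5 * (m1 * T_ * log(2 * pi) + logdet_new + quad_new)
    new_marg - clus_marg(cl)
  }

  ## random initial partition
  z <- sample(rep_len(seq_len(min(cfg$init_clusters, n)), n))
  z <- match(z, unique(z))
  clusters <- lapply(seq_len(max(z)), function(c0) {
    cl <- new_cluster(rnorm(3))
    for (i in which(z == c0)) cl <- add_member(cl, i)
    cl
  })
  alpha <- rgamma(1, cfg$alpha_shape, cfg$alpha_rate) + 0.1

  n_keep <- (cfg$n_iter - cfg$burn_in) %/% cfg$thin
  partitions <- matrix(0L, n_keep, n)
  k_trace <- numeric(cfg$n_iter)
  alpha_trace <- numeric(cfg$n_iter)
  stored <- 0L

  ## Persistent pool of empty (auxiliary) components: refreshed from the
  ## prior once per sweep and whenever a slot is consumed or recycled.
  ## Their full conditional given zero members is the prior, so lazy
  ## refreshing keeps the chain's stationary distribution intact while
  ## avoiding a fresh kernel eigendecomposition per protein update.
  aux <- lapply(seq_len(cfg$n_aux), function(j) new_cluster(rnorm(3)))

  for (iter in seq_len(cfg$n_iter)) {
    for (j in seq_len(cfg$n_aux)) aux[[j]] <- new_cluster(rnorm(3))
    for (i in seq_len(n)) {
      ci <- z[i]
      clusters[[ci]] <- drop_member(clusters[[ci]], i)
      if (clusters[[ci]]$m == 0L) {
        ## vacated singleton: recycle its parameters into an aux slot
        aux[[1L]] <- clusters[[ci]]
        clusters[[ci]] <- NULL
        z[z > ci] <- z[z > ci] - 1L
        z[i] <- 0L
      }
      C <- length(clusters)
      logw <- numeric(C + cfg$n_aux)
      for (c0 in seq_len(C))
        logw[c0] <- log(clusters[[c0]]$m) + pred_logw(clusters[[c0]], i)
      for (j in seq_len(cfg$n_aux))
        logw[C + j] <- log(alpha / cfg$n_aux) + pred_logw(aux[[j]], i)
      w <- exp(logw - max(logw))
      pick <- sample.int(C + cfg$n_aux, 1L, prob = w)
      if (pick <= C) {
        clusters[[pick]] <- add_member(clusters[[pick]], i)
        z[i] <- pick
      } else {
        clusters[[C + 1L]] <- add_member(aux[[pick - C]], i)
        z[i] <- C + 1L
        aux[[pick - C]] <- new_cluster(rnorm(3))
      }
    }

    ## Metropolis update of each cluster's kernel hyperparameters under
    ## independent standard normal priors on the log scale
    for (c0 in seq_along(clusters)) {
      cl <- clusters[[c0]]
      prop <- cl$theta + rnorm(3, 0, cfg$step)
      cl_new <- new_cluster(prop)
      cl_new$m <- cl$m; cl_new$S1 <- cl$S1; cl_new$ssq <- cl$ssq
      cl_new$S1q <- crossprod(cl_new$Q, cl$S1)[, 1]
      log_acc <- (clus_marg(cl_new) - clus_marg(cl)) +
        sum(dnorm(prop, log = TRUE)) - sum(dnorm(cl$theta, log = TRUE))
      if (log(runif(1)) < log_acc) clusters[[c0]] <- cl_new
    }

    ## Dirichlet-process mass parameter (Beta augmentation, Gamma prior)
    Kn <- length(clusters)
    eta <- rbeta(1, alpha + 1, n)
    odds <- (cfg$alpha_shape + Kn - 1) /
      (n * (cfg$alpha_rate - log(eta)))
    sh <- cfg$alpha_shape + Kn - (runif(1) >= odds / (1 + odds))
    alpha <- rgamma(1, sh, cfg$alpha_rate - log(eta))

    k_trace[iter] <- Kn
    alpha_trace[iter] <- alpha
    if (iter > cfg$burn_in && (iter - cfg$burn_in) %% cfg$thin == 0 &&
        stored < n_keep) {
      stored <- stored + 1L
      partitions[stored, ] <- match(z, unique(z))
    }
  }

  structure(list(partitions = partitions, k_trace = k_trace,
                 alpha_trace = alpha_trace,
                 accessions = rownames(Y), t01 = t01,
                 meta = cfg),
            class = "gp_partition_samples")
}

#' @export
print.gp_partition_samples <- function(x, ...) {
  cat("DP-GP mixture samples:", nrow(x$partitions), "partitions of",
      ncol(x$partitions), "proteins; posterior K mode =",
      as.integer(names(which.max(table(
        x$k_trace[(x$meta$burn_in + 1):x$meta$n_iter])))), "\n")
  invisible(x)
}
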