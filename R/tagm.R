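#' Empirical default priors for the TAGM classifier
#'
#' Fills the Normal-inverse-Wishart and outlier hyperparameters from the
#' data: the prior mean is the global mean profile; the prior scale matrix
#' is the diagonal of the empirical covariance divided by `K^(2/d)` (a
#' per-component share of the total spread); the outlier t component is
#' centred on the global mean with dispersion half the empirical covariance
#' and 4 degrees of freedom. These are weakly informative defaults intended
#' to let the marker data dominate.
#'
#' @param profiles Sum-normalised profile matrix (proteins x channels).
#' @param markers A [marker_map()]; every compartment needs at least two
#'   markers present in `profiles`.
#' @return A `tagm_priors` list with elements `beta0`, `lambda0` (0.01),
#'   `nu0` (`d + 2`), `S0`, `alpha` (1), `u`, `v` (Beta(2, 10) outlier
#'   weight prior), `kappa` (4), `M`, `V`.
#' @export
default_priors <- function(profiles, markers) {
  d <- ncol(profiles)
  K <- length(attr(markers, "schema"))
  present <- markers$accession %in% rownames(profiles)
  tab <- table(factor(markers$compartment[present],
                      levels = attr(markers, "schema")))
  if (any(tab < 2))
    stop("compartment(s) with fewer than 2 markers: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  emp_cov <- stats::cov(profiles)
  V <- emp_cov / 2
  diag(V) <- diag(V) + max(1e-8, 1e-6 * mean(diag(V)))  # ensure SPD
  structure(list(beta0 = colMeans(profiles),
                 lambda0 = 0.01,
                 nu0 = d + 2,
                 S0 = diag(diag(emp_cov), d) / K^(2 / d),
                 alpha = 1,
                 u = 2, v = 10,
                 kappa = 4,
                 M = colMeans(profiles),
                 V = V),
            class = "tagm_priors")
}

## Multivariate t log density (scale parameterisation).
mvt_logpdf_r <- function(x, mu, Sigma, df) {
  d <- length(x)
  R <- chol(Sigma)
  z <- backsolve(R, x - mu, transpose = TRUE)
  lgamma((df + d) / 2) - lgamma(df / 2) - d / 2 * log(df * pi) -
    sum(log(diag(R))) - (df + d) / 2 * log1p(sum(z * z) / df)
}

## Per-compartment sufficient statistics (count, mean, scatter).
collapsed_class_stats <- function(X, labels, schema) {
  lapply(schema, function(sc) {
    Xi <- X[labels == sc, , drop = FALSE]
    if (nrow(Xi) == 0)
      return(list(n = 0, xbar = numeric(ncol(X)),
                  S = matrix(0, ncol(X), ncol(X))))
    xb <- colMeans(Xi)
    list(n = nrow(Xi), xbar = xb, S = crossprod(sweep(Xi, 2, xb)))
  })
}

## Collapsed posterior over (compartment 1..K, outlier K+1) for one point,
## conditioning on fixed component statistics and outlier weight eps.
collapsed_posterior_probs <- function(x, stats, priors, eps) {
  d <- length(x)
  K <- length(stats)
  n_in <- sum(vapply(stats, `[[`, numeric(1), "n"))
  lw <- vapply(seq_len(K), function(k) {
    st <- stats[[k]]
    ln <- priors$lambda0 + st$n
    nun <- priors$nu0 + st$n
    mn <- (priors$lambda0 * priors$beta0 + st$n * st$xbar) / ln
    Sn <- priors$S0 + st$S +
      (priors$lambda0 * st$n / ln) * tcrossprod(st$xbar - priors$beta0)
    df <- nun - d + 1
    log1p(-eps) + log(st$n + priors$alpha) -
      log(n_in + K * priors$alpha) +
      mvt_logpdf_r(x, mn, Sn * (ln + 1) / (ln * df), df)
  }, numeric(1))
  lo <- log(eps) + mvt_logpdf_r(x, priors$M, priors$V, priors$kappa)
  w <- exp(c(lw, lo) - max(c(lw, lo)))
  w / sum(w)
}

#' Fit the TAGM classifier by collapsed Gibbs MCMC
#'
#' Runs independent MCMC chains of the semi-supervised T-augmented Gaussian
#' mixture: marker proteins are clamped to their compartment, unlabelled
#' proteins have their compartment allocation and outlier indicator sampled
#' jointly from the collapsed model (multivariate-t predictive per
#' compartment, fixed multivariate-t outlier component). Chains are run
#' sequentially with seeds `seed`, `seed + 1`, ...; the fit is deterministic
#' given `seed`.
#'
#' @param profiles Complete, sum-normalised profile matrix with accession
#'   rownames.
#' @param markers A [marker_map()]; all marker accessions must be rows of
#'   `profiles`.
#' @param priors A `tagm_priors` list; defaults to
#'   [default_priors()] on the data.
#' @param n_chains,n_iter Number of chains and iterations per chain.
#' @param burn_in Burn-in iterations (default 40% of `n_iter`).
#' @param thin Thinning interval (default 5).
#' @param seed Integer seed.
#' @return A `tagm_chains` object.
#' @export
fit_tagm_mcmc <- function(profiles, markers, priors = NULL,
                          n_chains = 4, n_iter = 2000,
                          burn_in = round(0.4 * n_iter), thin = 5,
                          seed = 1L) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles)) stop("profiles must be complete (no missing values)")
  schema <- attr(markers, "schema")
  if (!all(markers$accession %in% rownames(profiles)))
    stop("marker accessions absent from the profile matrix")
  if (is.null(priors)) priors <- default_priors(profiles, markers)
  marker_z <- integer(nrow(profiles))
  idx <- match(markers$accession, rownames(profiles))
  marker_z[idx] <- match(markers$compartment, schema)

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- withr::with_seed(as.integer(seed) + ch - 1L, {
      .tagm_gibbs(profiles, marker_z, length(schema),
                  priors$beta0, priors$lambda0, priors$nu0, priors$S0,
                  priors$alpha, priors$u, priors$v,
                  priors$kappa, priors$M, priors$V,
                  as.integer(n_iter), as.integer(burn_in), as.integer(thin))
    })
    if (isTRUE(chains[[ch]]$jittered))
      warning("chain ", ch, ": singular sufficient statistics, ",
              "scale matrix jittered by 1e-8")
  }
  structure(list(chains = chains,
                 accessions = rownames(profiles),
                 unknown = rownames(profiles)[marker_z == 0],
                 marker_z = marker_z,
                 schema = schema,
                 priors = priors,
                 meta = list(n_chains = n_chains, n_iter = n_iter,
                             burn_in = burn_in, thin = thin, seed = seed)),
            class = "tagm_chains")
}

#' @export
print.tagm_chains <- function(x, ...) {
  cat("TAGM MCMC fit:", length(x$chains), "chains,",
      x$meta$n_iter, "iterations (burn-in", x$meta$burn_in,
      ", thin", x$meta$thin, ")\n")
  cat(length(x$accessions), "proteins (", length(x$unknown),
      "unlabelled ),", length(x$schema), "compartments\n")
  invisible(x)
}

#' Assess chain convergence and select the best chains
#'
#' Computes the Gelman-Rubin potential scale reduction factor (PSRF) on the
#' outlier-count trace over all chains, then searches all subsets of
#' `n_keep` chains for the one minimising the pooled PSRF (ties broken by
#' the highest mean log joint density). Convergent runs should give PSRF
#' below 1.2.
#'
#' @param fit A `tagm_chains` object with at least two chains.
#' @param n_keep Number of chains to retain (default 3, capped at the
#'   number of chains).
#' @return List with `psrf` (PSRF over all chains), `retained` (indices of
#'   the kept chains) and `psrf_retained`.
#' @export
assess_convergence <- function(fit, n_keep = 3) {
  n_chains <- length(fit$chains)
  if (n_chains < 2) stop("convergence diagnostic requires at least 2 chains")
  traces <- lapply(fit$chains, function(ch) as.numeric(ch$n_outlier))
  lens <- vapply(traces, length, integer(1))
  if (length(unique(lens)) != 1L) stop("chains have unequal sample counts")
  psrf_all <- gelman_rubin(traces)
  n_keep <- min(n_keep, n_chains)
  if (n_keep < 2) {
    retained <- which.max(vapply(fit$chains,
                                 function(ch) mean(ch$log_joint), numeric(1)))
    return(list(psrf = psrf_all, retained = retained, psrf_retained = NA_real_))
  }
  subsets <- combn(n_chains, n_keep)
  scores <- apply(subsets, 2, function(s) gelman_rubin(traces[s]))
  best <- which(scores <= min(scores) + 1e-12)
  if (length(best) > 1) {
    mlj <- apply(subsets[, best, drop = FALSE], 2, function(s)
      mean(vapply(fit$chains[s], function(ch) mean(ch$log_joint), numeric(1))))
    best <- best[which.max(mlj)]
  } else best <- best[1]
  list(psrf = psrf_all, retained = subsets[, best],
       psrf_retained = scores[best])
}

#' Pool posterior allocation samples across retained chains
#'
#' For each protein, the joint posterior probability of compartment `k` is
#' the fraction of pooled samples allocating it to `k` while in the mixture
#' (`phi = 1`); the outlier probability is the fraction of samples with
#' `phi = 0`. Markers are clamped: probability one on their compartment.
#'
#' @param fit A `tagm_chains` object.
#' @param retained Indices of chains to pool (default: the subset chosen by
#'   [assess_convergence()]).
#' @return A `tagm_posterior` object: list with `pi` (proteins x
#'   compartments matrix of joint posterior probabilities), `outlier`
#'   (named vector), and `schema`. Rows satisfy
#'   `rowSums(pi) + outlier == 1`.
#' @export
pool_posteriors <- function(fit, retained = NULL) {
  if (is.null(retained)) retained <- assess_convergence(fit)$retained
  K <- length(fit$schema)
  n <- length(fit$accessions)
  Z <- do.call(rbind, lapply(fit$chains[retained], function(ch) ch$z))
  Phi <- do.call(rbind, lapply(fit$chains[retained], function(ch) ch$phi))
  n_samp <- nrow(Z)
  pi_mat <- matrix(0, n, K, dimnames = list(fit$accessions, fit$schema))
  outlier <- setNames(numeric(n), fit$accessions)
  unk <- which(fit$marker_z == 0)
  for (j in seq_along(unk)) {
    zin <- Z[, j][Phi[, j] == 1]
    pi_mat[unk[j], ] <- tabulate(zin, nbins = K) / n_samp
    outlier[unk[j]] <- mean(Phi[, j] == 0)
  }
  mk <- which(fit$marker_z > 0)
  pi_mat[cbind(mk, fit$marker_z[mk])] <- 1
  structure(list(pi = pi_mat, outlier = outlier, schema = fit$schema,
                 retained = retained, n_samples = n_samp),
            class = "tagm_posterior")
}

#' @export
print.tagm_posterior <- function(x, ...) {
  cat("TAGM posterior:", nrow(x$pi), "proteins x", ncol(x$pi),
      "compartments, pooled from", length(x$retained), "chains (",
      x$n_samples, "samples )\n")
  invisible(x)
}

#' Allocate proteins to compartments from pooled posteriors
#'
#' A protein is assigned to its maximum a posteriori compartment only when
#' the joint posterior probability exceeds `p_threshold` (strictly) and the
#' outlier probability is below `outlier_threshold` (strictly); otherwise
#' it is reported as `"unknown"`. The defaults reproduce the conservative
#' rule of assigning only when the posterior exceeds 0.999 with outlier
#' probability under 1e-6.
#'
#' @param posterior A `tagm_posterior` object.
#' @param p_threshold Joint posterior probability threshold (strict `>`).
#' @param outlier_threshold Outlier probability bound (strict `<`).
#' @return Data frame with columns `accession`, `best_label`, `best_prob`,
#'   `outlier_prob`, `label` (compartment or `"unknown"`).
#' @export
allocate <- function(posterior, p_threshold = 0.999,
                     outlier_threshold = 1e-6) {
  best <- max.col(posterior$pi, ties.method = "first")
  best_prob <- posterior$pi[cbind(seq_len(nrow(posterior$pi)), best)]
  label <- ifelse(best_prob > p_threshold &
                    posterior$outlier < outlier_threshold,
                  posterior$schema[best], "unknown")
  data.frame(accession = rownames(posterior$pi),
             best_label = posterior$schema[best],
             best_prob = best_prob,
             outlier_prob = unname(posterior$outlier),
             label = label,
             stringsAsFactors = FALSE)
}

#' One-call TAGM classification
#'
#' Convenience wrapper: fit chains, select the best subset by the
#' Gelman-Rubin diagnostic, pool them, and allocate.
#'
#' @inheritParams fit_tagm_mcmc
#' @param n_keep Chains retained after convergence assessment.
#' @inheritParams allocate
#' @return List with `fit`, `convergence`, `posterior` and `allocation`.
#' @export
tagm_classify <- function(profiles, markers, priors = NULL, n_chains = 4,
                          n_iter = 2000, burn_in = round(0.4 * n_iter),
                          thin = 5, n_keep = 3, seed = 1L,
                          p_threshold = 0.999, outlier_threshold = 1e-6) {
  fit <- fit_tagm_mcmc(profiles, markers, priors, n_chains, n_iter,
                       burn_in, thin, seed)
  conv <- assess_convergence(fit, n_keep)
  post <- pool_posteriors(fit, conv$retained)
  list(fit = fit, convergence = conv, posterior = post,
       allocation = allocate(post, p_threshold, outlier_threshold))
}
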