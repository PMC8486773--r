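#' Configuration for the synthetic spatial-profile generator
#'
#' Describes a two-condition subcellular fractionation experiment: a number
#' of compartment classes with distinct mean fractionation profiles on the
#' unit simplex, marker proteins of known class, unlabelled proteins, a
#' heavy-tailed outlier fraction, and planted between-condition
#' translocation ("mover") events of four types.
#'
#' Class mean profiles are softmax-transformed Gaussian bumps centred at
#' distinct channel positions, mimicking the single-peaked density-gradient
#' shapes of organelle fractionation profiles; `class_separation` scales the
#' bump height (larger values give more distinct compartments). Outliers are
#' drawn from a multivariate t with 4 degrees of freedom about the global
#' profile centroid, matching the outlier component the downstream
#' classifier assumes. Type-4 movers are placed at the midpoint of two
#' compartment mean profiles (maximal between-compartment ambiguity), with a
#' disjoint compartment pair in the second condition.
#'
#' @param n_classes Number of compartments (default 11).
#' @param n_channels Fraction channels per condition (default 19, emulating
#'   two interleaved 10-plexes with one channel removed).
#' @param n_markers_per_class Markers per compartment.
#' @param n_unknown Number of unlabelled proteins.
#' @param outlier_fraction Proportion of the unlabelled proteins drawn from
#'   the heavy-tailed outlier component, in `[0, 1]`.
#' @param class_separation Positive scalar; height of the pre-softmax bump.
#' @param within_class_sd Channel-wise standard deviation of member profiles
#'   about their class mean (on the simplex scale).
#' @param outlier_scale Outlier dispersion, as a multiple of
#'   `within_class_sd`.
#' @param type4_radius Fallback displacement of type-4 boundary-shell
#'   profiles from their anchor compartment mean, in units of
#'   `within_class_sd`, used when per-pair numerical calibration fails.
#' @param mover_counts Named integer vector with names `"1"`..`"4"`: planted
#'   movers of each translocation type.
#' @param seed Integer seed; the generator uses its own stream and leaves
#'   the global RNG state untouched.
#' @return A `spatial_sim_config` list.
#' @export
spatial_sim_config <- function(n_classes = 11, n_channels = 19,
                               n_markers_per_class = 20, n_unknown = 280,
                               outlier_fraction = 0.08, class_separation = 4,
                               within_class_sd = 0.015, outlier_scale = 5,
                               type4_radius = 9,
                               mover_counts = c("1" = 12, "2" = 12,
                                                "3" = 12, "4" = 12),
                               seed = 1L) {
  mv <- setNames(rep(0L, 4), as.character(1:4))
  if (length(mover_counts)) {
    if (is.null(names(mover_counts)))
      names(mover_counts) <- as.character(seq_along(mover_counts))
    mv[names(mover_counts)] <- as.integer(mover_counts)
  }
  cfg <- list(n_classes = as.integer(n_classes),
              n_channels = as.integer(n_channels),
              n_markers_per_class = as.integer(n_markers_per_class),
              n_unknown = as.integer(n_unknown),
              outlier_fraction = outlier_fraction,
              class_separation = class_separation,
              within_class_sd = within_class_sd,
              outlier_scale = outlier_scale,
              type4_radius = type4_radius,
              mover_counts = mv,
              seed = as.integer(seed))
  validate_spatial_config(cfg)
  class(cfg) <- "spatial_sim_config"
  cfg
}

validate_spatial_config <- function(cfg) {
  stopifnot(cfg$n_classes >= 2, cfg$n_channels >= 2,
            cfg$n_markers_per_class >= 0, cfg$n_unknown >= 0)
  if (cfg$outlier_fraction < 0 || cfg$outlier_fraction > 1)
    stop("configuration error: outlier_fraction must lie in [0, 1]")
  if (cfg$class_separation <= 0 || cfg$within_class_sd <= 0)
    stop("configuration error: separation and spread must be positive")
  if (any(cfg$mover_counts < 0))
    stop("configuration error: mover counts must be non-negative")
  n_movers <- sum(cfg$mover_counts)
  n_out <- round(cfg$outlier_fraction * cfg$n_unknown)
  if (n_movers + n_out > cfg$n_unknown)
    stop("configuration error: movers plus outliers exceed n_unknown")
  if (cfg$mover_counts["4"] > 0 && cfg$n_classes < 4)
    stop("configuration error: type-4 movers need at least 4 classes")
  invisible(cfg)
}

## Softmax-bump class mean profiles: one Gaussian bump per class, centred at
## evenly spaced channel positions, pushed through softmax onto the simplex.
class_mean_profiles <- function(n_classes, n_channels, separation) {
  pos <- seq_len(n_channels)
  centres <- (seq_len(n_classes) - 0.5) * n_channels / n_classes
  width <- n_channels / (2 * n_classes)
  means <- t(vapply(centres, function(cc) {
    z <- separation * exp(-(pos - cc)^2 / (2 * width^2))
    ez <- exp(z - max(z))
    ez / sum(ez)
  }, numeric(n_channels)))
  means
}

## Draw a single profile: base + channel-wise Gaussian noise, renormalised
## back onto the simplex. The noise sd is capped at a third of the channel
## mean so that near-empty channels (organelle absent from those fractions)
## stay near-empty and zero-clipping stays negligible, keeping the
## empirical class means unbiased for the generating means.
draw_profile <- function(base, sd) {
  p <- pmax(base + rnorm(length(base), 0, pmin(sd, base / 3)), 1e-8)
  p / sum(p)
}

draw_outlier_profile <- function(centre, scale) {
  p <- pmax(centre + scale * rt(length(centre), df = 4), 1e-8)
  p / sum(p)
}

## A deterministic profile on the classification boundary shell of
## compartment pair[1]: the class mean displaced by `radius` toward
## pair[2]. Far enough out that confident allocation fails, close enough
## that the compartment still dominates the posterior.
shell_profile <- function(means, pair, radius) {
  u <- means[pair[2], ] - means[pair[1], ]
  u <- u / sqrt(sum(u^2))
  p <- pmax(means[pair[1], ] + radius * u, 1e-8)
  p / sum(p)
}

## Root-find the shell radius (in units of the within-class sd) at which
## the collapsed posterior assigns the outlier component log-odds of -3
## (about 5%). Falls back to `fallback` when no root is bracketed.
calibrate_shell_radius <- function(means, pair, sd, stats, priors, eps,
                                   fallback, target_logodds = -3) {
  f <- function(r) {
    p <- collapsed_posterior_probs(shell_profile(means, pair, r * sd),
                                   stats, priors, eps)
    pk <- p[length(p)]
    log(pk) - log1p(-pk) - target_logodds
  }
  out <- tryCatch(uniroot(f, c(3, 30), tol = 0.01)$root,
                  error = function(e) fallback)
  out
}

#' Generate a paired two-condition spatial proteomics dataset
#'
#' Simulates protein-by-channel relative-abundance matrices for two
#' conditions sharing a protein index, a curated marker list, and a ground
#' truth record of compartment membership and planted translocation events.
#'
#' Mover types follow the translocation typology: type 1 proteins belong to
#' one compartment in condition A and a different one in condition B; type 2
#' are unassignable (outlier-like) in A and compartment members in B; type 3
#' the reverse; type 4 sit on the classification boundary shell of one
#' compartment in each condition — displaced from the compartment mean far
#' enough that confident allocation fails while most posterior mass stays
#' compartmental — with a different anchor compartment per condition, so the
#' posterior distribution shifts strongly between conditions although the
#' protein is unassignable in both.
#'
#' @param config A [spatial_sim_config()].
#' @return A list with elements `expr_a`, `expr_b` (matrices, rows sum to 1),
#'   `markers` (a [marker_map()]) and `truth` (data frame with columns
#'   `accession`, `true_label_A`, `true_label_B`, `true_mover_type`). The
#'   generating class mean profiles are attached as attribute
#'   `"class_means"`.
#' @export
generate_spatial_pair <- function(config) {
  validate_spatial_config(config)
  withr::with_seed(config$seed, generate_spatial_pair_impl(config))
}

generate_spatial_pair_impl <- function(cfg) {
  K <- cfg$n_classes
  d <- cfg$n_channels
  schema <- if (K == 11) lopit_compartments() else sprintf("class_%02d", 1:K)
  means <- class_mean_profiles(K, d, cfg$class_separation)
  rownames(means) <- schema
  centroid <- colMeans(means)
  sd <- cfg$within_class_sd
  out_scale <- cfg$outlier_scale * sd

  n_markers <- K * cfg$n_markers_per_class
  n_total <- n_markers + cfg$n_unknown
  acc <- sprintf("P%05d", seq_len(n_total))

  ## roles for the unlabelled proteins
  n_mv <- cfg$mover_counts
  n_out <- round(cfg$outlier_fraction * cfg$n_unknown)
  roles <- c(rep("m1", n_mv["1"]), rep("m2", n_mv["2"]),
             rep("m3", n_mv["3"]), rep("m4", n_mv["4"]),
             rep("outlier", n_out))
  roles <- c(roles, rep("member", cfg$n_unknown - length(roles)))
  roles <- sample(roles)

  expr_a <- matrix(0, n_total, d, dimnames = list(acc, sprintf("F%02d", 1:d)))
  expr_b <- expr_a
  truth <- data.frame(accession = acc,
                      true_label_A = NA_character_,
                      true_label_B = NA_character_,
                      true_mover_type = 0L,
                      stringsAsFactors = FALSE)

  marker_class <- rep(seq_len(K), each = cfg$n_markers_per_class)
  for (i in seq_len(n_markers)) {
    k <- marker_class[i]
    expr_a[i, ] <- draw_profile(means[k, ], sd)
    expr_b[i, ] <- draw_profile(means[k, ], sd)
    truth$true_label_A[i] <- schema[k]
    truth$true_label_B[i] <- schema[k]
  }

  rand_class <- function(excl = integer(0)) {
    pool <- setdiff(seq_len(K), excl)
    pool[sample.int(length(pool), 1L)]
  }
  ## Ordered adjacent (anchor, direction) compartment pairs for type-4
  ## boundary-shell planting. Each planted type-4 protein gets a distinct
  ## ordered pair per condition (anchor switching between conditions), so
  ## no two shell profiles coincide and none can prop up a component.
  n4 <- cfg$mover_counts["4"]
  if (n4 > 0) {
    op <- rbind(cbind(1:(K - 1), 2:K), cbind(2:K, 1:(K - 1)))
    a_sel <- op[sample.int(nrow(op), n4, replace = n4 > nrow(op)), ,
                drop = FALSE]
    b_sel <- matrix(0L, n4, 2)
    avail <- seq_len(nrow(op))
    for (q in seq_len(n4)) {
      ok <- avail[op[avail, 1] != a_sel[q, 1]]
      if (!length(ok)) ok <- which(op[, 1] != a_sel[q, 1])
      pick <- ok[sample.int(length(ok), 1L)]
      b_sel[q, ] <- op[pick, ]
      avail <- setdiff(avail, pick)
    }
    q4 <- 0L
    idx4 <- integer(n4)
  }

  for (j in seq_len(cfg$n_unknown)) {
    i <- n_markers + j
    role <- roles[j]
    if (role == "member") {
      k <- rand_class()
      expr_a[i, ] <- draw_profile(means[k, ], sd)
      expr_b[i, ] <- draw_profile(means[k, ], sd)
      truth$true_label_A[i] <- schema[k]
      truth$true_label_B[i] <- schema[k]
    } else if (role == "outlier") {
      expr_a[i, ] <- draw_outlier_profile(centroid, out_scale)
      expr_b[i, ] <- draw_outlier_profile(centroid, out_scale)
      truth$true_label_A[i] <- "outlier"
      truth$true_label_B[i] <- "outlier"
    } else if (role == "m1") {
      ka <- rand_class(); kb <- rand_class(excl = ka)
      expr_a[i, ] <- draw_profile(means[ka, ], sd)
      expr_b[i, ] <- draw_profile(means[kb, ], sd)
      truth$true_label_A[i] <- schema[ka]
      truth$true_label_B[i] <- schema[kb]
      truth$true_mover_type[i] <- 1L
    } else if (role == "m2") {
      kb <- rand_class()
      expr_a[i, ] <- draw_outlier_profile(centroid, out_scale)
      expr_b[i, ] <- draw_profile(means[kb, ], sd)
      truth$true_label_A[i] <- "unassigned"
      truth$true_label_B[i] <- schema[kb]
      truth$true_mover_type[i] <- 2L
    } else if (role == "m3") {
      ka <- rand_class()
      expr_a[i, ] <- draw_profile(means[ka, ], sd)
      expr_b[i, ] <- draw_outlier_profile(centroid, out_scale)
      truth$true_label_A[i] <- schema[ka]
      truth$true_label_B[i] <- "unassigned"
      truth$true_mover_type[i] <- 3L
    } else { # m4: boundary-shell profiles, filled in a second pass below
      q4 <- q4 + 1L
      idx4[q4] <- i
      truth$true_label_A[i] <- "unassigned"
      truth$true_label_B[i] <- "unassigned"
      truth$true_mover_type[i] <- 4L
    }
  }

  markers <- marker_map(acc[seq_len(n_markers)], schema[marker_class],
                        schema = schema)

  ## Second pass: type-4 boundary-shell profiles. The displacement radius
  ## is calibrated per ordered compartment pair and per condition so that
  ## the collapsed posterior at the planted point gives the outlier
  ## component a few percent - outside the confident-allocation region but
  ## with nearly all mass still on the anchor compartment.
  if (n4 > 0) {
    rest <- setdiff(seq_len(n_total), idx4)
    for (cond in c("A", "B")) {
      X <- if (cond == "A") expr_a else expr_b
      labels <- truth[[paste0("true_label_", cond)]]
      priors <- default_priors(X[rest, , drop = FALSE], markers)
      stats <- collapsed_class_stats(X[rest, , drop = FALSE], labels[rest],
                                     schema)
      n_amb <- n_out + n_mv[if (cond == "A") "2" else "3"]
      eps <- max(0.02, n_amb / n_total)
      sel <- if (cond == "A") a_sel else b_sel
      for (q in seq_len(n4)) {
        r <- calibrate_shell_radius(means, sel[q, ], sd, stats, priors,
                                    eps, fallback = cfg$type4_radius)
        X[idx4[q], ] <- shell_profile(means, sel[q, ], r * sd)
      }
      if (cond == "A") expr_a <- X else expr_b <- X
    }
  }
  attr(expr_a, "condition") <- "A"
  attr(expr_b, "condition") <- "B"
  res <- list(expr_a = expr_a, expr_b = expr_b,
              markers = markers, truth = truth)
  attr(res, "class_means") <- means
  res
}
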