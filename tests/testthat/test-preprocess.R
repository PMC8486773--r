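make_psm_row <- function(ii = 10, sn = 50, ion = 60, rank = 1L,
                         ser = 1L, npg = 1L, quan = "Unique",
                         contam = FALSE, inten = rep(100, 10)) {
  df <- data.frame(accession = "P1", n_protein_groups = npg, rank = rank,
                   search_engine_rank = ser, isolation_interference = ii,
                   avg_reporter_sn = sn, ion_score = ion, quan_info = quan,
                   is_contaminant = contam, stringsAsFactors = FALSE)
  cbind(df, setNames(as.data.frame(as.list(inten)),
                     sprintf("tmt_%02d", seq_along(inten))))
}

test_that("PSM filters apply inclusive boundaries exactly as stated", {
  pol <- filter_policy("spatial")
  expect_equal(nrow(filter_psms(make_psm_row(ii = 50.0), pol)), 1)  # <= 50
  expect_equal(nrow(filter_psms(make_psm_row(ii = 50.1), pol)), 0)
  expect_equal(nrow(filter_psms(make_psm_row(sn = 10.0), pol)), 1)  # >= 10
  expect_equal(nrow(filter_psms(make_psm_row(sn = 9.9), pol)), 0)
  expect_equal(nrow(filter_psms(make_psm_row(ion = 19.9), pol)), 0)
  expect_equal(nrow(filter_psms(make_psm_row(ion = 20.0), pol)), 1)
  tpol <- filter_policy("temporal")
  expect_equal(nrow(filter_psms(make_psm_row(ion = 20.0), tpol)), 0)
  expect_equal(nrow(filter_psms(make_psm_row(ion = 25.0), tpol)), 1)
  # two missing reporter values allowed, three not
  two <- make_psm_row(inten = c(rep(100, 8), NA, NA))
  three <- make_psm_row(inten = c(rep(100, 7), NA, NA, NA))
  expect_equal(nrow(filter_psms(two, pol)), 1)
  expect_equal(nrow(filter_psms(three, pol)), 0)
})

test_that("filtering matches the generator truth mask, preserves order, idempotent", {
  mix <- generate_psm_table(
    300, violation_rates = c(ion_score = 0.15, avg_reporter_sn = 0.1,
                             contaminant = 0.05),
    missing_rates = c(MAR = 0.02), seed = 8)
  kept <- filter_psms(mix$table, filter_policy("spatial"))
  expect_identical(rownames(kept), rownames(mix$table)[mix$keep_mask])
  expect_identical(filter_psms(kept, filter_policy("spatial")), kept)
  expect_lte(nrow(kept), nrow(mix$table))
  expect_error(filter_psms(mix$table[, -7], filter_policy("spatial")),
               "ion_score")
})

test_that("missingness mechanism labels follow the low-intensity quantile rule", {
  m <- matrix(rep(c(1, 10, 100, 1000, 1e4), each = 4), 5, 4, byrow = TRUE)
  m[1, 2] <- NA  # lowest-intensity row -> MNAR
  m[5, 3] <- NA  # highest-intensity row -> MAR
  lab <- classify_missingness(m, low_quantile = 0.2)
  expect_identical(lab[1, 2], "MNAR")
  expect_identical(lab[5, 3], "MAR")
  expect_true(all(is.na(lab[!is.na(m)])))
  expect_identical(attr(lab, "drop_rows"), integer(0))
  # no missing cells -> no labels
  expect_true(all(is.na(classify_missingness(matrix(1:6, 2)))))
  # random table matches an independent recomputation of the rule
  set.seed(3)
  r <- matrix(exp(rnorm(200, 5, 2)), 40, 5)
  r[sample(length(r), 30)] <- NA
  lab_r <- classify_missingness(r, low_quantile = 0.25)
  cut <- quantile(rowMeans(r, na.rm = TRUE), 0.25, names = FALSE)
  for (idx in which(is.na(r))) {
    i <- (idx - 1) %% 40 + 1
    expect_identical(lab_r[idx],
                     if (rowMeans(r, na.rm = TRUE)[i] < cut) "MNAR" else "MAR")
  }
  expect_warning(classify_missingness(rbind(r, NA)), "fully missing")
})

test_that("imputation fills MAR by neighbours and MNAR by channel minima", {
  m <- rbind(c(1, 2, 3, 4),
             c(1.1, 2.1, 3.1, 4.1),
             c(10, 20, 30, 40),
             c(5, 5, 5, 5))
  # no holes: identity
  mech0 <- matrix(NA_character_, 4, 4)
  expect_identical(impute_missing(m, mech0), m)
  # one MAR hole, k = 1: copied from the single nearest row
  m1 <- m; m1[1, 3] <- NA
  mech <- mech0; mech[1, 3] <- "MAR"
  out <- impute_missing(m1, mech, k = 1)
  expect_equal(out[1, 3], m[2, 3])  # row 2 is nearest to row 1
  expect_identical(out[-1, ], m1[-1, ])  # observed cells untouched
  # MNAR hole: column-wise observed minimum
  m2 <- m; m2[3, 2] <- NA
  mech2 <- mech0; mech2[3, 2] <- "MNAR"
  expect_equal(impute_missing(m2, mech2)[3, 2], min(m2[, 2], na.rm = TRUE))
  # k larger than the donor pool: warn and use all
  expect_warning(impute_missing(m1, mech, k = 50), "neighbours")
  expect_error(impute_missing(rbind(m1, NA), rbind(mech, "MAR")),
               "no observed value")
})

test_that("protein aggregation takes channel-wise medians", {
  one <- make_psm_row(inten = 1:10)
  expect_equal(unname(aggregate_to_proteins(one)[1, ]), as.numeric(1:10))
  two <- rbind(make_psm_row(inten = rep(1, 10)),
               make_psm_row(inten = rep(3, 10)))
  expect_equal(unname(aggregate_to_proteins(two)[1, ]), rep(2, 10))
  set.seed(1)
  five <- do.call(rbind, lapply(1:5, function(i)
    make_psm_row(inten = runif(10))))
  m <- as.matrix(five[, grep("^tmt_", names(five))])
  expect_equal(unname(aggregate_to_proteins(five)[1, ]),
               unname(apply(m, 2, function(x) sort(x)[3])))
  expect_equal(nrow(aggregate_to_proteins(five[0, ])), 0)
})

test_that("sum normalisation maps rows onto the simplex, scale-invariantly", {
  expect_equal(unname(sum_normalise(matrix(rep(7, 10), 1))[1, ]),
               rep(0.1, 10))
  onehot <- matrix(c(0, 0, 1, 0), 1)
  expect_equal(unname(sum_normalise(onehot)), unname(onehot))
  set.seed(2)
  r <- matrix(runif(60, 0.1, 5), 6)
  expect_equal(unname(rowSums(sum_normalise(r))), rep(1, 6),
               tolerance = 1e-12)
  expect_equal(sum_normalise(r * 37), sum_normalise(r))
  expect_warning(out <- sum_normalise(rbind(r, 0)), "all-zero")
  expect_equal(nrow(out), 6)
})

test_that("variance stabilisation calibrates columns and tames the mean-variance trend", {
  mu <- exp(rnorm(400, log(1e5), 1.2))
  m2 <- cbind(a = mu, b = 2 * mu)
  v2 <- vstab_normalise(m2, reference = 1)
  expect_lt(max(abs(v2[, 1] - v2[, 2])), 1e-6)
  const <- matrix(5000, 20, 4)
  vc <- vstab_normalise(const)
  expect_equal(sd(as.vector(vc)), 0)
  # multiplicative + additive noise: |Spearman rho(mean, sd)| must shrink
  # relative to a plain log2 transform
  set.seed(13)
  mu <- exp(rnorm(500, log(2e4), 1.5))
  raw <- sapply(1:6, function(j)
    pmax(mu * exp(rnorm(500, 0, 0.15)) * runif(1, 0.5, 2) +
           rnorm(500, 0, 2000), 1))
  v <- vstab_normalise(raw)
  rho <- function(x) abs(cor(rowMeans(x), apply(x, 1, sd),
                             method = "spearman"))
  expect_lt(rho(v), rho(log2(raw)))
})

test_that("condition intersection aligns accessions", {
  a <- matrix(1:6, 3, dimnames = list(c("P1", "P2", "P3"), NULL))
  b <- matrix(1:6, 3, dimnames = list(c("P2", "P4", "P1"), NULL))
  both <- intersect_conditions(a, b)
  expect_identical(rownames(both$a), rownames(both$b))
  expect_setequal(rownames(both$a), c("P1", "P2"))
  same <- intersect_conditions(a, a)
  expect_identical(same$a, a)
  rownames(b) <- c("Q1", "Q2", "Q3")
  expect_error(intersect_conditions(a, b), "no shared")
})
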