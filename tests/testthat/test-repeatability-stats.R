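pair_row <- function(test, retest, pid = "P01", lid = "L001") {
  tibble::tibble(
    patient_id = pid, lesion_id = lid,
    suv_max_test = test, suv_max_retest = retest,
    suv_mean_test = test, suv_mean_retest = retest,
    suv_total_test = test, suv_total_retest = retest,
    volume_cc_test = test, volume_cc_retest = retest
  )
}

test_that("log-ratios are ln(retest/test) with IDs carried through", {
  p <- pair_row(c(10, 10), c(10, 20), lid = c("L001", "L002"))
  lr <- log_ratios(p, "suv_max")
  expect_equal(lr$r, c(0, log(2)))
  expect_equal(lr$lesion_id, c("L001", "L002"))

  set.seed(1)
  a <- exp(rnorm(50))
  b <- exp(rnorm(50))
  lr2 <- log_ratios(pair_row(a, b, lid = sprintf("L%03d", 1:50)), "volume_cc")
  want <- numeric(50)
  for (i in 1:50) want[i] <- log(b[i] / a[i])
  expect_equal(lr2$r, want)
})

test_that("non-positive feature values are named in the error", {
  p <- pair_row(c(10, -1), c(10, 5), lid = c("L001", "L002"))
  expect_error(log_ratios(p, "suv_mean"), "L002",
               class = "petrep_error_validation")
  expect_error(wcov(p, "suv_mean"), class = "petrep_error_validation")
})

test_that("constant log-ratios give sigma zero and d_bar the constant", {
  s <- tibble::tibble(patient_id = c("A", "A", "B"), r = rep(0.07, 3))
  vc <- variance_components(s)
  expect_equal(vc$d_bar, 0.07)
  expect_equal(vc$sigma, 0)
})

test_that("the two-patient hand-computed ANOVA example is reproduced", {
  s <- tibble::tibble(patient_id = c("A", "A", "B", "B"),
                      r = c(0.1, 0.1, -0.1, -0.1))
  vc <- variance_components(s)
  expect_equal(vc$d_bar, 0)
  expect_equal(vc$ms_within, 0)
  expect_equal(vc$ms_between, 0.04)
  expect_equal(vc$m0, 2)
  expect_equal(vc$var_between, 0.02)
  expect_equal(vc$sigma, sqrt(0.02))
})

test_that("negative between-patient variance is clamped to zero", {
  # equal patient means, all spread within patients
  s <- tibble::tibble(patient_id = c("A", "A", "B", "B"),
                      r = c(-0.2, 0.2, -0.2, 0.2))
  vc <- variance_components(s)
  expect_equal(vc$var_between, 0)
  expect_equal(vc$sigma, sqrt(vc$ms_within))
  expect_gt(vc$ms_within, vc$ms_between)
})

test_that("variance components equal the sums-of-squares oracle", {
  for (seed in 1:60) {
    s <- random_samples(seed)
    vc <- variance_components(s)
    want <- oracle_vc(s$patient_id, s$r)
    for (f in c("d_bar", "ms_between", "ms_within", "m0", "var_between",
                "sigma")) {
      expect_lt(abs(vc[[f]] - want[[f]]), 1e-12)
    }
  }
})

test_that("degenerate groupings fall back to the marginal SD", {
  one_pat <- tibble::tibble(patient_id = "A", r = c(0.1, -0.3, 0.2))
  expect_equal(variance_components(one_pat)$sigma, sd(one_pat$r))
  singletons <- tibble::tibble(patient_id = c("A", "B", "C"),
                               r = c(0.1, -0.3, 0.2))
  expect_equal(variance_components(singletons)$sigma, sd(singletons$r),
               tolerance = 1e-12)
  expect_error(variance_components(tibble::tibble(patient_id = "A", r = 0.1)),
               class = "petrep_error_insufficient_data")
})

test_that("tidy and glance expose the variance components", {
  vc <- variance_components(random_samples(3))
  td <- tidy(vc)
  expect_equal(td$sigma, vc$sigma)
  expect_named(glance(vc), c("d_bar", "sigma", "n_patients", "n_lesions"))
})

test_that("the 95% LOA back-transform matches direct evaluation", {
  loa0 <- limits_of_agreement(list(d_bar = 0, sigma = 0))
  expect_equal(unlist(loa0), c(bias_pct = 0, loa_lower_pct = 0,
                               loa_upper_pct = 0))
  loa <- limits_of_agreement(list(d_bar = 0, sigma = 0.1))
  expect_equal(loa$loa_lower_pct, 100 * (exp(-0.196) - 1), tolerance = 1e-12)
  expect_equal(loa$loa_upper_pct, 100 * (exp(0.196) - 1), tolerance = 1e-12)
  # asymmetry of the back-transformed bounds
  expect_gt(loa$loa_upper_pct, abs(loa$loa_lower_pct))

  # a bias shift acts multiplicatively on both bounds
  shifted <- limits_of_agreement(list(d_bar = 0.05, sigma = 0.1))
  expect_equal(1 + shifted$loa_lower_pct / 100,
               exp(0.05) * (1 + loa$loa_lower_pct / 100), tolerance = 1e-12)
  expect_equal(1 + shifted$loa_upper_pct / 100,
               exp(0.05) * (1 + loa$loa_upper_pct / 100), tolerance = 1e-12)
})

test_that("ICC is one under perfect agreement and matches the oracle", {
  p <- pair_row(c(1, 2, 5, 9), c(1, 2, 5, 9), lid = sprintf("L%d", 1:4))
  expect_equal(icc(p, "suv_max"), 1)

  hand <- pair_row(c(10, 12, 20, 31), c(11, 12, 18, 33),
                   lid = sprintf("L%d", 1:4))
  expect_equal(icc(hand, "suv_max"),
               oracle_icc21(c(10, 12, 20, 31), c(11, 12, 18, 33)),
               tolerance = 1e-12)
  expect_equal(icc(hand, "suv_max", type = "one_way"),
               oracle_icc11(c(10, 12, 20, 31), c(11, 12, 18, 33)),
               tolerance = 1e-12)

  same <- pair_row(rep(3, 4), rep(3, 4), lid = sprintf("L%d", 1:4))
  expect_error(icc(same, "suv_max"), class = "petrep_error_validation")
})

test_that("ICC of randomly permuted retest values is near zero", {
  set.seed(42)
  n <- 5000
  true <- exp(rnorm(n, 1, 0.5))
  x1 <- true * exp(rnorm(n, 0, 0.1))
  x2 <- sample(true * exp(rnorm(n, 0, 0.1)))
  p <- pair_row(x1, x2, lid = sprintf("L%04d", 1:n))
  expect_lt(abs(icc(p, "suv_max")), 0.05)
})

test_that("ICC approaches the lognormal variance-ratio prediction", {
  set.seed(7)
  n <- 5000
  s_l <- 0.5
  s_w <- 0.1
  true <- exp(rnorm(n, 1, s_l))
  p <- pair_row(true * exp(rnorm(n, 0, s_w)), true * exp(rnorm(n, 0, s_w)),
                lid = sprintf("L%04d", 1:n))
  b <- exp(s_l^2) - 1
  w <- exp(s_l^2) * (exp(s_w^2) - 1)
  expect_lt(abs(icc(p, "suv_max") - b / (b + w)), 0.03)
})

test_that("wCOV reproduces hand-computed values in both variants", {
  equal_pairs <- pair_row(c(5, 8), c(5, 8), lid = c("L1", "L2"))
  expect_equal(wcov(equal_pairs, "suv_max"), 0)

  one <- pair_row(90, 110)
  expect_equal(wcov(one, "suv_max"), 100 * (20 / sqrt(2)) / 100,
               tolerance = 1e-12)

  p <- pair_row(c(90, 40), c(110, 44), lid = c("L1", "L2"))
  cv2 <- c((20 / sqrt(2) / 100)^2, (4 / sqrt(2) / 42)^2)
  expect_equal(wcov(p, "suv_max"), 100 * sqrt(mean(cv2)), tolerance = 1e-12)
  pooled <- 100 * sqrt(mean(c(20, 4)^2 / 2)) / mean(c(100, 42))
  expect_equal(wcov(p, "suv_max", method = "pooled_sd"), pooled,
               tolerance = 1e-12)
})

test_that("wCOV recovers the generative noise level", {
  co <- simulate_cohort(cohort_params(
    n_patients = 250, lesions_per_patient_mean = 20,
    patient_bias_sd = 0, lesion_noise_sd = 0.10, seed = 23))
  w <- wcov(co$pairs, "suv_mean")
  expect_lt(abs(w - 10) / 10, 0.10)
})

test_that("volume filtering is strict and monotone", {
  p <- pair_row(c(2, 0.9, 0.5), c(2, 1.2, 0.5), lid = c("L1", "L2", "L3"))
  expect_equal(nrow(filter_by_volume(p, 0)), 3)
  kept <- filter_by_volume(p, 1.0)
  expect_setequal(kept$lesion_id, c("L1", "L2"))  # mean(0.9, 1.2) = 1.05 > 1
  expect_setequal(filter_by_volume(p, 1.0, statistic = "test")$lesion_id, "L1")
  # boundary: mean exactly at the threshold is excluded
  expect_equal(nrow(filter_by_volume(pair_row(1, 1), 1.0)), 0)
  expect_error(filter_by_volume(p, -1), class = "petrep_error_params")

  co <- simulate_cohort(cohort_params(seed = 4))
  n <- sapply(c(0, 1, 1.5), function(th) nrow(filter_by_volume(co$pairs, th)))
  expect_true(all(diff(n) <= 0))
})

test_that("the stratified table has one row per feature and stratum", {
  co <- simulate_cohort(cohort_params(n_patients = 8, seed = 10))
  rt <- repeatability_table(co$pairs)
  expect_equal(nrow(rt), 12)
  expect_setequal(unique(rt$stratum), c("all", ">1 cm3", ">1.5 cm3"))
  expect_true(all(rt$loa_lower_pct <= rt$bias_pct))
  expect_true(all(rt$bias_pct <= rt$loa_upper_pct))
  expect_true(all(rt$loa_lower_pct > -100))
})

test_that("a zero-noise cohort gives degenerate metrics everywhere", {
  co <- simulate_cohort(zero_noise_params(n_patients = 6, seed = 12))
  rt <- repeatability_table(co$pairs)
  expect_equal(rt$bias_pct, rep(0, nrow(rt)))
  expect_equal(rt$loa_lower_pct, rep(0, nrow(rt)))
  expect_equal(rt$loa_upper_pct, rep(0, nrow(rt)))
  expect_equal(rt$wcov_pct, rep(0, nrow(rt)))
  expect_equal(rt$icc, rep(1, nrow(rt)))
})

test_that("table rows equal direct recomposition from the five operations", {
  co <- simulate_cohort(cohort_params(n_patients = 10, seed = 20))
  rt <- repeatability_table(co$pairs)
  strata <- list("all" = co$pairs,
                 ">1 cm3" = filter_by_volume(co$pairs, 1),
                 ">1.5 cm3" = filter_by_volume(co$pairs, 1.5))
  for (i in seq_len(nrow(rt))) {
    sub <- strata[[rt$stratum[i]]]
    f <- rt$feature[i]
    vc <- variance_components(log_ratios(sub, f))
    loa <- limits_of_agreement(vc)
    expect_equal(rt$n_lesions[i], nrow(sub))
    expect_equal(rt$bias_pct[i], loa$bias_pct)
    expect_equal(rt$loa_lower_pct[i], loa$loa_lower_pct)
    expect_equal(rt$loa_upper_pct[i], loa$loa_upper_pct)
    expect_equal(rt$icc[i], icc(sub, f))
    expect_equal(rt$wcov_pct[i], wcov(sub, f))
  }
})

test_that("understaffed strata are skipped with a warning", {
  p <- pair_row(c(0.2, 0.3, 5), c(0.25, 0.28, 5.5),
                pid = c("A", "A", "B"), lid = c("L1", "L2", "L3"))
  warns <- testthat::capture_warnings(rt <- repeatability_table(p))
  expect_true(any(grepl("skipped", warns)))
  expect_setequal(unique(rt$stratum), "all")
})

test_that("all metrics are invariant to a global positive rescaling", {
  co <- simulate_cohort(cohort_params(n_patients = 6, seed = 30))
  scaled <- co$pairs
  for (col in names(scaled)[-(1:2)]) scaled[[col]] <- scaled[[col]] * 37.5
  f <- "suv_total"
  vc1 <- variance_components(log_ratios(co$pairs, f))
  vc2 <- variance_components(log_ratios(scaled, f))
  expect_equal(vc1$d_bar, vc2$d_bar, tolerance = 1e-10)
  expect_equal(vc1$sigma, vc2$sigma, tolerance = 1e-10)
  expect_equal(icc(co$pairs, f), icc(scaled, f), tolerance = 1e-10)
  expect_equal(wcov(co$pairs, f), wcov(scaled, f), tolerance = 1e-10)
})
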