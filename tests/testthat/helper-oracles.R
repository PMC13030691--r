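# Independent brute-force oracles. These deliberately use plain voxel loops
# and explicit sums of squares so they share no code path with the package.

oracle_features <- function(suv, labels, voxel_size_mm) {
  vox_cc <- prod(voxel_size_mm) / 1000
  out <- list()
  for (l in sort(unique(labels[labels > 0]))) {
    vals <- c()
    for (i in seq_len(dim(suv)[1])) {
      for (j in seq_len(dim(suv)[2])) {
        for (k in seq_len(dim(suv)[3])) {
          if (labels[i, j, k] == l) vals <- c(vals, suv[i, j, k])
        }
      }
    }
    out[[as.character(l)]] <- data.frame(
      lesion_id = l,
      suv_max = max(vals),
      suv_mean = mean(vals),
      suv_total = sum(vals) * vox_cc,
      volume_cc = length(vals) * vox_cc
    )
  }
  do.call(rbind, out)
}

oracle_centroid <- function(labels, label, voxel_size_mm) {
  acc <- c(0, 0, 0)
  n <- 0
  for (i in seq_len(dim(labels)[1])) {
    for (j in seq_len(dim(labels)[2])) {
      for (k in seq_len(dim(labels)[3])) {
        if (labels[i, j, k] == label) {
          acc <- acc + (c(i, j, k) - 0.5) * voxel_size_mm
          n <- n + 1
        }
      }
    }
  }
  acc / n
}

# One-way ANOVA variance components by explicit loops over patients.
oracle_vc <- function(patient_id, r) {
  d_bar <- sum(r) / length(r)
  ids <- unique(patient_id)
  n <- length(ids)
  N <- length(r)
  ssb <- 0
  ssw <- 0
  sum_m2 <- 0
  for (id in ids) {
    ri <- r[patient_id == id]
    m <- length(ri)
    sum_m2 <- sum_m2 + m^2
    ssb <- ssb + m * (mean(ri) - d_bar)^2
    for (x in ri) ssw <- ssw + (x - mean(ri))^2
  }
  ms_between <- ssb / (n - 1)
  ms_within <- if (N > n) ssw / (N - n) else 0
  m0 <- (N - sum_m2 / N) / (n - 1)
  var_between <- max(0, (ms_between - ms_within) / m0)
  list(d_bar = d_bar, ms_between = ms_between, ms_within = ms_within,
       m0 = m0, var_between = var_between,
       sigma = sqrt(var_between + ms_within))
}

# Two-way (lesions x scans) sums of squares for ICC(2,1), by loops.
oracle_icc21 <- function(x1, x2) {
  n <- length(x1)
  k <- 2
  g <- mean(c(x1, x2))
  ss_total <- 0
  for (v in c(x1, x2)) ss_total <- ss_total + (v - g)^2
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * ((x1[i] + x2[i]) / 2 - g)^2
  ss_cols <- n * (mean(x1) - g)^2 + n * (mean(x2) - g)^2
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

oracle_icc11 <- function(x1, x2) {
  n <- length(x1)
  k <- 2
  g <- mean(c(x1, x2))
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * ((x1[i] + x2[i]) / 2 - g)^2
  msr <- ss_rows / (n - 1)
  ssw <- 0
  for (i in seq_len(n)) {
    m <- (x1[i] + x2[i]) / 2
    ssw <- ssw + (x1[i] - m)^2 + (x2[i] - m)^2
  }
  msw <- ssw / (n * (k - 1))
  (msr - msw) / (msr + (k - 1) * msw)
}

# Random small grouped log-ratio dataset for oracle-equivalence tests.
random_samples <- function(seed) {
  set.seed(seed)
  n_pat <- sample(2:6, 1)
  rows <- lapply(seq_len(n_pat), function(i) {
    m <- sample(1:5, 1)
    data.frame(patient_id = sprintf("P%02d", i),
               lesion_id = sprintf("P%02d_L%d", i, seq_len(m)),
               r = rnorm(m, sd = runif(1, 0.01, 0.5)))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# Random positive matched-pair table (lognormal features).
random_pairs <- function(seed, n = 20, n_patients = 4) {
  set.seed(seed)
  pid <- sprintf("P%02d", sample(seq_len(n_patients), n, replace = TRUE))
  mk <- function() exp(rnorm(n, 1, 0.6))
  tibble::tibble(
    patient_id = pid,
    lesion_id = sprintf("L%03d", seq_len(n)),
    suv_max_test = mk(), suv_max_retest = mk(),
    suv_mean_test = mk(), suv_mean_retest = mk(),
    suv_total_test = mk(), suv_total_retest = mk(),
    volume_cc_test = mk(), volume_cc_retest = mk()
  )
}

zero_noise_params <- function(...) {
  cohort_params(patient_bias_sd = 0, lesion_noise_sd = 0,
                jitter_boundary_prob = 0, ...)
}
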