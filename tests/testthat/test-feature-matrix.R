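test_that("identical peak lists align to one feature per peak", {
  pl <- list(
    S1 = data.frame(mass = c(100.05, 200.10), rt = c(1, 5),
                    intensity = c(1e4, 2e4)),
    S2 = data.frame(mass = c(100.05, 200.10), rt = c(1, 5),
                    intensity = c(1.1e4, 2.1e4))
  )
  ft <- align_peak_lists(pl, ppm_tol = 10, rt_tol = 0.3)
  expect_equal(n_features(ft), 2)
  expect_true(all(!is.na(intensities(ft))))
})

test_that("peaks separated beyond the ppm window stay distinct", {
  pl <- list(S1 = data.frame(mass = c(500.000, 500.025), rt = c(1, 1),
                             intensity = c(1e4, 1e4)))
  ft <- align_peak_lists(pl, ppm_tol = 10, rt_tol = 0.3) # 50 ppm apart
  expect_equal(n_features(ft), 2)
})

test_that("empty input aligns to an empty table, not an error", {
  ft <- align_peak_lists(list(), ppm_tol = 10, rt_tol = 0.3)
  expect_equal(n_features(ft), 0)
  expect_error(align_peak_lists(list(), ppm_tol = 0, rt_tol = 0.3), "ppm")
})

test_that("jittered synthetic peak lists re-align to the true features", {
  cfg <- synthetic_config(n_features = 150, n_discriminating = 20,
                          n_extra = 0, n_per_group = 4, presence_rate = 0.9)
  gen <- generate_cohort(cfg, seed = 21)
  pl <- generate_peak_lists(gen$table, mz_jitter_ppm = 5,
                            rt_jitter_min = 0.1, seed = 22)
  ft <- align_peak_lists(pl, ppm_tol = 10, rt_tol = 0.3)
  expect_equal(n_features(ft), n_features(gen$table))
  members <- attr(ft, "cluster_members")
  purity <- vapply(members, function(m) {
    length(unique(m$source_feature)) == 1
  }, TRUE)
  expect_true(all(purity))
  # centroids sorted by mass then rt
  expect_true(!is.unsorted(ft$features$neutral_mass))
})

test_that("presence filter implements the any-group and per-group rules", {
  tab <- make_tiny_table() # F03 detected in all 4 A, 1 S, 0 C
  kept_any <- presence_filter(tab, 4, "any_group", c("C", "S", "A"))
  expect_true("F03" %in% kept_any$features$feature_id)
  kept_per <- presence_filter(tab, 4, "per_group", c("A", "C"))
  expect_false("F03" %in% kept_per$features$feature_id)
  expect_false("F02" %in% kept_per$features$feature_id) # absent in C
  # min_count 0 is the identity on features
  expect_identical(presence_filter(tab, 0, "any_group")$features,
                   tab$features)
  expect_error(presence_filter(tab, 4, "any_group", "QC"), "QC")
})

test_that("presence filter is monotone and any_group contains per_group", {
  gen <- generate_cohort(small_config(presence_rate = 0.7), 3)
  tab <- gen$table
  prev <- NULL
  for (mc in c(2, 4, 6, 8, 10)) {
    ids <- presence_filter(tab, mc, "any_group")$features$feature_id
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    per <- presence_filter(tab, mc, "per_group")$features$feature_id
    expect_true(all(per %in% ids))
    prev <- ids
  }
})

test_that("log10 transform is exact, guarded, and invertible", {
  tab <- make_tiny_table()
  tab$intensities[1, 1] <- 1000
  tab$intensities[1, 2] <- 1
  lg <- log10_transform(tab)
  expect_equal(intensities(lg)[1, 1], 3)
  expect_equal(intensities(lg)[1, 2], 0)
  expect_equal(10^intensities(lg), intensities(tab), tolerance = 1e-12)
  expect_error(log10_transform(lg), "already")

  tab$intensities[2, 5] <- -1
  expect_error(log10_transform(tab), "F02.*S01")
})

test_that("welch_t_test matches the closed form and its symmetries", {
  res <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(1)
  x <- rnorm(8); y <- rnorm(10, 1)
  a <- welch_t_test(x, y)
  b <- welch_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_error(welch_t_test(1, c(1, 2)), "non-missing")
})

test_that("welch equals the classical t when sizes and variances match", {
  for (i in 1:10) {
    set.seed(i)
    x <- rnorm(9)
    y <- rnorm(9)
    y <- (y - mean(y)) / sd(y) * sd(x) + mean(y) # force equal variance
    w <- welch_t_test(x, y)
    classical <- (mean(x) - mean(y)) /
      (sd(x) * sqrt(2 / 9)) # pooled sd = common sd
    expect_equal(w$t, classical, tolerance = 1e-10)
    expect_equal(w$df, 16)
  }
})

test_that("percent change reproduces reference fold arithmetic", {
  expect_equal(percent_change(c(5, 5), c(5, 5)), 0)
  expect_equal(percent_change(40.9, 10.0), 309, tolerance = 1e-10)
  expect_equal(percent_change(2.4, 10.0), -76, tolerance = 1e-10)
  x <- c(1, 2, NA, 4); y <- c(2, 2, 2)
  expect_equal(percent_change(x * 10, y * 10), percent_change(x, y))
  expect_error(percent_change(numeric(0), y), "non-empty")
})

test_that("shapiro_wilk flags non-normal samples and rejects constants", {
  set.seed(3)
  x_norm <- rnorm(50)
  x_exp <- rexp(50)
  expect_gt(shapiro_wilk(x_norm)$p_value, 0.05)
  expect_lt(shapiro_wilk(x_exp)$p_value, 0.05)
  # agrees with the reference implementation on the same draw
  expect_equal(shapiro_wilk(x_exp)$W,
               unname(shapiro.test(x_exp)$statistic))
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("qc_cv is the percent sd/mean and is scale invariant", {
  expect_equal(qc_cv(c(10, 10, 10)), 0)
  expect_equal(qc_cv(c(9, 10, 11)), 10)
  v <- c(5, 8, 13, NA, 9)
  expect_equal(qc_cv(v * 1000), qc_cv(v))
  expect_true(is.na(qc_cv(c(4, NA, NA))))
})

test_that("compare_groups orders by p, counts significance, logs skips", {
  cfg <- synthetic_config(n_features = 40, n_discriminating = 1,
                          n_extra = 0, effect_table = data.frame(
                            feature = 1L, group = "A", fold = 4.09))
  gen <- generate_cohort(cfg, 2)
  res <- compare_groups(gen$table, "A", "C", min_count = 10)
  expect_s3_class(res, "comparison_result")
  expect_false(is.unsorted(res$p))
  expect_equal(res$feature_id[1], "F0001") # the planted effect ranks first
  expect_gt(res$pct_change[1], 200)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$df > 0))
  expect_true(all(res$pct_change > -100))
  expect_identical(attr(res, "groups"), c("A", "C"))
})

test_that("comparing a group to itself gives zero percent change", {
  gen <- generate_cohort(small_config(), 5)
  res <- compare_groups(gen$table, "C", "C", min_count = 5)
  expect_true(all(res$pct_change == 0))
  expect_true(all(res$t == 0))
})

test_that("compare_groups is invariant to sample column permutation", {
  gen <- generate_cohort(small_config(), 6)
  tab <- gen$table
  set.seed(1)
  perm <- sample(n_samples(tab))
  tab_perm <- feature_table(tab$features,
                            tab$samples[perm, , drop = FALSE],
                            intensities(tab)[, perm, drop = FALSE])
  a <- compare_groups(tab, "A", "C", 8)
  b <- compare_groups(tab_perm, "A", "C", 8)
  expect_identical(a$feature_id, b$feature_id)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("feature tables round-trip through CSV", {
  gen <- generate_cohort(small_config(), 8)
  qc <- generate_qc_block(small_config(), 8)
  tab <- bind_sample_block(gen$table, qc, label = "QC")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(back$samples, tab$samples)
  expect_equal(back$features$neutral_mass, tab$features$neutral_mass,
               tolerance = 1e-6)
  expect_equal(is.na(intensities(back)), is.na(intensities(tab)))
  expect_equal(intensities(back), intensities(tab), tolerance = 1e-6)
})

test_that("qc_metrics reports one CV per feature from QC columns", {
  cfg <- small_config()
  gen <- generate_cohort(cfg, 12)
  tab <- bind_sample_block(gen$table, generate_qc_block(cfg, 12), "QC")
  qm <- qc_metrics(tab)
  expect_equal(nrow(qm), n_features(tab))
  expect_true(all(qm$cv_percent >= 0, na.rm = TRUE))
  expect_error(qc_metrics(gen$table), "no QC samples")
})
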