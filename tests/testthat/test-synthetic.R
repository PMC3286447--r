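test_that("default cohort has the study's sample and feature counts", {
  gen <- generate_cohort(synthetic_config(), seed = 1)
  expect_equal(n_samples(gen$table), 41) # 3 x 11 modeled + 8 prediction-only
  expect_equal(n_features(gen$table), 600)
  expect_equal(as.integer(table(gen$table$samples$label)[c("C", "S", "A",
                                                           "P")]),
               c(11L, 11L, 11L, 8L))
  # extras carry true classes split half large, half small
  extras <- gen$truth$sample_classes$true_class[
    gen$table$samples$label == "P"]
  expect_equal(sum(extras == "A"), 4)
  expect_equal(sum(extras == "S"), 4)
})

test_that("generators are deterministic in (config, seed)", {
  cfg <- small_config()
  expect_identical(generate_cohort(cfg, 7), generate_cohort(cfg, 7))
  expect_identical(generate_qc_block(cfg, 7), generate_qc_block(cfg, 7))
  gen <- generate_cohort(cfg, 7)
  expect_identical(generate_peak_lists(gen$table, seed = 3),
                   generate_peak_lists(gen$table, seed = 3))
  expect_identical(generate_msms_spectrum("lysoPC", 500, seed = 3),
                   generate_msms_spectrum("lysoPC", 500, seed = 3))
  expect_false(identical(generate_cohort(cfg, 7), generate_cohort(cfg, 8)))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(synthetic_config(n_per_group = 1), "n_per_group")
  expect_error(synthetic_config(n_discriminating = 700), "n_discriminating")
  expect_error(synthetic_config(qc_cv_range = c(0, 45)), "qc_cv_range")
  expect_error(synthetic_config(presence_rate = 0), "presence_rate")
  et <- default_effect_table(5)
  et$fold[1] <- -2
  expect_error(synthetic_config(effect_table = et), "effect_table")
})

test_that("ground truth relates fold and percent change exactly", {
  gen <- generate_cohort(small_config(), seed = 2)
  tf <- gen$truth$features
  expect_identical(tf$pct_A_vs_C, (tf$fold_A - 1) * 100)
  expect_identical(tf$pct_S_vs_C, (tf$fold_S - 1) * 100)
  expect_identical(tf$pct_A_vs_S, (tf$fold_A / tf$fold_S - 1) * 100)
})

test_that("a planted 4.09-fold effect is recovered at large n", {
  et <- data.frame(feature = 1L, group = "A", fold = 4.09)
  cfg <- synthetic_config(n_per_group = 200, n_extra = 0, n_features = 10,
                          n_discriminating = 1, effect_table = et)
  gen <- generate_cohort(cfg, seed = 5)
  mat <- intensities(gen$table)
  lab <- gen$table$samples$label
  realized <- percent_change(mat[1, lab == "A"], mat[1, lab == "C"])
  expect_lt(abs(realized - 309), 10)
})

test_that("detection rate per feature stays within binomial 99% bounds", {
  cfg <- synthetic_config(n_features = 200, n_discriminating = 0,
                          n_extra = 0, presence_rate = 0.9)
  gen <- generate_cohort(cfg, seed = 11)
  det <- rowMeans(!is.na(intensities(gen$table)))
  n <- n_samples(gen$table)
  half_width <- qnorm(0.995) * sqrt(0.9 * 0.1 / n)
  # individual features may graze the bound; 99% of 200 should lie inside
  inside <- mean(abs(det - 0.9) <= half_width + 1e-12)
  expect_gte(inside, 0.95)
})

test_that("QC block matches the requested replicate count and CV", {
  cfg <- synthetic_config()
  qc <- generate_qc_block(cfg, seed = 1)
  expect_equal(ncol(qc), 13)
  expect_equal(nrow(qc), 600)
  expect_error(generate_qc_block(synthetic_config(n_qc = 1), 1),
               "undefined")

  cfg10 <- synthetic_config(n_features = 50, n_discriminating = 0,
                            n_qc = 1000, qc_cv_range = c(10, 10))
  block <- generate_qc_block(cfg10, seed = 3)
  cvs <- apply(block, 1, qc_cv)
  expect_true(all(abs(cvs - 10) <= 1))
})

test_that("QC block shares feature identity with the cohort", {
  cfg <- small_config()
  gen <- generate_cohort(cfg, 9)
  qc <- generate_qc_block(cfg, 9)
  expect_identical(rownames(qc), gen$table$features$feature_id)
  # QC replicates are drawn around the control baseline: per-feature QC
  # medians track control medians on the log scale
  ctrl <- intensities(gen$table)[, gen$table$samples$label == "C"]
  delta <- log10(apply(qc, 1, median)) -
    log10(apply(ctrl, 1, median, na.rm = TRUE))
  expect_lt(median(abs(delta)), 0.2)
})

test_that("peak-list jitter respects the configured bounds", {
  gen <- generate_cohort(small_config(), 4)
  exact <- generate_peak_lists(gen$table, mz_jitter_ppm = 0,
                               rt_jitter_min = 0, seed = 1)
  f_mass <- setNames(gen$table$features$neutral_mass,
                     gen$table$features$feature_id)
  for (pl in exact[1:3]) {
    expect_identical(pl$mass, unname(f_mass[pl$source_feature]))
  }
  jit <- generate_peak_lists(gen$table, mz_jitter_ppm = 5,
                             rt_jitter_min = 0.1, seed = 1)
  for (pl in jit) {
    ppm_dev <- abs(pl$mass / f_mass[pl$source_feature] - 1) * 1e6
    expect_true(all(ppm_dev <= 5))
    expect_true(all(abs(pl$rt - gen$table$features$rt[
      match(pl$source_feature, gen$table$features$feature_id)]) <= 0.1))
  }
  expect_error(generate_peak_lists(gen$table, mz_jitter_ppm = -1),
               "jitters")
})

test_that("synthetic MS/MS spectra carry the class-diagnostic peaks", {
  acyl <- generate_msms_spectrum("acylcarnitine", 400.34, seed = 1)
  expect_true(any(abs(acyl$peaks$mz - 60.08) < 0.02))
  expect_true(any(abs(acyl$peaks$mz - 85.03) < 0.02))
  expect_equal(match_fragment_rules(acyl), "acylcarnitine",
               ignore_attr = TRUE)

  lpe <- generate_msms_spectrum("lysoPE", 482.32, seed = 1)
  expect_true(any(abs(lpe$peaks$mz - (482.32 - 141.02)) < 0.03))
  expect_true("lysoPE" %in% match_fragment_rules(lpe))

  other <- generate_msms_spectrum("other", 400, seed = 1)
  expect_length(match_fragment_rules(other), 0)

  expect_error(generate_msms_spectrum("acylcarnitine", 70, seed = 1),
               "precursor")
})

test_that("spectrum text files round-trip", {
  sp <- generate_msms_spectrum("lysoPC", 496.34, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$precursor_mz, sp$precursor_mz, tolerance = 1e-6)
  expect_equal(back$peaks$mz, sp$peaks$mz, tolerance = 1e-6)
})

test_that("YAML configs round-trip through read_synthetic_config", {
  cfg <- synthetic_config(n_features = 30, n_discriminating = 2,
                          effect_table = data.frame(
                            feature = c(1L, 2L), group = c("A", "S"),
                            fold = c(2, 0.5)))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_features = 30, n_discriminating = 2,
    effect_table = list(
      list(feature = 1, group = "A", fold = 2),
      list(feature = 2, group = "S", fold = 0.5)
    )
  ), path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(cfg2$n_features, 30)
  expect_equal(cfg2$effect_table$fold, c(2, 0.5))
  expect_identical(generate_cohort(cfg, 3), generate_cohort(cfg2, 3))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(42)
  before <- .Random.seed
  invisible(generate_cohort(small_config(), 1))
  expect_identical(.Random.seed, before)
})
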