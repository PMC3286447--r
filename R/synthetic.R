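# Default between-group effect magnitudes used by the synthetic generator:
# percent changes (large-vs-control, small-vs-control) typical of plasma
# metabolites discriminating aneurysm stage (guanidinosuccinic acid up
# several-fold in large aneurysm; acylcarnitines and lysophospholipids down
# 30-70% with the small group intermediate).
.default_effect_pcts <- matrix(c(
  # pct_A_vs_C, pct_S_vs_C
   309,  -16,
   -18,   -4,
   -76,  235,
   -68,   -6,
    67,  -25,
   -41,  140,
   -16,  -28,
   -54,  -63,
    -8,   16,
    -8,  -59,
   -43,  -26,
   -25,  -36,
   -25,  -30,
   -60,  -36,
   -51,  -44,
   -66,  -67,
   -53,  -47,
   -55,  -41,
   -60,  -48,
   -71,  -22,
   -45,  -40,
   -50,  -15,
   -52,  -11,
   -55,  -20,
   -55,   11,
   -53,  -21,
   -73,  -36,
   -61,  -32,
   -61,  -25,
   -62,  -29,
   -49,  -36,
   -42,  -20,
   -57,  -26,
   -45,  -40,
   -50,  -26,
   -64,  -35,
   -14,   -8,
   -55,  -34,
   -43,  -29,
   -31,  -32,
   -53,  -52
), ncol = 2, byrow = TRUE)

#' Default effect table for the synthetic cohort generator
#'
#' Assigns multiplicative group effects (fold relative to control) to the
#' first `n_discriminating` features, cycling through a panel of percent
#' changes representative of metabolites separating control, small- and
#' large-aneurysm plasma. Fold and percent change are related by
#' `percent = (fold - 1) * 100`.
#'
#' @param n_discriminating number of features carrying true effects.
#' @return data.frame with columns `feature` (index), `group` (`"A"` or
#'   `"S"`) and `fold` (> 0).
#' @export
default_effect_table <- function(n_discriminating = 60) {
  if (n_discriminating == 0) {
    return(data.frame(feature = integer(), group = character(),
                      fold = numeric()))
  }
  idx <- ((seq_len(n_discriminating) - 1L) %% nrow(.default_effect_pcts)) + 1L
  data.frame(
    feature = rep(seq_len(n_discriminating), each = 2L),
    group = rep(c("A", "S"), times = n_discriminating),
    fold = as.vector(t(1 + .default_effect_pcts[idx, , drop = FALSE] / 100))
  )
}

#' Configuration of the synthetic LC-MS cohort generator
#'
#' Defines the study conditions the generator emulates: three modeled
#' groups (control `C`, small aneurysm `S`, large aneurysm `A`) of
#' `n_per_group` samples each, `n_extra` prediction-only samples (split
#' half large, half small), `n_qc` replicates of a pooled control-like
#' plasma, and `n_features` aligned features of which `n_discriminating`
#' carry true multiplicative group effects. Intensities are log-normal:
#' normal on the log10 scale with per-feature baseline drawn from
#' `N(base_log10_mean, base_log10_sd)` and within-group dispersion
#' `noise_log10_sd`. Detection is Bernoulli per sample-feature cell with
#' probability `presence_rate`; non-detected cells are missing, never zero.
#'
#' @param n_per_group samples per modeled class (default 11).
#' @param n_extra held-out prediction samples, split half `A` half `S`
#'   (default 8).
#' @param n_qc QC replicates (default 13).
#' @param n_features total aligned features (default 600).
#' @param n_discriminating features with true effects (default 60).
#' @param base_log10_mean,base_log10_sd location/scale of the per-feature
#'   baseline intensity on the log10 scale.
#' @param noise_log10_sd within-group dispersion on the log10 scale.
#' @param effect_table data.frame (`feature`, `group`, `fold`) of
#'   multiplicative effects relative to control; defaults to
#'   [default_effect_table()].
#' @param qc_cv_range percent interval from which per-feature QC replicate
#'   coefficients of variation are drawn (default `c(5, 45)`).
#' @param presence_rate probability a feature is detected in a sample.
#' @param mass_range Da interval for feature neutral masses.
#' @param rt_range minutes interval for retention times.
#' @param seed default integer seed used when a generator is called
#'   without an explicit one.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = 11,
                             n_extra = 8,
                             n_qc = 13,
                             n_features = 600,
                             n_discriminating = 60,
                             base_log10_mean = 5,
                             base_log10_sd = 1,
                             noise_log10_sd = 0.03,
                             effect_table = NULL,
                             qc_cv_range = c(5, 45),
                             presence_rate = 0.95,
                             mass_range = c(100, 1000),
                             rt_range = c(0.5, 35),
                             seed = 1L) {
  cfg <- structure(
    list(
      n_per_group = n_per_group, n_extra = n_extra, n_qc = n_qc,
      n_features = n_features, n_discriminating = n_discriminating,
      base_log10_mean = base_log10_mean, base_log10_sd = base_log10_sd,
      noise_log10_sd = noise_log10_sd,
      effect_table = effect_table %||% default_effect_table(n_discriminating),
      qc_cv_range = qc_cv_range, presence_rate = presence_rate,
      mass_range = mass_range, rt_range = rt_range, seed = seed
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  cfg_err <- function(field, why) {
    abort("invalid synthetic config: `", field, "` ", why)
  }
  if (!is_count(cfg$n_per_group, 2)) cfg_err("n_per_group", "must be >= 2")
  if (!is_count(cfg$n_extra)) cfg_err("n_extra", "must be a count >= 0")
  if (cfg$n_extra %% 2 != 0) cfg_err("n_extra", "must be even (split A/S)")
  if (!is_count(cfg$n_qc)) cfg_err("n_qc", "must be a count")
  if (!is_count(cfg$n_features, 1)) cfg_err("n_features", "must be >= 1")
  if (!is_count(cfg$n_discriminating) ||
      cfg$n_discriminating > cfg$n_features) {
    cfg_err("n_discriminating", "must be a count <= n_features")
  }
  et <- cfg$effect_table
  if (!is.data.frame(et) ||
      !all(c("feature", "group", "fold") %in% names(et))) {
    cfg_err("effect_table", "needs columns feature, group, fold")
  }
  if (nrow(et) > 0) {
    if (any(et$fold <= 0)) cfg_err("effect_table", "folds must be > 0")
    if (!all(et$group %in% c("S", "A"))) {
      cfg_err("effect_table", "groups must be S or A (relative to C)")
    }
    if (any(et$feature < 1 | et$feature > cfg$n_features)) {
      cfg_err("effect_table", "feature indices out of range")
    }
  }
  if (length(cfg$qc_cv_range) != 2 || any(cfg$qc_cv_range <= 0) ||
      any(cfg$qc_cv_range >= 100) || diff(cfg$qc_cv_range) < 0) {
    cfg_err("qc_cv_range", "must be an increasing interval within (0, 100)")
  }
  if (!is_number(cfg$presence_rate) || cfg$presence_rate <= 0 ||
      cfg$presence_rate > 1) {
    cfg_err("presence_rate", "must be in (0, 1]")
  }
  if (!is_number(cfg$noise_log10_sd) || cfg$noise_log10_sd <= 0) {
    cfg_err("noise_log10_sd", "must be > 0")
  }
  if (length(cfg$mass_range) != 2 || cfg$mass_range[1] <= 0 ||
      diff(cfg$mass_range) <= 0) {
    cfg_err("mass_range", "must be a positive increasing interval")
  }
  if (length(cfg$rt_range) != 2 || cfg$rt_range[1] < 0 ||
      diff(cfg$rt_range) <= 0) {
    cfg_err("rt_range", "must be a non-negative increasing interval")
  }
  invisible(cfg)
}

#' Read a synthetic generator configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; `effect_table` may be
#' given as a list of `{feature, group, fold}` records.
#'
#' @param path YAML file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effect_table)) {
    raw$effect_table <- do.call(rbind, lapply(raw$effect_table, function(r) {
      data.frame(feature = as.integer(r$feature), group = r$group,
                 fold = as.numeric(r$fold))
    }))
  }
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort("unknown synthetic config field(s): ",
          paste(unknown, collapse = ", "))
  }
  do.call(synthetic_config, raw)
}

# Per-feature fixed parameters (mass, rt, baseline log10 intensity); shared
# by generate_cohort() and generate_qc_block() so a QC block generated from
# the same (config, seed) is consistent with the cohort.
draw_feature_params <- function(cfg, seed) {
  with_seed(derive_seed(seed, 11L), {
    n <- cfg$n_features
    data.frame(
      feature_id = sprintf("F%04d", seq_len(n)),
      neutral_mass = stats::runif(n, cfg$mass_range[1], cfg$mass_range[2]),
      rt = stats::runif(n, cfg$rt_range[1], cfg$rt_range[2]),
      mu_log10 = stats::rnorm(n, cfg$base_log10_mean, cfg$base_log10_sd)
    )
  })
}

# n_features x 2 matrix of log10 fold offsets for groups S and A.
effect_offsets <- function(cfg) {
  off <- matrix(0, cfg$n_features, 2, dimnames = list(NULL, c("S", "A")))
  et <- cfg$effect_table
  if (nrow(et) > 0) {
    off[cbind(et$feature, match(et$group, c("S", "A")))] <- log10(et$fold)
  }
  off
}

#' Generate a synthetic three-group cohort with known ground truth
#'
#' Emulates an aligned LC-MS feature table for `3 * n_per_group` modeled
#' samples (classes `C`, `S`, `A`) plus `n_extra` prediction-only samples
#' (label `P`; half carrying large-aneurysm effects, half small). Identical
#' `(config, seed)` yield bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (a `ground_truth` list: per-feature true folds and percent changes,
#'   presence rate, and the true class of every sample including the
#'   prediction-only ones).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  params <- draw_feature_params(config, seed)
  off <- effect_offsets(config)

  n_half <- config$n_extra / 2
  samples <- data.frame(
    sample_id = c(
      sprintf("C%02d", seq_len(config$n_per_group)),
      sprintf("S%02d", seq_len(config$n_per_group)),
      sprintf("A%02d", seq_len(config$n_per_group)),
      if (config$n_extra > 0) sprintf("P%02d", seq_len(config$n_extra))
    ),
    label = c(
      rep(c("C", "S", "A"), each = config$n_per_group),
      rep("P", config$n_extra)
    ),
    true_class = c(
      rep(c("C", "S", "A"), each = config$n_per_group),
      rep(c("A", "S"), each = n_half)
    )
  )

  n_s <- nrow(samples)
  mat <- with_seed(derive_seed(seed, 23L), {
    shift <- vapply(samples$true_class, function(g) {
      if (g == "C") rep(0, config$n_features) else off[, g]
    }, numeric(config$n_features))
    logi <- params$mu_log10 + shift +
      matrix(stats::rnorm(config$n_features * n_s, 0, config$noise_log10_sd),
             config$n_features, n_s)
    detected <- matrix(
      stats::runif(config$n_features * n_s) < config$presence_rate,
      config$n_features, n_s
    )
    m <- 10^logi
    m[!detected] <- NA_real_
    m
  })

  tab <- feature_table(
    params[, c("feature_id", "neutral_mass", "rt")],
    samples[, c("sample_id", "label")],
    mat
  )

  fold_s <- 10^off[, "S"]
  fold_a <- 10^off[, "A"]
  truth <- structure(
    list(
      features = data.frame(
        feature_id = params$feature_id,
        fold_S = fold_s,
        fold_A = fold_a,
        pct_A_vs_C = (fold_a - 1) * 100,
        pct_S_vs_C = (fold_s - 1) * 100,
        pct_A_vs_S = (fold_a / fold_s - 1) * 100,
        presence_rate = config$presence_rate
      ),
      sample_classes = samples[, c("sample_id", "true_class")]
    ),
    class = "ground_truth"
  )
  list(table = tab, truth = truth)
}

#' Generate a QC replicate intensity block
#'
#' QC replicates emulate independent preparations of one pooled
#' control-like plasma: per feature, `n_qc` raw intensities are drawn
#' log-normally around the control baseline mean with a coefficient of
#' variation sampled uniformly from `qc_cv_range` percent. Feature
#' parameters are shared with [generate_cohort()] at equal
#' `(config, seed)`.
#'
#' @inheritParams generate_cohort
#' @return Numeric matrix (`n_features` x `n_qc`), rownames = feature ids,
#'   colnames `QC01`, ..., with the drawn per-feature target CVs attached
#'   as attribute `"target_cv"`.
#' @export
generate_qc_block <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  if (config$n_qc < 2) {
    abort("n_qc must be >= 2: the QC coefficient of variation is ",
          "undefined for fewer than two replicates")
  }
  params <- draw_feature_params(config, seed)
  with_seed(derive_seed(seed, 37L), {
    n <- config$n_features
    cv <- stats::runif(n, config$qc_cv_range[1], config$qc_cv_range[2]) / 100
    pool_mean <- 10^params$mu_log10
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(pool_mean) - sdlog^2 / 2
    block <- matrix(
      stats::rlnorm(n * config$n_qc, meanlog = rep(meanlog, config$n_qc),
                    sdlog = rep(sdlog, config$n_qc)),
      nrow = n, ncol = config$n_qc,
      dimnames = list(params$feature_id,
                      sprintf("QC%02d", seq_len(config$n_qc)))
    )
    attr(block, "target_cv") <- cv * 100
    block
  })
}

#' Explode a feature table into per-sample peak lists
#'
#' Each sample's detected features become `(mass, rt, intensity)` peaks
#' with the mass perturbed uniformly within `±mz_jitter_ppm` and the
#' retention time within `±rt_jitter_min`. The generating feature id is
#' retained in a `source_feature` column so alignment can be scored
#' against provenance.
#'
#' @param table a [feature_table()] on the raw scale.
#' @param mz_jitter_ppm,rt_jitter_min non-negative jitter half-widths.
#' @param seed integer seed.
#' @return Named list (one data.frame per sample) with columns `mass`,
#'   `rt`, `intensity`, `source_feature`; sample labels attached as
#'   attribute `"sample_labels"`.
#' @export
generate_peak_lists <- function(table, mz_jitter_ppm = 5,
                                rt_jitter_min = 0.1, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (mz_jitter_ppm < 0 || rt_jitter_min < 0) {
    abort("jitters must be >= 0")
  }
  mat <- table$intensities
  with_seed(derive_seed(seed, 53L), {
    out <- lapply(seq_len(ncol(mat)), function(j) {
      present <- which(!is.na(mat[, j]))
      n <- length(present)
      mass0 <- table$features$neutral_mass[present]
      data.frame(
        mass = mass0 * (1 + stats::runif(n, -mz_jitter_ppm,
                                         mz_jitter_ppm) * 1e-6),
        rt = table$features$rt[present] +
          stats::runif(n, -rt_jitter_min, rt_jitter_min),
        intensity = mat[present, j],
        source_feature = table$features$feature_id[present]
      )
    })
    names(out) <- table$samples$sample_id
    attr(out, "sample_labels") <- stats::setNames(table$samples$label,
                                                  table$samples$sample_id)
    out
  })
}

#' Generate a synthetic MS/MS spectrum for a compound class
#'
#' Plants the diagnostic fragment peaks of the requested class (from
#' [default_fragment_rules()]) plus random decoy peaks that avoid every
#' rule window, so that [match_fragment_rules()] can be exercised with a
#' known answer. Class `"other"` produces decoys only.
#'
#' @param compound_class one of `"acylcarnitine"`, `"lysoPC"`, `"lysoPE"`,
#'   `"other"`.
#' @param precursor_mz precursor m/z; must exceed the largest diagnostic
#'   fragment of the class.
#' @param seed integer seed.
#' @param n_decoys number of decoy peaks.
#' @return An `msms_spectrum`: list with `precursor_mz` and `peaks`
#'   (data.frame `mz`, `intensity`).
#' @export
generate_msms_spectrum <- function(compound_class, precursor_mz, seed = 1L,
                                   n_decoys = 6) {
  compound_class <- match.arg(compound_class,
                              c("acylcarnitine", "lysoPC", "lysoPE", "other"))
  rules <- default_fragment_rules()
  diag_mz <- numeric()
  if (compound_class != "other") {
    rule <- rules[[compound_class]]
    diag_mz <- ifelse(rule$peaks$kind == "absolute", rule$peaks$value,
                      precursor_mz - rule$peaks$value)
    if (any(diag_mz >= precursor_mz) || any(diag_mz <= 0)) {
      abort("precursor_mz must exceed the largest diagnostic fragment of ",
            "class ", compound_class)
    }
  }
  if (precursor_mz <= 50) abort("precursor_mz must be > 50")

  # every window any rule could match, for this precursor, padded so decoys
  # can never confirm a class
  windows <- do.call(rbind, lapply(rules, function(r) {
    mz <- ifelse(r$peaks$kind == "absolute", r$peaks$value,
                 precursor_mz - r$peaks$value)
    cbind(lo = mz - r$peaks$tolerance - 0.05,
          hi = mz + r$peaks$tolerance + 0.05)
  }))

  with_seed(derive_seed(seed, 71L), {
    decoys <- numeric(0)
    guard <- 0L
    while (length(decoys) < n_decoys && guard < 10000L) {
      cand <- stats::runif(1, 50, precursor_mz - 1)
      if (!any(cand >= windows[, "lo"] & cand <= windows[, "hi"])) {
        decoys <- c(decoys, cand)
      }
      guard <- guard + 1L
    }
    peaks <- data.frame(
      mz = c(diag_mz, decoys),
      intensity = c(stats::runif(length(diag_mz), 5e3, 5e4),
                    stats::runif(length(decoys), 1e2, 5e3))
    )
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    structure(list(precursor_mz = precursor_mz, peaks = peaks),
              class = "msms_spectrum")
  })
}

#' Write / read a peak-list spectrum as two-column text
#'
#' Format: a `# precursor=<mz>` header line followed by whitespace-
#' delimited `mz intensity` rows.
#'
#' @param spectrum an `msms_spectrum`.
#' @param path file path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  lines <- c(
    sprintf("# precursor=%.6f", spectrum$precursor_mz),
    sprintf("%.6f %.4f", spectrum$peaks$mz, spectrum$peaks$intensity)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*precursor=", lines, value = TRUE)
  if (length(hdr) != 1) abort("spectrum file needs one '# precursor=' line")
  precursor <- as.numeric(sub("^#\\s*precursor=", "", hdr))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  vals <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  peaks <- data.frame(mz = vals[, 1], intensity = vals[, 2])
  if (any(peaks$mz <= 0) || any(peaks$intensity < 0)) {
    abort("spectrum peaks must have mz > 0 and intensity >= 0")
  }
  structure(list(precursor_mz = precursor, peaks = peaks),
            class = "msms_spectrum")
}
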