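#' Configuration of a full fingerprinting pipeline run
#'
#' @param synthetic a [synthetic_config()] or path to its YAML form; used
#'   when no `feature_table_path` is given.
#' @param feature_table_path optional CSV path of a real feature table
#'   (dialect of [write_feature_table()]); disables the synthetic stages
#'   that need ground truth.
#' @param out_dir directory for artifacts (created if needed).
#' @param min_count presence-filter threshold (default 10).
#' @param n_components PLS-DA components (default 2).
#' @param q2_folds cross-validation folds for Q2 (default 7).
#' @param seed master integer seed.
#' @param alpha significance level (default 0.05).
#' @param tol_ppm accurate-mass annotation window (default 15).
#' @param mz_tol fragment-rule m/z window (default 0.02).
#' @param margin prediction margin for the "between classes" report
#'   (default 0.1); accuracy bookkeeping always uses strict argmax.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       feature_table_path = NULL,
                       out_dir = tempfile("plasmafp_run_"),
                       min_count = 10, n_components = 2, q2_folds = 7,
                       seed = 1L, alpha = 0.05, tol_ppm = 15,
                       mz_tol = 0.02, margin = 0.1) {
  if (is.character(synthetic)) {
    if (!file.exists(synthetic)) {
      abort("synthetic config file not found: ", synthetic)
    }
    synthetic <- read_synthetic_config(synthetic)
  }
  if (!is.null(feature_table_path) && !file.exists(feature_table_path)) {
    abort("feature table file not found: ", feature_table_path)
  }
  structure(
    list(synthetic = synthetic, feature_table_path = feature_table_path,
         out_dir = out_dir, min_count = min_count,
         n_components = n_components, q2_folds = q2_folds,
         seed = as.integer(seed), alpha = alpha, tol_ppm = tol_ppm,
         mz_tol = mz_tol, margin = margin),
    class = "run_config"
  )
}

write_csv_artifact <- function(df, path) {
  utils::write.csv(format(as.data.frame(df), digits = 10, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

# Modeling matrix on the log10 scale: raw intensities of the selected
# samples, missing cells filled with half the per-feature minimum observed
# over the *reference* samples (the training set), then log10.
modeling_matrix <- function(table, sample_idx, reference_idx = sample_idx) {
  raw <- t(table$intensities[, sample_idx, drop = FALSE])
  ref <- t(table$intensities[, reference_idx, drop = FALSE])
  log10(impute_half_min(raw, reference = ref))
}

#' Run the full fingerprinting study at desk scale
#'
#' Executes, in order: (1) data acquisition (synthetic cohort + QC block,
#' or a feature-table file); (2) primary any-group presence filter over
#' the modeled classes; (3) three-class PLS-DA with Q2 cross-validation,
#' QC projection and leave-1/3-out validation; (4) prediction of the
#' held-out samples; (5) per-comparison secondary filter, Welch tests and
#' percent changes for C vs A, C vs S, A vs S; (6) two-class A-vs-C model
#' with validation and projection of all small-aneurysm samples; (7)
#' accurate-mass annotation of significant features. All tabular
#' artifacts are CSV, models and the manifest JSON; identical
#' `(config, seed)` reproduce identical analysis artifacts (the manifest
#' additionally records wall-clock timings).
#'
#' PLS-DA operates on log10 intensities with half-minimum imputation;
#' QC and prediction-only samples never influence filtering or model
#' fitting.
#'
#' @param config a [run_config()].
#' @return A `run_manifest` (invisibly written to
#'   `out_dir/manifest.json`): per-stage feature/sample counts, timing
#'   and the artifact inventory.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stages <- list()
  artifacts <- character(0)
  t0 <- proc.time()[["elapsed"]]

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest <- build_manifest(config, stages, artifacts, t0,
                                 failed_stage = name,
                                 error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$out_dir,
                                               "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      abort("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  log_stage <- function(name, ...) {
    stages[[name]] <<- list(...)
  }
  add_artifact <- function(path) artifacts <<- c(artifacts, basename(path))

  ## stage 1: acquire -------------------------------------------------
  truth <- NULL
  tab <- stage("acquire", {
    if (!is.null(config$feature_table_path)) {
      read_feature_table(config$feature_table_path)
    } else {
      gen <- generate_cohort(config$synthetic, seed)
      truth <- gen$truth
      qc <- generate_qc_block(config$synthetic, seed)
      bind_sample_block(gen$table, qc, label = "QC")
    }
  })
  add_artifact(write_feature_table(tab, file.path(config$out_dir,
                                                  "feature_table.csv")))
  if (!is.null(truth)) {
    add_artifact(write_csv_artifact(
      truth$features, file.path(config$out_dir, "ground_truth_features.csv")
    ))
    add_artifact(write_csv_artifact(
      truth$sample_classes,
      file.path(config$out_dir, "ground_truth_samples.csv")
    ))
  }
  log_stage("acquire", n_features = n_features(tab),
            n_samples = n_samples(tab))

  ## stage 2: primary filter ------------------------------------------
  filtered <- stage("primary_filter", {
    presence_filter(tab, config$min_count, "any_group",
                    intersect(c("C", "S", "A"), unique(tab$samples$label)))
  })
  add_artifact(write_feature_table(
    filtered, file.path(config$out_dir, "filtered_table.csv")
  ))
  log_stage("primary_filter", n_features = n_features(filtered),
            n_samples = n_samples(filtered))

  labels_all <- filtered$samples$label
  idx_model <- which(labels_all %in% c("C", "S", "A"))
  idx_qc <- which(labels_all == "QC")
  idx_extra <- which(labels_all == "P")

  ## stage 3: three-class model ---------------------------------------
  model3 <- q2_3 <- val3 <- qc_proj <- NULL
  stage("model_three_class", {
    x_model <- modeling_matrix(filtered, idx_model)
    lab_model <- labels_all[idx_model]
    model3 <- fit_plsda(x_model, lab_model, config$n_components)
    q2_3 <- q2_cross_validation(x_model, lab_model, config$n_components,
                                 config$q2_folds, derive_seed(seed, 301L))
    model3$q2 <- as.numeric(q2_3)
    val3 <- leave_third_out_validation(x_model, lab_model,
                                        config$n_components,
                                        derive_seed(seed, 302L))
    if (length(idx_qc) > 0) {
      x_qc <- modeling_matrix(filtered, idx_qc, reference_idx = idx_model)
      sc <- transform_scores(model3, x_qc)
      cent <- score_centroids(model3)
      nearest <- apply(sc, 1, function(v) {
        names(which.min(colSums((t(cent) - v)^2)))
      })
      qc_proj <- data.frame(
        sample_id = filtered$samples$sample_id[idx_qc],
        nearest_class = nearest,
        as.data.frame(sc)
      )
    }
  })
  add_artifact(write_plsda_model(
    model3, file.path(config$out_dir, "model3.json"), val3
  ))
  add_artifact(write_csv_artifact(
    data.frame(sample_id = filtered$samples$sample_id[idx_model],
               label = labels_all[idx_model],
               as.data.frame(model3$scores)),
    file.path(config$out_dir, "model3_scores.csv")
  ))
  if (!is.null(qc_proj)) {
    add_artifact(write_csv_artifact(
      qc_proj, file.path(config$out_dir, "qc_projection.csv")
    ))
  }
  log_stage("model_three_class",
            r2y = model3$r2y[config$n_components],
            q2 = model3$q2[config$n_components],
            loto_mean_accuracy = val3$mean_accuracy,
            loto_sd_accuracy = val3$sd_accuracy,
            qc_projected = length(idx_qc))

  ## stage 4: extras prediction ---------------------------------------
  extras_pred <- NULL
  stage("extras_prediction", {
    if (length(idx_extra) > 0) {
      x_extra <- modeling_matrix(filtered, idx_extra,
                                 reference_idx = idx_model)
      pred <- predict_classes(model3, x_extra, margin = config$margin)
      strict <- predict_classes(model3, x_extra, margin = 0)
      pred$assigned_strict <- strict$assigned
      if (!is.null(truth)) {
        tc <- truth$sample_classes
        pred$true_class <- tc$true_class[match(pred$sample_id,
                                               tc$sample_id)]
        pred$correct_strict <- pred$assigned_strict == pred$true_class
      }
      extras_pred <- pred
    }
  })
  if (!is.null(extras_pred)) {
    add_artifact(write_csv_artifact(
      extras_pred, file.path(config$out_dir, "extras_predictions.csv")
    ))
  }
  log_stage("extras_prediction",
            n_predicted = length(idx_extra),
            n_correct_strict = if (!is.null(extras_pred) &&
                                   "correct_strict" %in% names(extras_pred)) {
              sum(extras_pred$correct_strict)
            } else {
              NA
            })

  ## stage 5: univariate comparisons ----------------------------------
  comparisons <- stage("comparisons", {
    pairs <- list(c("A", "C"), c("S", "C"), c("A", "S"))
    out <- lapply(pairs, function(pr) {
      compare_groups(filtered, pr[1], pr[2], config$min_count,
                     config$alpha)
    })
    names(out) <- vapply(pairs, paste, "", collapse = "_vs_")
    out
  })
  for (nm in names(comparisons)) {
    add_artifact(write_csv_artifact(
      comparisons[[nm]], file.path(config$out_dir,
                                   sprintf("comparison_%s.csv", nm))
    ))
  }
  log_stage("comparisons",
            n_tested = vapply(comparisons, nrow, 0L),
            n_significant = vapply(comparisons, attr, 0L, "n_significant"))

  ## stage 6: two-class model + small-AAA projection ------------------
  model2 <- val2 <- s_proj <- NULL
  stage("model_two_class", {
    idx_ac <- which(labels_all %in% c("A", "C"))
    x_ac <- modeling_matrix(filtered, idx_ac)
    lab_ac <- labels_all[idx_ac]
    model2 <- fit_plsda(x_ac, lab_ac, config$n_components)
    model2$q2 <- as.numeric(
      q2_cross_validation(x_ac, lab_ac, config$n_components,
                          config$q2_folds, derive_seed(seed, 601L))
    )
    val2 <- leave_third_out_validation(x_ac, lab_ac, config$n_components,
                                        derive_seed(seed, 602L))
    idx_s <- which(labels_all == "S")
    if (!is.null(truth)) {
      extra_s <- filtered$samples$sample_id[idx_extra][
        truth$sample_classes$true_class[
          match(filtered$samples$sample_id[idx_extra],
                truth$sample_classes$sample_id)] == "S"]
      idx_s <- c(idx_s, which(filtered$samples$sample_id %in% extra_s))
    }
    if (length(idx_s) > 0) {
      x_s <- modeling_matrix(filtered, idx_s, reference_idx = idx_ac)
      sc <- transform_scores(model2, x_s)
      cent <- score_centroids(model2)
      between <- sc[, 1] > min(cent[, 1]) & sc[, 1] < max(cent[, 1])
      s_proj <- data.frame(
        sample_id = filtered$samples$sample_id[idx_s],
        as.data.frame(sc),
        between_centroids_t1 = between
      )
    }
  })
  add_artifact(write_plsda_model(
    model2, file.path(config$out_dir, "model2.json"), val2
  ))
  if (!is.null(s_proj)) {
    add_artifact(write_csv_artifact(
      s_proj, file.path(config$out_dir, "s_projection.csv")
    ))
  }
  log_stage("model_two_class",
            r2y = model2$r2y[config$n_components],
            q2 = model2$q2[config$n_components],
            loto_mean_accuracy = val2$mean_accuracy,
            loto_sd_accuracy = val2$sd_accuracy,
            n_s_projected = if (is.null(s_proj)) 0L else nrow(s_proj),
            frac_s_between = if (is.null(s_proj)) {
              NA
            } else {
              mean(s_proj$between_centroids_t1)
            })

  ## stage 7: annotation ----------------------------------------------
  annotations <- stage("annotation", {
    db <- default_compound_db()
    out <- lapply(comparisons, function(res) {
      annotate_results(res, tab, db, tol_ppm = config$tol_ppm,
                       mz_tol = config$mz_tol, alpha = config$alpha)
    })
    out
  })
  for (nm in names(annotations)) {
    add_artifact(write_csv_artifact(
      annotations[[nm]], file.path(config$out_dir,
                                   sprintf("annotation_%s.csv", nm))
    ))
  }
  log_stage("annotation",
            n_annotated = vapply(annotations, nrow, 0L),
            n_identified = vapply(annotations, function(a) {
              sum(a$compound != "unknown")
            }, 0L))

  manifest <- build_manifest(config, stages, artifacts, t0)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(
    list(manifest = manifest, table = tab, filtered = filtered,
         truth = truth, model3 = model3, validation3 = val3,
         qc_projection = qc_proj, extras = extras_pred,
         comparisons = comparisons, model2 = model2, validation2 = val2,
         s_projection = s_proj, annotations = annotations,
         out_dir = config$out_dir),
    class = "pipeline_result"
  ))
}

score_centroids <- function(model) {
  lv <- model$labels
  cent <- t(vapply(lv, function(g) {
    colMeans(model$scores[model$sample_labels == g, , drop = FALSE])
  }, numeric(model$n_components)))
  rownames(cent) <- lv
  cent
}

build_manifest <- function(config, stages, artifacts, t0,
                           failed_stage = NULL, error = NULL) {
  list(
    package = "plasmafp",
    version = as.character(utils::packageVersion("plasmafp")),
    seed = config$seed,
    config = list(
      min_count = config$min_count, n_components = config$n_components,
      q2_folds = config$q2_folds, alpha = config$alpha,
      tol_ppm = config$tol_ppm, mz_tol = config$mz_tol,
      margin = config$margin,
      input = if (is.null(config$feature_table_path)) {
        "synthetic"
      } else {
        config$feature_table_path
      }
    ),
    stages = stages,
    n_stages_completed = length(stages),
    failed_stage = failed_stage,
    error = error,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
    artifacts = artifacts
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$manifest$n_stages_completed,
      "stages completed ->", x$out_dir, "\n")
  cat(sprintf("  features: %d aligned, %d after primary filter\n",
              x$manifest$stages$acquire$n_features,
              x$manifest$stages$primary_filter$n_features))
  cat(sprintf("  3-class leave-1/3-out accuracy: %.1f +/- %.1f %%\n",
              x$validation3$mean_accuracy, x$validation3$sd_accuracy))
  cat(sprintf("  2-class (A vs C) accuracy: %.1f +/- %.1f %%\n",
              x$validation2$mean_accuracy, x$validation2$sd_accuracy))
  invisible(x)
}

#' Format identification-style report tables
#'
#' Joins each comparison's significant features to their annotations and
#' emits one table per comparison with the classic identification-table
#' column set: compound, retention time, measured mass, mass error,
#' percent change with p-value, and QC coefficient of variation.
#'
#' @param results named list of `comparison_result`s.
#' @param annotations named list of `annotation_report`s (same names).
#' @return Named list of data.frames, with per-comparison significant
#'   counts attached as attribute `"n_significant"`.
#' @export
report_tables <- function(results, annotations) {
  stopifnot(identical(names(results), names(annotations)))
  out <- lapply(names(results), function(nm) {
    ann <- annotations[[nm]]
    df <- data.frame(
      compound = ann$compound,
      feature_id = ann$feature_id,
      rt_min = round(ann$rt_min, 1),
      measured_mass_da = round(ann$measured_mass_da, 3),
      mass_error_ppm = round(ann$ppm_error, 1),
      change_pct = round(ann$pct_change),
      p_value = signif(ann$p, 2),
      cv_qc_pct = round(ann$cv_qc_percent)
    )
    rownames(df) <- NULL
    df
  })
  names(out) <- names(results)
  attr(out, "n_significant") <- vapply(results, attr, 0L, "n_significant")
  out
}
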