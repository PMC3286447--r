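group_presence_counts <- function(table, groups) {
  mat <- !is.na(table$intensities)
  out <- lapply(groups, function(g) {
    cols <- table$samples$label == g
    rowSums(mat[, cols, drop = FALSE])
  })
  matrix(unlist(out), nrow = n_features(table),
         dimnames = list(NULL, groups))
}

#' Filter features by per-group detection counts
#'
#' Mirrors the two filters of the fingerprinting workflow: the primary
#' filter keeps features detected in at least `min_count` samples of *any*
#' listed group; the secondary (per-comparison) filter requires
#' `min_count` detections in *every* listed group. Sample columns and
#' feature order are unchanged.
#'
#' @param table a [feature_table()].
#' @param min_count minimum number of samples a feature must be detected
#'   in (default 10).
#' @param scope `"any_group"` or `"per_group"`.
#' @param groups class labels over which counts are taken; defaults to the
#'   modeled classes present among `C`, `S`, `A`.
#' @return The filtered `feature_table`.
#' @export
presence_filter <- function(table, min_count = 10,
                            scope = c("any_group", "per_group"),
                            groups = NULL) {
  stopifnot(inherits(table, "feature_table"))
  scope <- match.arg(scope)
  if (!is_count(min_count)) abort("min_count must be a count >= 0")
  groups <- groups %||% intersect(c("C", "S", "A"),
                                  unique(table$samples$label))
  unknown <- setdiff(groups, unique(table$samples$label))
  if (length(unknown) > 0) {
    abort("group label(s) not in table: ", paste(unknown, collapse = ", "))
  }
  counts <- group_presence_counts(table, groups)
  keep <- if (scope == "any_group") {
    apply(counts >= min_count, 1, any)
  } else {
    apply(counts >= min_count, 1, all)
  }
  feature_table(table$features[keep, , drop = FALSE], table$samples,
                table$intensities[keep, , drop = FALSE],
                scale = attr(table, "scale"))
}

#' Common-logarithm transform of a feature table
#'
#' Replaces every detected intensity by its base-10 logarithm, the
#' transform used to bring log-normal LC-MS intensities close to
#' normality before univariate testing. Missing cells stay missing.
#'
#' @param table a raw-scale [feature_table()]; all detected intensities
#'   must be positive.
#' @return A `feature_table` on the log10 scale.
#' @export
log10_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (attr(table, "scale") == "log10") {
    abort("table is already log10-transformed")
  }
  bad <- which(table$intensities <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "nonpositive intensity for feature %s in sample %s",
      table$features$feature_id[bad[1, 1]],
      table$samples$sample_id[bad[1, 2]]
    ))
  }
  feature_table(table$features, table$samples, log10(table$intensities),
                scale = "log10")
}

#' Welch's unequal-variance two-sample t test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`:
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' Missing values are dropped pairwise.
#'
#' @param x,y numeric vectors; each needs at least 2 non-missing values
#'   and the two groups must not be jointly constant.
#' @return List with `t`, `df`, `p`, `n_x`, `n_y`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs >= 2 non-missing values")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      # identical constant groups: no evidence of difference
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  n_x = length(x), n_y = length(y)))
    }
    abort("zero variance in both groups; Welch statistic undefined")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, n_x = length(x), n_y = length(y))
}

#' Percent change between group means on the raw intensity scale
#'
#' `(mean(x)/mean(y) - 1) * 100`, missing entries excluded; positive means
#' higher abundance in `x` than in the reference `y`.
#'
#' @param x raw-scale intensities of the comparison group.
#' @param y raw-scale intensities of the reference group; `mean(y)` must
#'   be positive.
#' @return Percent change (a number > -100 for positive data).
#' @export
percent_change <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("percent_change needs non-empty groups")
  }
  if (mean(y) <= 0) abort("reference group mean must be > 0")
  (mean(x) / mean(y) - 1) * 100
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector, 3 to 5000 non-missing values, not constant.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort("shapiro_wilk needs 3 to 5000 non-missing values")
  }
  if (stats::var(x) == 0) abort("shapiro_wilk undefined for constant input")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Coefficient of variation of QC replicate intensities
#'
#' `100 * sd(x) / mean(x)` on raw intensities, with the n-1 standard
#' deviation. Returns `NA` (undefined-CV marker) when fewer than two
#' non-missing replicates are available or the mean is not positive.
#'
#' @param x raw-scale QC intensities of one feature.
#' @return CV in percent, or `NA_real_`.
#' @export
qc_cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2 || mean(x) <= 0) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

#' Per-feature QC coefficients of variation
#'
#' @param x a raw-scale [feature_table()] containing `QC`-labelled
#'   samples, or a numeric matrix of QC intensities (features in rows).
#' @return data.frame with `feature_id` and `cv_percent`.
#' @export
qc_metrics <- function(x) {
  if (inherits(x, "feature_table")) {
    if (attr(x, "scale") != "raw") abort("qc_metrics needs raw intensities")
    qc_cols <- x$samples$label == "QC"
    if (!any(qc_cols)) abort("table has no QC samples")
    mat <- x$intensities[, qc_cols, drop = FALSE]
    ids <- x$features$feature_id
  } else {
    mat <- as.matrix(x)
    ids <- rownames(mat) %||% sprintf("F%04d", seq_len(nrow(mat)))
  }
  data.frame(
    feature_id = ids,
    cv_percent = apply(mat, 1, qc_cv)
  )
}

#' Two-group univariate comparison of a feature table
#'
#' Applies the per-comparison presence filter (`min_count` detections in
#' each of the two groups), log10-transforms, runs Welch's t test per
#' feature on the transformed intensities, and computes the percent change
#' of group means on the raw scale. Features with insufficient data are
#' skipped with a recorded reason. Benjamini-Hochberg q-values are
#' appended as a supplementary column; the significance count uses the
#' raw p-values.
#'
#' @param table a raw-scale [feature_table()].
#' @param group_a,group_b class labels; the percent change is
#'   `group_a` relative to `group_b`.
#' @param min_count per-group presence threshold (default 10).
#' @param alpha significance level for the reported count (default 0.05).
#' @return data.frame of class `comparison_result`, sorted by p ascending,
#'   with columns `feature_id`, `neutral_mass_da`, `rt_min`, `pct_change`,
#'   `t`, `df`, `p`, `q`, `n_a`, `n_b`. Attributes: `n_significant`,
#'   `alpha`, `groups`, `skipped` (data.frame of skipped features and
#'   reasons).
#' @export
compare_groups <- function(table, group_a, group_b, min_count = 10,
                           alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (attr(table, "scale") != "raw") {
    abort("compare_groups expects raw intensities")
  }
  present <- unique(table$samples$label)
  if (!all(c(group_a, group_b) %in% present)) {
    abort("both group labels must be present in the table")
  }
  filtered <- if (group_a == group_b) {
    presence_filter(table, min_count, "per_group", group_a)
  } else {
    presence_filter(table, min_count, "per_group", c(group_a, group_b))
  }
  raw <- filtered$intensities
  cols_a <- filtered$samples$label == group_a
  cols_b <- filtered$samples$label == group_b

  rows <- vector("list", n_features(filtered))
  skipped <- list()
  for (i in seq_len(n_features(filtered))) {
    xa <- raw[i, cols_a]
    xb <- raw[i, cols_b]
    res <- tryCatch(
      welch_t_test(log10(xa), log10(xb)),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        feature_id = filtered$features$feature_id[i], reason = res
      )
      next
    }
    rows[[i]] <- data.frame(
      feature_id = filtered$features$feature_id[i],
      neutral_mass_da = filtered$features$neutral_mass[i],
      rt_min = filtered$features$rt[i],
      pct_change = percent_change(xa, xb),
      t = res$t, df = res$df, p = res$p,
      n_a = res$n_x, n_b = res$n_y
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(
      feature_id = character(), neutral_mass_da = numeric(),
      rt_min = numeric(), pct_change = numeric(), t = numeric(),
      df = numeric(), p = numeric(), n_a = integer(), n_b = integer()
    )
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$feature_id),
             c("feature_id", "neutral_mass_da", "rt_min", "pct_change",
               "t", "df", "p", "q", "n_a", "n_b")]
  rownames(out) <- NULL
  structure(
    out,
    n_significant = sum(out$p <= alpha),
    alpha = alpha,
    groups = c(group_a, group_b),
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    class = c("comparison_result", "data.frame")
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf(
    "<comparison_result> %s vs %s: %d features tested, %d with p <= %g\n",
    g[1], g[2], nrow(x), attr(x, "n_significant"), attr(x, "alpha")
  ))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
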