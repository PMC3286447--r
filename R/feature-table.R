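#' Sample class labels understood by the pipeline
#'
#' `C` control, `S` small aneurysm, `A` large aneurysm, `QC` pooled-plasma
#' quality-control replicate, `P` prediction-only sample (held out of all
#' modeling and filtering decisions).
#'
#' @export
CLASS_LABELS <- c("C", "S", "A", "QC", "P")

#' Construct an aligned LC-MS feature table
#'
#' The central exchange object of the pipeline: a set of aligned features
#' (neutral mass, retention time) with one intensity per sample. Missing
#' cells (`NA`) mean "feature not detected in that sample", never zero.
#'
#' @param features data.frame with columns `feature_id`, `neutral_mass`
#'   (Da, > 0) and `rt` (minutes, >= 0).
#' @param samples data.frame with columns `sample_id` and `label`
#'   (one of [CLASS_LABELS]).
#' @param intensities numeric matrix, rows = features, columns = samples;
#'   non-detected cells are `NA`; detected intensities must be positive.
#' @param scale `"raw"` or `"log10"`; bookkeeping for [log10_transform()].
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, samples, intensities, scale = "raw") {
  stopifnot(is.data.frame(features), is.data.frame(samples))
  req_f <- c("feature_id", "neutral_mass", "rt")
  if (!all(req_f %in% names(features))) {
    abort("`features` needs columns: ", paste(req_f, collapse = ", "))
  }
  req_s <- c("sample_id", "label")
  if (!all(req_s %in% names(samples))) {
    abort("`samples` needs columns: ", paste(req_s, collapse = ", "))
  }
  bad <- setdiff(unique(samples$label), CLASS_LABELS)
  if (length(bad) > 0) {
    abort("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids")
  if (anyDuplicated(features$feature_id)) abort("duplicate feature ids")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features) ||
      ncol(intensities) != nrow(samples)) {
    abort("intensity matrix must be n_features x n_samples")
  }
  if (any(features$neutral_mass <= 0)) abort("neutral_mass must be > 0")
  if (any(features$rt < 0)) abort("rt must be >= 0")
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- samples$sample_id
  structure(
    list(features = features, samples = samples, intensities = intensities),
    scale = match.arg(scale, c("raw", "log10")),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(factor(x$samples$label, levels = CLASS_LABELS))
  cat(sprintf(
    "<feature_table> %d features x %d samples (%s scale)\n",
    nrow(x$features), nrow(x$samples), attr(x, "scale")
  ))
  cat("  samples per class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  missing cells: %.1f%%\n",
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Extract the intensity matrix of a feature table
#'
#' @param x a `feature_table`.
#' @return Numeric matrix (features x samples) with `NA` for non-detected
#'   cells.
#' @export
intensities <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  x$intensities
}

#' Number of features / samples
#' @param x a `feature_table`.
#' @export
n_features <- function(x) nrow(x$features)

#' @rdname n_features
#' @export
n_samples <- function(x) nrow(x$samples)

#' Subset a feature table by sample
#'
#' @param x a `feature_table`.
#' @param labels keep samples whose class label is in this set, or
#' @param sample_ids keep these sample ids (overrides `labels`).
#' @return A `feature_table` with the selected sample columns.
#' @export
select_samples <- function(x, labels = NULL, sample_ids = NULL) {
  stopifnot(inherits(x, "feature_table"))
  keep <- if (!is.null(sample_ids)) {
    x$samples$sample_id %in% sample_ids
  } else {
    x$samples$label %in% labels
  }
  feature_table(x$features, x$samples[keep, , drop = FALSE],
                x$intensities[, keep, drop = FALSE],
                scale = attr(x, "scale"))
}

#' Append sample columns (e.g. a QC block) to a feature table
#'
#' @param x a `feature_table`.
#' @param block numeric matrix with `n_features(x)` rows.
#' @param label class label for the appended samples.
#' @param sample_ids optional ids; defaults to the block's column names.
#' @return A `feature_table` with the extra columns appended.
#' @export
bind_sample_block <- function(x, block, label, sample_ids = NULL) {
  stopifnot(inherits(x, "feature_table"))
  block <- as.matrix(block)
  if (nrow(block) != n_features(x)) {
    abort("block must have one row per feature")
  }
  ids <- sample_ids %||% colnames(block) %||%
    sprintf("%s%02d", label, seq_len(ncol(block)))
  samples <- rbind(
    x$samples[, c("sample_id", "label")],
    data.frame(sample_id = ids, label = label)
  )
  feature_table(x$features, samples, cbind(x$intensities, block),
                scale = attr(x, "scale"))
}

#' Write a feature table as delimited text
#'
#' Layout: columns `feature_id`, `neutral_mass_da`, `rt_min`, then one
#' column per sample, the header carrying `sample_id|label`; missing cells
#' are written empty.
#'
#' @param x a `feature_table`.
#' @param path output file path.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  out <- data.frame(
    feature_id = x$features$feature_id,
    neutral_mass_da = sprintf("%.6f", x$features$neutral_mass),
    rt_min = sprintf("%.4f", x$features$rt),
    check.names = FALSE
  )
  mat <- x$intensities
  cols <- apply(mat, 2, function(v) {
    ifelse(is.na(v), "", sprintf("%.8g", v))
  })
  cols <- as.data.frame(cols, check.names = FALSE)
  names(cols) <- paste(x$samples$sample_id, x$samples$label, sep = "|")
  utils::write.csv(cbind(out, cols), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' Sample columns whose header lacks a `|label` suffix are taken as
#' prediction-only (`P`).
#'
#' @param path CSV file path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  req <- c("feature_id", "neutral_mass_da", "rt_min")
  if (!all(req %in% names(raw))) {
    abort("feature table file must start with columns: ",
          paste(req, collapse = ", "))
  }
  sample_cols <- setdiff(names(raw), req)
  parts <- strsplit(sample_cols, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  labels <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "P", "")
  mat <- vapply(sample_cols, function(cn) {
    v <- raw[[cn]]
    ifelse(v == "", NA_real_, as.numeric(v))
  }, numeric(nrow(raw)))
  mat <- matrix(mat, nrow = nrow(raw),
                dimnames = list(raw$feature_id, ids))
  feature_table(
    data.frame(
      feature_id = raw$feature_id,
      neutral_mass = as.numeric(raw$neutral_mass_da),
      rt = as.numeric(raw$rt_min)
    ),
    data.frame(sample_id = ids, label = labels),
    mat
  )
}
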