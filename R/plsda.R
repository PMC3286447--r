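#' Dummy (one-hot) class encoding for PLS-DA
#'
#' @param labels character vector of class labels (at least two distinct).
#' @return A `class_encoding`: list with `labels` (sorted unique) and
#'   `indicator` (n x k 0/1 matrix, one column per class; each row sums
#'   to 1).
#' @export
encode_classes <- function(labels) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) < 2) abort("need at least 2 distinct class labels")
  y <- matrix(0, length(labels), length(lv),
              dimnames = list(NULL, lv))
  y[cbind(seq_along(labels), match(labels, lv))] <- 1
  structure(list(labels = lv, indicator = y), class = "class_encoding")
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares regression of the one-hot class indicator matrix
#' on the feature matrix, components extracted one at a time by the
#' NIPALS iteration with deflation of both blocks. `X` is always
#' mean-centered; unit-variance scaling is off by default (the usual
#' convention for "no scaling" in chemometrics software, where centering
#' is retained). The sign of each weight vector is fixed by making its
#' largest-magnitude entry positive.
#'
#' @param X numeric matrix, samples x features, no missing values (impute
#'   upstream, e.g. with [impute_half_min()]).
#' @param labels class label per row of `X`.
#' @param n_components number of components (default 2); at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param scaling `"none"` (default) or `"unit_variance"`.
#' @param max_iter,tol NIPALS iteration cap and relative score-change
#'   convergence tolerance. Each iteration is two matrix-vector products,
#'   so the cap is generous: it is only approached when the leading
#'   eigenvalues of the class covariance are nearly degenerate (e.g. on
#'   label-permuted data), where power-type iterations converge slowly.
#' @return A `plsda_model`: weights `W`, loadings `P`, scores `T`,
#'   y-loadings `C` (one column per component), centering/scaling vectors,
#'   cumulative `r2x`/`r2y`, class labels and training metadata. `q2` is
#'   `NULL` until filled by [q2_cross_validation()].
#' @export
fit_plsda <- function(X, labels, n_components = 2,
                      scaling = c("none", "unit_variance"),
                      max_iter = 20000L, tol = 1e-10) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (anyNA(X)) {
    abort("X contains missing values; impute before fitting ",
          "(see impute_half_min)")
  }
  n <- nrow(X)
  p <- ncol(X)
  if (length(labels) != n) abort("labels must match rows of X")
  if (!is_count(n_components, 1) || n_components > min(n - 1, p)) {
    abort("n_components must be in 1..min(nrow(X)-1, ncol(X))")
  }
  enc <- encode_classes(labels)
  y0 <- enc$indicator
  k <- ncol(y0)

  x_mean <- colMeans(X)
  scale_vec <- if (scaling == "unit_variance") {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else {
    rep(1, p)
  }
  y_mean <- colMeans(y0)
  Xc <- sweep(sweep(X, 2, x_mean), 2, scale_vec, "/")
  Yc <- sweep(y0, 2, y_mean)
  ssx0 <- sum(Xc^2)
  ssy0 <- sum(Yc^2)

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  Cm <- matrix(0, k, n_components)
  r2x <- numeric(n_components)
  r2y <- numeric(n_components)

  Xa <- Xc
  Ya <- Yc
  for (a in seq_len(n_components)) {
    u <- Ya[, which.max(colSums(Ya^2))]
    if (sum(u^2) < .Machine$double.eps) {
      abort("component ", a, ": response residual variance exhausted")
    }
    t_old <- rep(0, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xa, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t_new <- Xa %*% w
      cc <- crossprod(Ya, t_new) / sum(t_new^2)
      u <- Ya %*% cc / sum(cc^2)
      if (sqrt(sum((t_new - t_old)^2) / sum(t_new^2)) < tol) {
        converged <- TRUE
        break
      }
      t_old <- t_new
    }
    if (!converged) {
      abort("NIPALS did not converge for component ", a,
            " within ", max_iter, " iterations")
    }
    # sign convention: dominant weight entry positive
    j <- which.max(abs(w))
    if (w[j] < 0) {
      w <- -w
      t_new <- -t_new
      cc <- -cc
    }
    p_load <- crossprod(Xa, t_new) / sum(t_new^2)
    Xa <- Xa - tcrossprod(t_new, p_load)
    Ya <- Ya - tcrossprod(t_new, cc)
    W[, a] <- w
    P[, a] <- p_load
    Tm[, a] <- t_new
    Cm[, a] <- cc
    r2x[a] <- 1 - sum(Xa^2) / ssx0
    r2y[a] <- 1 - sum(Ya^2) / ssy0
  }
  rotation <- W %*% solve(crossprod(P, W))
  dimnames(Tm) <- list(rownames(X), paste0("t", seq_len(n_components)))
  structure(
    list(
      n_components = n_components,
      x_mean = x_mean, scale_vector = scale_vec, y_mean = y_mean,
      weights = W, loadings = P, scores = Tm, y_loadings = Cm,
      rotation = rotation,
      r2x = r2x, r2y = r2y, q2 = NULL,
      labels = enc$labels, sample_labels = as.character(labels),
      feature_names = colnames(X), scaling = scaling
    ),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "<plsda_model> %d classes (%s), %d components, %d features\n",
    length(x$labels), paste(x$labels, collapse = "/"),
    x$n_components, length(x$x_mean)
  ))
  cat("  cumulative R2X:", sprintf("%.3f", x$r2x), "\n")
  cat("  cumulative R2Y:", sprintf("%.3f", x$r2y), "\n")
  if (!is.null(x$q2)) cat("  cumulative Q2: ", sprintf("%.3f", x$q2), "\n")
  invisible(x)
}

check_new_x <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_mean)) {
    abort("X_new has ", ncol(X_new), " features; model expects ",
          length(model$x_mean))
  }
  if (anyNA(X_new)) {
    abort("X_new contains missing values; impute before projection")
  }
  X_new
}

#' Project new samples into a fitted PLS-DA score space
#'
#' Applies the model's centering/scaling and the `W (P'W)^-1` rotation;
#' training samples reproduce the stored scores.
#'
#' @param model a `plsda_model`.
#' @param X_new numeric matrix (samples x features), feature count
#'   matching the model.
#' @return Score matrix (samples x components).
#' @export
transform_scores <- function(model, X_new) {
  stopifnot(inherits(model, "plsda_model"))
  X_new <- check_new_x(model, X_new)
  Xc <- sweep(sweep(X_new, 2, model$x_mean), 2, model$scale_vector, "/")
  scores <- Xc %*% model$rotation
  dimnames(scores) <- list(rownames(X_new),
                           paste0("t", seq_len(model$n_components)))
  scores
}

#' Predict class membership of new samples
#'
#' Computes the fitted indicator response `y_hat` for each sample and
#' assigns the class with the largest response. When the top two
#' responses differ by less than `margin` the sample is reported as
#' `"unassigned"` — the formalization of a sample "classified between"
#' two groups on the score plot.
#'
#' @inheritParams transform_scores
#' @param margin minimum lead of the best class response over the
#'   runner-up (default 0 = strict argmax).
#' @return data.frame of class `plsda_prediction`: `sample_id`,
#'   `assigned`, one `y.<class>` column per class and one `t<i>` score
#'   column per component.
#' @export
predict_classes <- function(model, X_new, margin = 0) {
  stopifnot(inherits(model, "plsda_model"), margin >= 0)
  scores <- transform_scores(model, X_new)
  y_hat <- sweep(scores %*% t(model$y_loadings), 2, model$y_mean, "+")
  colnames(y_hat) <- model$labels
  assigned <- apply(y_hat, 1, function(v) {
    o <- order(v, decreasing = TRUE)
    if (length(v) > 1 && v[o[1]] - v[o[2]] < margin) "unassigned"
    else model$labels[o[1]]
  })
  out <- data.frame(
    sample_id = rownames(X_new) %||% seq_len(nrow(y_hat)),
    assigned = assigned
  )
  yh <- as.data.frame(y_hat)
  names(yh) <- paste0("y.", model$labels)
  out <- cbind(out, yh, as.data.frame(scores))
  rownames(out) <- NULL
  class(out) <- c("plsda_prediction", "data.frame")
  out
}

stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- ((seq_along(idx) - 1L) %% n_folds) + 1L
    }
    fold
  })
}

#' Cumulative Q2 by class-stratified venetian-blind cross-validation
#'
#' `Q2(a) = 1 - PRESS(a)/SS`, where `PRESS(a)` accumulates squared
#' indicator-prediction errors of samples left out fold by fold
#' (predicted by a model refitted without them, truncated to `a`
#' components) and `SS` is the total centered indicator sum of squares.
#' Fold assignment takes every `n_folds`-th sample of each class after a
#' seeded shuffle; an assignment that would leave a training set without
#' some class is re-drawn (at most 10 attempts).
#'
#' @inheritParams fit_plsda
#' @param n_folds number of folds (default 7), between 2 and `nrow(X)`.
#' @param seed integer seed for the fold shuffle.
#' @return Numeric vector of cumulative Q2 per component; fold assignment
#'   attached as attribute `"folds"`.
#' @export
q2_cross_validation <- function(X, labels, n_components = 2, n_folds = 7,
                                seed = 1L,
                                scaling = c("none", "unit_variance")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (!is_count(n_folds, 2) || n_folds > nrow(X)) {
    abort("n_folds must be between 2 and the number of samples")
  }
  enc <- encode_classes(labels)
  y0 <- enc$indicator
  SS <- sum(sweep(y0, 2, colMeans(y0))^2)

  fold <- NULL
  for (attempt in seq_len(10)) {
    cand <- stratified_folds(labels, n_folds, derive_seed(seed, attempt))
    ok <- all(vapply(seq_len(n_folds), function(f) {
      length(unique(labels[cand != f])) == length(enc$labels)
    }, TRUE))
    if (ok) {
      fold <- cand
      break
    }
    message("refolding Q2 cross-validation: a training set lost a class")
  }
  if (is.null(fold)) {
    abort("could not build folds keeping every class in training ",
          "after 10 attempts")
  }

  press <- numeric(n_components)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    m <- fit_plsda(X[!test, , drop = FALSE], labels[!test],
                   n_components = n_components, scaling = scaling)
    scores <- transform_scores(m, X[test, , drop = FALSE])
    y_test <- y0[test, enc$labels, drop = FALSE]
    for (a in seq_len(n_components)) {
      y_hat <- sweep(
        scores[, seq_len(a), drop = FALSE] %*%
          t(m$y_loadings[, seq_len(a), drop = FALSE]),
        2, m$y_mean, "+"
      )
      # columns of y_hat follow the training label order, which equals the
      # full label order because every class is retained in training
      press[a] <- press[a] + sum((y_test - y_hat)^2)
    }
  }
  q2 <- 1 - press / SS
  attr(q2, "folds") <- fold
  q2
}

#' Leave-one-third-out classification validation
#'
#' Repeatedly excludes a random class-stratified third of the samples,
#' refits the model on the remaining two thirds, and predicts the
#' excluded third by strict argmax, recording the percentage classified
#' correctly. Repetitions continue until every sample has been excluded
#' at least once (minimum 3 repetitions).
#'
#' @inheritParams fit_plsda
#' @param seed integer seed for the stratified splits.
#' @param min_reps minimum number of repetitions (default 3).
#' @param max_reps safety cap on repetitions.
#' @return A `plsda_validation`: list with `repetitions`, `accuracy`
#'   (percent correct per repetition), `mean_accuracy`, `sd_accuracy`,
#'   `coverage` (per-sample exclusion counts, all >= 1) and `confusion`
#'   (true x assigned tally over all repetitions).
#' @export
leave_third_out_validation <- function(X, labels, n_components = 2,
                                       seed = 1L, min_reps = 3L,
                                       max_reps = 100L,
                                       scaling = c("none", "unit_variance")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  labels <- as.character(labels)
  class_sizes <- table(labels)
  if (any(class_sizes < 3)) {
    abort("every class needs >= 3 samples for leave-1/3-out validation")
  }
  n <- nrow(X)
  coverage <- stats::setNames(integer(n),
                              rownames(X) %||% as.character(seq_len(n)))
  accuracy <- numeric(0)
  lv <- sort(unique(labels))
  confusion <- matrix(0L, length(lv), length(lv) + 1L,
                      dimnames = list(true = lv,
                                      assigned = c(lv, "unassigned")))
  rep_i <- 0L
  while (rep_i < max_reps) {
    rep_i <- rep_i + 1L
    excluded <- with_seed(derive_seed(seed, 1000L + rep_i), {
      unlist(lapply(lv, function(g) {
        idx <- which(labels == g)
        sample(idx, ceiling(length(idx) / 3))
      }), use.names = FALSE)
    })
    m <- fit_plsda(X[-excluded, , drop = FALSE], labels[-excluded],
                   n_components = n_components, scaling = scaling)
    pred <- predict_classes(m, X[excluded, , drop = FALSE], margin = 0)
    correct <- pred$assigned == labels[excluded]
    accuracy <- c(accuracy, 100 * mean(correct))
    coverage[excluded] <- coverage[excluded] + 1L
    for (i in seq_along(excluded)) {
      confusion[labels[excluded[i]], pred$assigned[i]] <-
        confusion[labels[excluded[i]], pred$assigned[i]] + 1L
    }
    if (rep_i >= min_reps && all(coverage >= 1L)) break
  }
  if (!all(coverage >= 1L)) {
    abort("coverage incomplete after ", max_reps, " repetitions")
  }
  structure(
    list(
      repetitions = rep_i,
      accuracy = accuracy,
      mean_accuracy = mean(accuracy),
      sd_accuracy = if (length(accuracy) > 1) stats::sd(accuracy) else 0,
      coverage = coverage,
      confusion = confusion
    ),
    class = "plsda_validation"
  )
}

#' @export
print.plsda_validation <- function(x, ...) {
  cat(sprintf(
    "<plsda_validation> %d repetitions, accuracy %.1f +/- %.1f %%\n",
    x$repetitions, x$mean_accuracy, x$sd_accuracy
  ))
  print(x$confusion)
  invisible(x)
}

#' Impute missing cells with half the feature minimum
#'
#' Deterministic, scale-respecting fill for the sparse missingness that
#' survives presence filtering: each missing cell gets half the smallest
#' observed value of its feature in the reference matrix (by default the
#' matrix itself, i.e. the training data).
#'
#' @param X numeric matrix, samples x features (or a feature matrix with
#'   features in columns).
#' @param reference matrix with the same columns supplying the minima;
#'   pass the training matrix when imputing projection data.
#' @return `X` with missing values filled.
#' @export
impute_half_min <- function(X, reference = X) {
  X <- as.matrix(X)
  reference <- as.matrix(reference)
  if (ncol(X) != ncol(reference)) {
    abort("reference must have the same columns as X")
  }
  fill <- apply(reference, 2, function(v) {
    m <- suppressWarnings(min(v, na.rm = TRUE))
    if (!is.finite(m)) NA_real_ else 0.5 * m
  })
  for (j in which(colSums(is.na(X)) > 0)) {
    if (is.na(fill[j])) {
      abort("column ", j, " has no observed value to impute from")
    }
    X[is.na(X[, j]), j] <- fill[j]
  }
  X
}

#' Serialize a PLS-DA model (and optional validation) to JSON
#'
#' @param model a `plsda_model`.
#' @param path output path.
#' @param validation optional `plsda_validation` to embed.
#' @export
write_plsda_model <- function(model, path, validation = NULL) {
  stopifnot(inherits(model, "plsda_model"))
  doc <- list(
    n_components = model$n_components,
    classes = model$labels,
    scaling = model$scaling,
    r2x = model$r2x,
    r2y = model$r2y,
    q2 = model$q2,
    x_mean = unname(model$x_mean),
    scale_vector = unname(model$scale_vector),
    y_mean = unname(model$y_mean),
    weights = unname(model$weights),
    loadings = unname(model$loadings),
    y_loadings = unname(model$y_loadings),
    scores = unname(model$scores),
    feature_names = model$feature_names,
    sample_labels = model$sample_labels
  )
  if (!is.null(validation)) {
    doc$validation <- list(
      repetitions = validation$repetitions,
      accuracy = validation$accuracy,
      mean_accuracy = validation$mean_accuracy,
      sd_accuracy = validation$sd_accuracy
    )
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
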