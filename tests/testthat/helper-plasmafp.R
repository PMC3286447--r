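# Small hand-built feature table: 4 features x 12 samples (4 C, 4 S, 4 A),
# with controlled presence patterns for filter tests.
make_tiny_table <- function() {
  samples <- data.frame(
    sample_id = c(sprintf("C%02d", 1:4), sprintf("S%02d", 1:4),
                  sprintf("A%02d", 1:4)),
    label = rep(c("C", "S", "A"), each = 4)
  )
  features <- data.frame(
    feature_id = sprintf("F%02d", 1:4),
    neutral_mass = c(150.1, 250.2, 350.3, 450.4),
    rt = c(1, 5, 10, 20)
  )
  mat <- matrix(100, 4, 12)
  mat[2, 1:4] <- NA          # F02 absent in C
  mat[3, c(1:4, 5:7)] <- NA  # F03 only in A (4) and one S
  mat[3, 7] <- 100
  rownames(mat) <- features$feature_id
  colnames(mat) <- samples$sample_id
  feature_table(features, samples, mat)
}

# Small synthetic config for fast model tests: well-separated classes.
small_config <- function(...) {
  synthetic_config(n_features = 60, n_discriminating = 40, n_extra = 0,
                   n_qc = 5, ...)
}

# Random PLS-DA instance generator for property tests.
random_plsda_instance <- function(n = NULL, p = NULL, k = NULL) {
  n <- n %||% sample(10:20, 1)
  p <- p %||% sample(8:50, 1)
  k <- k %||% sample(2:3, 1)
  labels <- sample(LETTERS[1:k], n, replace = TRUE)
  while (length(unique(labels)) < k || min(table(labels)) < 2) {
    labels <- sample(LETTERS[1:k], n, replace = TRUE)
  }
  X <- matrix(rnorm(n * p), n, p)
  # mild class structure so components are well defined
  for (i in seq_len(k)) {
    X[labels == LETTERS[i], seq_len(min(p, 3))] <-
      X[labels == LETTERS[i], seq_len(min(p, 3))] + i
  }
  list(X = X, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# Dominant eigenvector of X'YY'X after centering both blocks: the
# independent oracle for the first NIPALS weight vector.
plsda_weight_oracle <- function(X, labels) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  y <- encode_classes(labels)$indicator
  Yc <- scale(y, center = TRUE, scale = FALSE)
  M <- t(Xc) %*% Yc %*% t(Yc) %*% Xc
  e <- eigen(M, symmetric = TRUE)
  e$vectors[, 1]
}

# Closed-form Welch statistic, written independently of welch_t_test().
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}
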