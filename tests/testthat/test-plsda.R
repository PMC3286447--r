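test_that("class encoding is one-hot with sorted label order", {
  enc <- encode_classes(c("S", "A", "C", "A", "S", "C"))
  expect_identical(enc$labels, c("A", "C", "S"))
  expect_true(all(rowSums(enc$indicator) == 1))
  expect_equal(unname(colSums(enc$indicator)), c(2, 2, 2))
  expect_error(encode_classes(rep("A", 5)), "2 distinct")
})

test_that("scores are orthogonal and r2 is monotone on random fits", {
  set.seed(101)
  for (i in 1:20) {
    inst <- random_plsda_instance()
    a_max <- min(3, nrow(inst$X) - 1, ncol(inst$X))
    m <- fit_plsda(inst$X, inst$labels, n_components = a_max)
    G <- crossprod(m$scores)
    offdiag <- abs(G[upper.tri(G)])
    norms <- sqrt(diag(G))
    expect_true(all(offdiag <= 1e-8 * outer(norms, norms)[upper.tri(G)]))
    expect_true(all(diff(m$r2x) >= -1e-12))
    expect_true(all(diff(m$r2y) >= -1e-12))
    expect_true(all(m$r2x >= 0 & m$r2x <= 1))
    expect_true(all(m$r2y >= 0 & m$r2y <= 1))
  }
})

test_that("first NIPALS weight matches the eigendecomposition oracle", {
  set.seed(55)
  inst <- random_plsda_instance(n = 10, p = 8, k = 2)
  m <- fit_plsda(inst$X, inst$labels, n_components = 1)
  w <- m$weights[, 1]
  e1 <- plsda_weight_oracle(inst$X, inst$labels)
  cosine <- abs(sum(w * e1)) / sqrt(sum(w^2) * sum(e1^2))
  expect_gte(cosine, 1 - 1e-8)
})

test_that("duplicating every sample leaves weights and loadings unchanged", {
  set.seed(9)
  inst <- random_plsda_instance(n = 12, p = 10, k = 2)
  m1 <- fit_plsda(inst$X, inst$labels, 2)
  m2 <- fit_plsda(rbind(inst$X, inst$X), c(inst$labels, inst$labels), 2)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-8)
  expect_equal(m1$loadings, m2$loadings, tolerance = 1e-8)
  expect_equal(m1$r2y, m2$r2y, tolerance = 1e-8)
})

test_that("projection reproduces training scores and centers correctly", {
  set.seed(13)
  inst <- random_plsda_instance(n = 15, p = 20, k = 3)
  m <- fit_plsda(inst$X, inst$labels, 2)
  sc <- transform_scores(m, inst$X)
  expect_equal(sc, m$scores, tolerance = 1e-8, ignore_attr = TRUE)
  mean_sample <- matrix(m$x_mean, 1)
  expect_equal(as.numeric(transform_scores(m, mean_sample)), c(0, 0),
               tolerance = 1e-10)
  expect_error(transform_scores(m, inst$X[, 1:5]), "features")
})

test_that("prediction assigns by largest response with a margin rule", {
  set.seed(17)
  inst <- random_plsda_instance(n = 20, p = 12, k = 2)
  m <- fit_plsda(inst$X, inst$labels, 2)
  cent_a <- colMeans(inst$X[inst$labels == "A", , drop = FALSE])
  pred <- predict_classes(m, matrix(cent_a, 1), margin = 0)
  expect_equal(pred$assigned, "A")
  # margin 0 never leaves a sample unassigned
  all_pred <- predict_classes(m, inst$X, margin = 0)
  expect_false(any(all_pred$assigned == "unassigned"))
  # a sample exactly midway between centroids of a symmetric two-class
  # model ties and is unassigned for any positive margin
  Xs <- rbind(diag(4) + 1, -diag(4) - 1)
  lab <- rep(c("A", "B"), each = 4)
  ms <- fit_plsda(Xs, lab, 1)
  midpoint <- matrix((colMeans(Xs[1:4, ]) + colMeans(Xs[5:8, ])) / 2, 1)
  predm <- predict_classes(ms, midpoint, margin = 1e-6)
  expect_equal(predm$assigned, "unassigned")
})

test_that("prediction is invariant to feature permutation", {
  set.seed(23)
  inst <- random_plsda_instance(n = 16, p = 15, k = 2)
  m <- fit_plsda(inst$X, inst$labels, 2)
  perm <- sample(ncol(inst$X))
  m_perm <- fit_plsda(inst$X[, perm], inst$labels, 2)
  p1 <- predict_classes(m, inst$X)
  p2 <- predict_classes(m_perm, inst$X[, perm])
  expect_equal(p1$assigned, p2$assigned)
  expect_equal(p1[, startsWith(names(p1), "y.")],
               p2[, startsWith(names(p2), "y.")], tolerance = 1e-8)
})

test_that("Q2 is high on separable data and bounded by R2Y", {
  gen <- generate_cohort(small_config(), 31)
  lab <- gen$table$samples$label
  x <- log10(impute_half_min(t(intensities(gen$table))))
  q2 <- q2_cross_validation(x, lab, 2, 7, seed = 1)
  expect_gt(q2[2], 0.5)
  m <- fit_plsda(x, lab, 2)
  expect_true(all(q2 <= m$r2y + 1e-8))
  # Q2 <= R2Y also on unstructured data
  set.seed(71)
  for (i in 1:5) {
    inst <- random_plsda_instance(n = 18, p = 12, k = 2)
    q <- q2_cross_validation(inst$X, inst$labels, 2, 6, seed = i)
    mm <- fit_plsda(inst$X, inst$labels, 2)
    expect_true(all(q <= mm$r2y + 1e-8))
  }
  expect_error(q2_cross_validation(x, lab, 2, n_folds = 1), "n_folds")
})

test_that("leave-1/3-out is perfect on separable two-class data", {
  cfg <- synthetic_config(n_per_group = 11, n_extra = 0, n_features = 20,
                          n_discriminating = 20)
  gen <- generate_cohort(cfg, 41)
  keep <- gen$table$samples$label %in% c("A", "C")
  x <- log10(impute_half_min(t(intensities(gen$table)[, keep])))
  val <- leave_third_out_validation(x, gen$table$samples$label[keep],
                                    2, seed = 1)
  expect_equal(val$mean_accuracy, 100)
  expect_equal(val$sd_accuracy, 0)
  expect_true(all(val$coverage >= 1))
  expect_gte(val$repetitions, 3)
})

test_that("leave-1/3-out needs at least three samples per class", {
  set.seed(3)
  X <- matrix(rnorm(10 * 4), 10, 4)
  expect_error(
    leave_third_out_validation(X, c(rep("A", 8), "B", "B"), 1),
    ">= 3 samples"
  )
})

test_that("half-minimum imputation fills from the reference columns", {
  X <- matrix(c(4, NA, 8, 2, 6, NA), 3, 2)
  filled <- impute_half_min(X)
  expect_equal(filled[2, 1], 2)  # half of min(4, 8)
  expect_equal(filled[3, 2], 1)  # half of min(2, 6)
  ref <- matrix(c(10, 10, 10, 10, 10, 10), 3, 2)
  expect_equal(impute_half_min(X, ref)[2, 1], 5)
  expect_error(impute_half_min(matrix(NA_real_, 2, 1)), "no observed")
})

test_that("model fitting rejects missing data and bad component counts", {
  set.seed(5)
  X <- matrix(rnorm(20), 5, 4)
  lab <- c("A", "A", "B", "B", "B")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_plsda(Xna, lab, 1), "impute")
  expect_error(fit_plsda(X, lab, 5), "n_components")
})

test_that("fitted scores agree with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(61)
  inst <- random_plsda_instance(n = 18, p = 25, k = 2)
  m <- fit_plsda(inst$X, inst$labels, 2)
  ref <- mixOmics::plsda(inst$X, factor(inst$labels), ncomp = 2,
                         scale = FALSE)
  for (a in 1:2) {
    cosine <- abs(cor(m$scores[, a], ref$variates$X[, a]))
    expect_gt(cosine, 0.999)
  }
})

test_that("model JSON serialization captures the fit", {
  set.seed(77)
  inst <- random_plsda_instance(n = 12, p = 6, k = 2)
  m <- fit_plsda(inst$X, inst$labels, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_plsda_model(m, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$n_components, 2)
  expect_equal(doc$classes, m$labels)
  expect_equal(doc$r2y, m$r2y, tolerance = 1e-12)
  expect_equal(dim(doc$weights), dim(m$weights))
})
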