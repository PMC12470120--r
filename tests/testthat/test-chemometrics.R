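# PCA, Fisher LDA, LOOCV, PC-count selection, metrics and ROC.

test_that("PCA satisfies the spectral decomposition contracts", {
  set.seed(41)
  # rank-1 structure: all rows are multiples of one direction plus a mean
  v <- rnorm(30)
  x1 <- outer(rnorm(8), v) + matrix(rep(rnorm(30), each = 8), 8)
  m1 <- fit_pca(x1, 1L)
  expect_equal(m1$explained_variance_fraction, 1, tolerance = 1e-10)

  x <- matrix(rnorm(12 * 30), 12, 30)
  k <- 11L  # min(n - 1, p)
  m <- fit_pca(x, k)
  # orthonormal loadings
  g <- crossprod(m$loadings)
  expect_equal(g, diag(k), tolerance = 1e-8)
  # non-increasing variance fractions summing to <= 1
  expect_true(all(diff(m$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(m$explained_variance_fraction), 1 + 1e-12)
  # full-rank reconstruction of the centered matrix
  xc <- sweep(x, 2, m$center)
  expect_equal(m$scores %*% t(m$loadings), xc, tolerance = 1e-8)
  # scores are centered per component
  expect_lt(max(abs(colMeans(m$scores))), 1e-10)
  expect_error(fit_pca(x, 12L), "n_components")
})

test_that("Fisher LDA matches its closed form and fixes the sign convention", {
  # 1-D separated clusters
  sc <- matrix(c(-5, -4, 4, 5), ncol = 1)
  labs <- c("OSAS", "OSAS", "CTR", "CTR")
  m <- fit_lda(sc, labs)
  expect_equal(m$threshold, 0, tolerance = 1e-12)
  expect_identical(lda_predict(m, lda_score(m, sc)), labs)
  expect_gt(m$group_means_on_cv[["CTR"]], 0)
  expect_lt(m$group_means_on_cv[["OSAS"]], 0)

  # 2-D toy with identity within-class scatter: direction parallel to the
  # mean difference
  a <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  b <- a + matrix(rep(c(3, 1), each = 4), 4)
  sc2 <- rbind(a, b)
  labs2 <- rep(c("OSAS", "CTR"), each = 4)
  m2 <- fit_lda(sc2, labs2)
  md <- c(-3, -1) / sqrt(10)  # (m_OSAS - m_CTR), unit length
  cosang <- abs(sum(m2$direction * md))
  expect_equal(cosang, 1, tolerance = 1e-10)

  expect_error(fit_lda(rbind(a, a), labs2), "degenerate")
  expect_error(fit_lda(a, rep("OSAS", 4)), "two classes")
})

test_that("LOOCV equals an exhaustive delete-one refit from scratch", {
  toy <- make_toy_matrix(n1 = 4L, n2 = 4L, p = 20L, sep = 3, seed = 43L)
  res <- loocv(toy$x, toy$labels, 3L)
  ora <- oracle_loocv(toy$x, toy$labels, 3L)
  expect_equal(res$cv_scores, ora$cv_scores, tolerance = 1e-8)
  expect_identical(res$predicted, ora$predicted)

  # agreement with an equal-priors reference discriminant per fold
  skip_if_not_installed("MASS")
  pred_mass <- vapply(seq_len(nrow(toy$x)), function(i) {
    pc <- prcomp(toy$x[-i, ], center = TRUE)
    fit <- MASS::lda(pc$x[, 1:3], grouping = toy$labels[-i],
                     prior = c(0.5, 0.5))
    newsc <- scale(toy$x[i, , drop = FALSE], pc$center,
                   scale = FALSE) %*% pc$rotation[, 1:3]
    as.character(predict(fit, newsc)$class)
  }, character(1))
  expect_identical(res$predicted, pred_mass)
})

test_that("LOOCV error bookkeeping uses the balanced definition", {
  toy <- make_toy_matrix(n1 = 6L, n2 = 4L, p = 15L, sep = 8, seed = 44L)
  res <- loocv(toy$x, toy$labels, 2L)
  expect_identical(sum(res$confusion[c("TP", "FN")]), 6L)
  expect_identical(sum(res$confusion[c("TN", "FP")]), 4L)
  expect_equal(res$overall_error, mean(res$per_group_error))
  # perfectly separated classes classify without error
  expect_equal(res$overall_error, 0)
})

test_that("held-out subjects never influence their own fold", {
  toy <- make_toy_matrix(n1 = 5L, n2 = 5L, p = 12L, sep = 2, seed = 45L)
  res <- loocv(toy$x, toy$labels, 2L)
  for (i in c(1L, 6L)) {
    corrupted <- toy$labels
    corrupted[i] <- setdiff(c("OSAS", "CTR"), corrupted[i])
    res2 <- loocv(toy$x, corrupted, 2L)
    expect_equal(res2$cv_scores[i], res$cv_scores[i], tolerance = 1e-10)
  }
})

test_that("PC-count selection finds top-component signal and reports the profile", {
  set.seed(46)
  n <- 16L
  x <- matrix(rnorm(n * 25, sd = 0.3), n, 25)
  labs <- rep(c("OSAS", "CTR"), each = n / 2)
  x[labs == "OSAS", 1] <- x[labs == "OSAS", 1] + 5  # signal = top variance
  sel <- select_n_components(x, labs, 5L)
  expect_identical(sel$selected, 1L)
  expect_identical(nrow(sel$profile), 5L)
  expect_equal(sel$profile$n_components, 1:5)
  # ties break to the smaller k by construction of which.min
  expect_true(sel$profile$overall_error[1] ==
                min(sel$profile$overall_error))
})

test_that("confusion metrics follow the standard definitions", {
  m <- compute_metrics(c(TP = 30, FN = 10, TN = 15, FP = 5))
  expect_equal(m$accuracy, 45 / 60)
  expect_equal(m$sensitivity, 30 / 40)
  expect_equal(m$specificity, 15 / 20)
  expect_equal(m$precision, 30 / 35)
  expect_equal(m$balanced_error, (10 / 40 + 5 / 20) / 2)

  perfect <- compute_metrics(c(TP = 10, FN = 0, TN = 10, FP = 0))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "precision")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 precision = 1))
  expect_error(compute_metrics(c(TP = 0, FN = 10, TN = 10, FP = 0)),
               "precision")
  expect_error(compute_metrics(c(TP = 0, FN = 0, TN = 10, FP = 2)),
               "margin")
})

test_that("ROC AUC equals exhaustive pair counting, with tie handling", {
  set.seed(47)
  scores <- c(1, 2, 2, 3, 5, 5, 5, 7, 8, 9, 9, 10)
  labels <- rep(c("CTR", "OSAS"), 6)
  r <- roc_of_scores(scores, labels)
  expect_equal(r$auc, oracle_auc_paircount(scores, labels),
               tolerance = 1e-12)

  sep <- roc_of_scores(c(rnorm(10), rnorm(10) + 100),
                       rep(c("CTR", "OSAS"), each = 10))
  expect_equal(sep$auc, 1)
  expect_lt(sep$asymptotic_p, 1e-3)  # normal approximation at n = 10/10

  const <- roc_of_scores(rep(1, 20), rep(c("CTR", "OSAS"), 10))
  expect_equal(const$auc, 0.5)
  expect_equal(const$asymptotic_p, 1)

  skip_if_not_installed("pROC")
  s2 <- rnorm(30)
  l2 <- rep(c("OSAS", "CTR"), 15)
  expect_equal(roc_of_scores(s2, l2)$auc,
               as.numeric(pROC::auc(pROC::roc(l2, s2, levels = c("CTR", "OSAS"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("ROC AUC is calibrated under label permutation", {
  set.seed(48)
  scores <- rnorm(85)
  labels <- c(rep("OSAS", 51), rep("CTR", 34))
  aucs <- vapply(1:200, function(i) {
    roc_of_scores(scores, sample(labels))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
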