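# Peak-area biomarker and the downstream statistical battery.

test_that("peak area integrates the snapped window by the trapezoid rule", {
  grid <- target_grid(preprocess_config())
  zero <- raman_spectrum(grid, rep(0, length(grid)), stage = "resampled")
  expect_equal(peak_auc(zero)$auc, 0)

  one <- raman_spectrum(grid, rep(1, length(grid)), stage = "resampled")
  r <- peak_auc(one)
  expect_equal(r$auc, diff(r$snapped_window), tolerance = 1e-12)

  # truncated-Gaussian closed form
  amp <- 3; sigma <- 4; ctr <- 920
  g <- raman_spectrum(grid, amp * exp(-(grid - ctr)^2 / (2 * sigma^2)),
                      stage = "resampled")
  rg <- peak_auc(g)
  a <- rg$snapped_window[1]; b <- rg$snapped_window[2]
  want <- amp * sigma * sqrt(2 * pi) *
    (pnorm((b - ctr) / sigma) - pnorm((a - ctr) / sigma))
  expect_lt(abs(rg$auc - want) / want, 0.01)

  expect_error(peak_auc(zero, window = c(2000, 2100)), "fewer than 2")
})

test_that("peak area is linear in the spectrum", {
  grid <- target_grid(preprocess_config())
  set.seed(51)
  s <- raman_spectrum(grid, rnorm(length(grid)), stage = "resampled")
  t <- raman_spectrum(grid, rnorm(length(grid)), stage = "resampled")
  combo <- raman_spectrum(grid, 2 * s$intensities + 5 * t$intensities,
                          stage = "resampled")
  expect_equal(peak_auc(combo)$auc,
               2 * peak_auc(s)$auc + 5 * peak_auc(t)$auc,
               tolerance = 1e-10)
})

test_that("Shapiro-Wilk wrapper is calibrated and detects skew", {
  set.seed(52)
  rejects <- vapply(1:400, function(i) {
    shapiro_wilk(rnorm(500))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejects) - 0.05), 0.02 + 1e-9)

  skew_detect <- vapply(1:100, function(i) {
    shapiro_wilk(rexp(100))$p_value < 0.01
  }, logical(1))
  expect_gt(mean(skew_detect), 0.95)

  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "identical")
})

test_that("two-sample t-test wrapper matches its contracts", {
  same <- c(1, 2, 3, 4)
  r <- two_sample_t(same, same)
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0)

  far <- two_sample_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(far$p_value, 0.001)

  set.seed(53)
  rejects <- vapply(1:1000, function(i) {
    two_sample_t(rnorm(34), rnorm(51))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejects) - 0.05), 0.02)

  expect_error(two_sample_t(c(1, 1), c(1, 1)), "degenerate")
})

test_that("Mann-Whitney U equals exhaustive pair counting and reports medians", {
  set.seed(54)
  a <- sample(c(1:8, 4, 4), 10)
  b <- sample(c(3:10, 6, 6), 10)
  r <- mann_whitney(a, b)
  expect_equal(as.numeric(r$statistic), oracle_u_paircount(a, b))
  expect_equal(r$group_summaries$median, c(median(a), median(b)))

  same <- c(2, 4, 6, 8)
  expect_equal(mann_whitney(same, same)$p_value, 1)
})

test_that("one-way ANOVA reduces to t^2 for two groups and is calibrated", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  r <- anova_oneway(g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(55)
  x <- rnorm(12); y <- rnorm(15, 1)
  ra <- anova_oneway(list(x = x, y = y))
  rt <- two_sample_t(x, y)
  expect_equal(ra$statistic, rt$statistic^2, tolerance = 1e-10)
  expect_equal(ra$p_value, rt$p_value, tolerance = 1e-10)

  rejects <- vapply(1:1000, function(i) {
    anova_oneway(list(rnorm(10), rnorm(10), rnorm(10)))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejects) - 0.05), 0.02)

  expect_error(anova_oneway(list(rep(1, 5), rep(2, 5))), "degenerate")
})

test_that("stratification applies the AHI and BMI class boundaries", {
  clin <- validate_clinical_table(data.frame(
    subject_id = sprintf("S%d", 1:5),
    group = c(rep("OSAS", 4), "CTR"),
    ahi = c(6, 15, 30, 31, NA),
    bmi = c(24.9, 27, 30, 35, 22)))
  ahi <- stratify(clin, "ahi_class")
  expect_identical(unname(ahi$labels[1:4]),
                   c("mild", "moderate", "moderate", "severe"))
  expect_identical(ahi$excluded, "S5")

  bmi <- stratify(clin, "bmi_class")
  expect_identical(unname(bmi$labels),
                   c(NA, "overweight", "obese", "obese", NA))
  expect_true(all(c("S1", "S5") %in% bmi$excluded))
})

test_that("generated AHI severity proportions track the configured targets", {
  counts <- matrix(0, 0, 3)
  for (s in 1:10) {
    cfg <- synthetic_cohort_config(seed = s, replicates_per_subject = 1L)
    clin <- generate_cohort(cfg)$cohort$clinical
    lab <- stratify(clin[clin$group == "OSAS", ], "ahi_class")$labels
    counts <- rbind(counts, table(factor(lab, c("mild", "moderate",
                                                "severe"))))
  }
  expect_equal(unname(colMeans(counts)), c(14, 14, 23), tolerance = 0.25)
})

test_that("Spearman correlation matches the exhaustive permutation oracle", {
  set.seed(56)
  x <- rnorm(8)
  y <- 0.8 * x + rnorm(8, sd = 0.6)
  r <- spearman_cor(x, y)
  o <- oracle_spearman_exact(x, y)
  expect_equal(r$rho, o$rho, tolerance = 1e-12)
  expect_equal(r$p_value, o$p, tolerance = 1e-12)
  expect_identical(r$method, "exact_permutation")

  # monotone-transform invariance, large-n branch
  x2 <- rnorm(40)
  y2 <- x2^3 + rnorm(40, sd = 0.1)
  r2 <- spearman_cor(x2, y2)
  r2t <- spearman_cor(exp(x2), y2)
  expect_equal(r2$rho, r2t$rho)
  expect_identical(r2$method, "t_approximation")

  mono <- spearman_cor(1:10, exp(1:10 / 3))
  expect_equal(mono$rho, 1)

  expect_error(spearman_cor(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("quadratic lactate model recovers exact coefficients and flags outliers", {
  set.seed(57)
  lact <- runif(30, 5, 60)
  cv <- 0.5 + 0.02 * lact - 3e-4 * lact^2
  fit <- suppressWarnings(fit_lm_quadratic(cv, lact))  # exact fit: summary.lm warns
  expect_equal(unname(fit$coefficients),
               c(0.5, 0.02, -3e-4), tolerance = 1e-8)
  expect_length(fit$removed_points, 0L)

  # plant one gross outlier in otherwise linear data
  cv2 <- 0.1 + 0.01 * lact + rnorm(30, sd = 0.01)
  cv2[7] <- cv2[7] + 2
  fit2 <- fit_lm_quadratic(cv2, lact, subject_id = sprintf("S%02d", 1:30))
  expect_true("S07" %in% fit2$removed_points)
  expect_true(all(c("residual_shapiro_p", "breusch_pagan_p") %in%
                    names(fit2$diagnostics)))

  expect_error(fit_lm_quadratic(cv[1:5], lact[1:5]), "at least 10")
})

test_that("quadratic model slope p-values are null-calibrated", {
  set.seed(58)
  ok <- vapply(1:200, function(i) {
    lact <- runif(40, 5, 60)
    fit <- fit_lm_quadratic(rnorm(40), lact)
    all(fit$p_values[c("lactate", "lactate_sq")] > 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})

test_that("joint model recovers exact planted coefficients and rejects collinearity", {
  set.seed(59)
  lact <- runif(40, 5, 60)
  auc <- runif(40, 0.4, 1.2)
  cv <- 0.3 + 0.019 * lact - 1.15 * auc
  fit <- suppressWarnings(fit_lm_joint(cv, lact, auc))  # exact fit: summary.lm warns
  expect_equal(fit$coefficients[["beta1"]], 0.019, tolerance = 1e-8)
  expect_equal(fit$coefficients[["beta2"]], -1.15, tolerance = 1e-8)

  expect_error(fit_lm_joint(cv, lact, lact), "collinear")

  # unbiasedness under a zero-coefficient null
  betas <- t(vapply(1:200, function(i) {
    f <- fit_lm_joint(rnorm(40), lact, auc)
    c(f$coefficients[["beta1"]], f$coefficients[["beta2"]])
  }, numeric(2)))
  se <- apply(betas, 2, sd) / sqrt(nrow(betas))
  expect_lt(abs(mean(betas[, 1])), 4 * se[1] + 1e-6)
  expect_lt(abs(mean(betas[, 2])), 4 * se[2] + 1e-3)
})

test_that("group tests are invariant to swapping the groups", {
  set.seed(60)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  expect_equal(two_sample_t(a, b)$p_value, two_sample_t(b, a)$p_value)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value,
               tolerance = 1e-12)
})
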