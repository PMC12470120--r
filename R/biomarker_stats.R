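# Lactic-acid peak-area biomarker and the downstream univariate,
# stratified, correlation and linear-model statistics.

#' Integrate a spectral peak area over a wavenumber window
#'
#' Trapezoidal integral of the intensities over the window, with the window
#' endpoints snapped inward to the nearest grid points so the integration
#' bounds are bit-reproducible on a fixed grid. The default window
#' 910.75-930.13 cm^-1 covers the lactic-acid peak at 920 cm^-1. No local
#' baseline chord is subtracted by default; `chord = TRUE` subtracts the
#' straight line connecting the two window endpoints first.
#'
#' @param spectrum A [raman_spectrum] on the common grid (stage
#'   `resampled`, `normalized` or `averaged`) covering the window.
#' @param window `(lo, hi)` integration bounds in cm^-1.
#' @param chord Subtract a linear local-baseline chord (default `FALSE`).
#' @return An object of class `peak_auc_result`: `subject_id`, `auc`,
#'   `window` (requested), `snapped_window` (grid bounds actually used).
#' @export
peak_auc <- function(spectrum, window = c(910.75, 930.13), chord = FALSE) {
  validate_raman_spectrum(spectrum)
  .assert_stage(spectrum, c("resampled", "normalized", "averaged"),
                "peak_auc")
  stopifnot(length(window) == 2L, window[1] < window[2])
  wn <- spectrum$wavenumbers
  sel <- which(wn >= window[1] & wn <= window[2])
  if (length(sel) < 2L) {
    stop("window ", window[1], "-", window[2],
         " cm^-1 covers fewer than 2 grid points", call. = FALSE)
  }
  xw <- wn[sel]
  yw <- spectrum$intensities[sel]
  if (chord) {
    m <- length(yw)
    yw <- yw - (yw[1] + (xw - xw[1]) * (yw[m] - yw[1]) / (xw[m] - xw[1]))
  }
  structure(list(
    subject_id = spectrum$subject_id,
    auc = pracma::trapz(xw, yw),
    window = as.numeric(window),
    snapped_window = c(xw[1], xw[length(xw)])
  ), class = "peak_auc_result")
}

# Wrap a stats result into the common group_comparison shape.
.group_comparison <- function(test, statistic, p_value, group_summaries,
                              note = NULL) {
  structure(list(test = test,
                 statistic = unname(statistic),
                 p_value = unname(p_value),
                 group_summaries = group_summaries,
                 note = note),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$group_summaries)) print(x$group_summaries, row.names = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, 3 <= n <= 5000, not constant.
#' @return A `group_comparison` with the W statistic and p-value.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n, call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("degenerate sample: all values identical", call. = FALSE)
  }
  ht <- stats::shapiro.test(values)
  .group_comparison("shapiro_wilk", ht$statistic, ht$p.value,
                    data.frame(n = n, mean = mean(values),
                               sd = stats::sd(values)))
}

#' Two-sample t-test on group values
#'
#' Classic pooled-variance two-sided test by default; `welch = TRUE` drops
#' the equal-variance assumption.
#'
#' @param values_a,values_b Numeric vectors, n >= 2 each.
#' @param welch Use the Welch correction (default `FALSE`).
#' @param group_names Labels for the report.
#' @return A `group_comparison` with t, p, and per-group mean/SD/n.
#' @export
two_sample_t <- function(values_a, values_b, welch = FALSE,
                         group_names = c("a", "b")) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("two_sample_t requires n >= 2 per group", call. = FALSE)
  }
  if (stats::var(values_a) + stats::var(values_b) == 0) {
    stop("degenerate data: zero variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(values_a, values_b, var.equal = !welch)
  .group_comparison(
    if (welch) "t_two_sample_welch" else "t_two_sample",
    ht$statistic, ht$p.value,
    data.frame(group = group_names,
               n = c(length(values_a), length(values_b)),
               mean = c(mean(values_a), mean(values_b)),
               sd = c(stats::sd(values_a), stats::sd(values_b))))
}

#' Mann-Whitney rank-sum test on group values
#'
#' Two-sided U test with tie correction (normal approximation, no
#' continuity correction, so identical samples give p = 1); reports group
#' medians and interquartile ranges.
#'
#' @param values_a,values_b Numeric vectors, n >= 1 each.
#' @param group_names Labels for the report.
#' @return A `group_comparison` with U, p, and per-group median/IQR/n.
#' @export
mann_whitney <- function(values_a, values_b, group_names = c("a", "b")) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 1L || length(values_b) < 1L) {
    stop("mann_whitney requires non-empty groups", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = FALSE, correct = FALSE))
  .group_comparison(
    "mann_whitney", ht$statistic,
    if (is.nan(ht$p.value)) 1 else ht$p.value,
    data.frame(group = group_names,
               n = c(length(values_a), length(values_b)),
               median = c(stats::median(values_a), stats::median(values_b)),
               iqr = c(stats::IQR(values_a), stats::IQR(values_b))))
}

#' One-way ANOVA across value groups
#'
#' Classic equal-variance F test across two or more groups.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, n >= 2 each).
#' @return A `group_comparison` with F, p, and per-group mean/SD/n.
#' @export
anova_oneway <- function(groups) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2L) {
    stop("anova_oneway requires at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("anova_oneway requires n >= 2 in every group", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups),
                  vapply(groups, length, integer(1))))
  if (sum(vapply(groups, stats::var, numeric(1))) == 0) {
    stop("degenerate data: zero within-group variance", call. = FALSE)
  }
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  nm <- if (is.null(names(groups))) as.character(seq_along(groups)) else
    names(groups)
  .group_comparison(
    "anova_oneway", ht$statistic, ht$p.value,
    data.frame(group = nm,
               n = vapply(groups, length, integer(1)),
               mean = vapply(groups, mean, numeric(1)),
               sd = vapply(groups, stats::sd, numeric(1))))
}

#' Stratify subjects by AHI severity class or BMI class
#'
#' AHI classes: mild `[5, 15)`, moderate `[15, 30]`, severe `(30, Inf)`
#' events/h (15 and 30 belong to moderate). BMI classes: overweight
#' `25-29.99` kg/m^2, obese `>= 30` kg/m^2; subjects below 25 (or with a
#' missing covariate) fall outside all bins and are reported as excluded.
#'
#' @param clinical A `clinical_table` (or the `clinical` element of a
#'   cohort).
#' @param by `"ahi_class"` or `"bmi_class"`.
#' @return A list with `labels` (named character vector, subject id ->
#'   stratum, `NA` for excluded) and `excluded` (subject ids outside all
#'   bins).
#' @export
stratify <- function(clinical, by = c("ahi_class", "bmi_class")) {
  by <- match.arg(by)
  clinical <- as.data.frame(clinical)
  col <- if (by == "ahi_class") "ahi" else "bmi"
  if (!col %in% names(clinical)) {
    stop("clinical table lacks the ", sQuote(col), " column", call. = FALSE)
  }
  v <- clinical[[col]]
  lab <- rep(NA_character_, length(v))
  if (by == "ahi_class") {
    lab[!is.na(v) & v >= 5 & v < 15] <- "mild"
    lab[!is.na(v) & v >= 15 & v <= 30] <- "moderate"
    lab[!is.na(v) & v > 30] <- "severe"
  } else {
    lab[!is.na(v) & v >= 25 & v < 30] <- "overweight"
    lab[!is.na(v) & v >= 30] <- "obese"
  }
  names(lab) <- clinical$subject_id
  list(labels = lab, excluded = clinical$subject_id[is.na(lab)])
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling. The two-sided p-value
#' is computed by exhaustive permutation of one variable's ranks when
#' n <= 9 and neither variable has ties, and by the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Paired numeric vectors, n >= 4 complete pairs; neither may be
#'   constant.
#' @param variables Names of the two variables, for the report.
#' @return An object of class `correlation_result`: `variables`, `rho`,
#'   `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, variables = c("x", "y")) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4L) {
    stop("spearman_cor requires at least 4 complete pairs", call. = FALSE)
  }
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("undefined correlation: constant variable", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n <= 9L && no_ties) {
    # exhaustive permutation null: correlate rx with every permutation of ry
    perms <- .permutations(n)
    rx_c <- rx - mean(rx)
    ry_c <- ry - mean(ry)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    permuted <- matrix(ry_c[perms], nrow = nrow(perms))
    rhos <- as.vector(permuted %*% rx_c) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
    method <- "t_approximation"
  }
  structure(list(variables = variables, rho = rho, p_value = p, n = n,
                 method = method),
            class = "correlation_result")
}

# All permutations of 1..n as a matrix (n! rows); n <= 9 keeps this small.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub],
                                                         nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman %s ~ %s: rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$variables[1], x$variables[2], x$rho, x$p_value, x$n,
              x$method))
  invisible(x)
}

# Shared diagnostics block for the linear-model fits.
.lm_diagnostics <- function(fit) {
  res <- stats::residuals(fit)
  shapiro_p <- if (length(res) >= 3 && diff(range(res)) > 0) {
    stats::shapiro.test(res)$p.value
  } else {
    NA_real_
  }
  bp_p <- tryCatch(lmtest::bptest(fit)$p.value, error = function(e) NA_real_)
  c(residual_shapiro_p = unname(shapiro_p),
    breusch_pagan_p = unname(bp_p))
}

#' Quadratic-lactate linear model with outlier and influence screening
#'
#' Fits `cv ~ lactate + lactate^2` by ordinary least squares, using the
#' centered-lactate quadratic internally to limit collinearity between the
#' linear and quadratic terms. Points with Cook's distance above `4/n` or
#' absolute studentized residual above 3 are flagged, removed, and the
#' model refit. Reported coefficients are mapped back to the raw
#' (uncentered) scale: `(Intercept)`, `lactate`, `lactate_sq`.
#'
#' @param cv Canonical-variable scores.
#' @param lactate Lactate concentrations (uM), paired with `cv`.
#' @param subject_id Optional subject ids (default index numbers).
#' @return An object of class `linear_model_fit`: `formula`,
#'   `coefficients`, `p_values`, `removed_points`, `diagnostics`
#'   (residual Shapiro-Wilk p, Breusch-Pagan p), `n_used`, and the refit
#'   `model`.
#' @export
fit_lm_quadratic <- function(cv, lactate, subject_id = NULL) {
  ok <- !(is.na(cv) | is.na(lactate))
  if (is.null(subject_id)) subject_id <- as.character(seq_along(cv))
  cv <- cv[ok]
  lactate <- lactate[ok]
  subject_id <- subject_id[ok]
  n <- length(cv)
  if (n < 10L) {
    stop("fit_lm_quadratic requires at least 10 complete pairs, got ", n,
         call. = FALSE)
  }
  ctr <- mean(lactate)
  fit_centered <- function(cvv, lac) {
    lc <- lac - ctr
    stats::lm(cvv ~ lc + I(lc^2))
  }
  fit0 <- fit_centered(cv, lactate)
  if (summary(fit0)$sigma < 1e-8 * max(stats::sd(cv), .Machine$double.eps)) {
    # an (essentially) exactly interpolating fit has no outliers; influence
    # measures on machine-noise residuals are meaningless
    flag <- rep(FALSE, n)
  } else {
    flag <- stats::cooks.distance(fit0) > 4 / n |
      abs(stats::rstudent(fit0)) > 3
    flag[is.na(flag)] <- FALSE
  }
  removed <- subject_id[flag]
  keep <- !flag
  if (sum(keep) < 4L) {
    stop("outlier removal left fewer than 4 points", call. = FALSE)
  }
  fit <- fit_centered(cv[keep], lactate[keep])
  bc <- stats::coef(fit)
  # map centered coefficients back to the raw lactate scale
  coefs <- c(
    "(Intercept)" = unname(bc[1] - bc[2] * ctr + bc[3] * ctr^2),
    lactate = unname(bc[2] - 2 * bc[3] * ctr),
    lactate_sq = unname(bc[3])
  )
  pv <- summary(fit)$coefficients[, 4]
  p_values <- c("(Intercept)" = unname(pv[1]), lactate = unname(pv[2]),
                lactate_sq = unname(pv[3]))
  structure(list(
    formula = "cv ~ lactate + lactate^2",
    coefficients = coefs,
    p_values = p_values,
    removed_points = removed,
    diagnostics = .lm_diagnostics(fit),
    n_used = sum(keep),
    model = fit
  ), class = "linear_model_fit")
}

#' Joint linear model of the canonical variable
#'
#' Ordinary least squares of `cv` on lactate concentration and the
#' lactic-acid peak area: `cv ~ lactate + auc_920`. Coefficients are
#' reported as `beta1` (lactate) and `beta2` (auc_920). Observations whose
#' ids appear in `exclude` (typically the removals of
#' [fit_lm_quadratic()]) are dropped before fitting. Rank-deficient designs
#' (e.g. perfectly collinear predictors) are an error.
#'
#' @param cv Canonical-variable scores.
#' @param lactate Lactate concentrations (uM).
#' @param auc_920 Lactic-acid peak areas.
#' @param subject_id Optional subject ids (default index numbers).
#' @param exclude Subject ids to drop before fitting.
#' @return A `linear_model_fit` (see [fit_lm_quadratic()]); coefficient
#'   and p-value vectors are named `(Intercept)`, `beta1`, `beta2`.
#' @export
fit_lm_joint <- function(cv, lactate, auc_920, subject_id = NULL,
                         exclude = character(0)) {
  if (is.null(subject_id)) subject_id <- as.character(seq_along(cv))
  ok <- !(is.na(cv) | is.na(lactate) | is.na(auc_920)) &
    !subject_id %in% exclude
  cv <- cv[ok]
  lactate <- lactate[ok]
  auc_920 <- auc_920[ok]
  subject_id <- subject_id[ok]
  if (length(cv) < 4L) {
    stop("fit_lm_joint requires at least 4 complete cases", call. = FALSE)
  }
  X <- cbind(1, lactate, auc_920)
  if (qr(X)$rank < 3L) {
    stop("rank-deficient design: lactate and auc_920 are collinear",
         call. = FALSE)
  }
  fit <- stats::lm(cv ~ lactate + auc_920)
  bc <- stats::coef(fit)
  pv <- summary(fit)$coefficients[, 4]
  structure(list(
    formula = "cv ~ lactate + auc_920",
    coefficients = c("(Intercept)" = unname(bc[1]), beta1 = unname(bc[2]),
                     beta2 = unname(bc[3])),
    p_values = c("(Intercept)" = unname(pv[1]), beta1 = unname(pv[2]),
                 beta2 = unname(pv[3])),
    removed_points = exclude,
    diagnostics = .lm_diagnostics(fit),
    n_used = length(cv),
    model = fit
  ), class = "linear_model_fit")
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat(sprintf("Linear model %s (n = %d)\n", x$formula, x$n_used))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %-12s %+.4g (p = %.4g)\n", nm, x$coefficients[[nm]],
                x$p_values[[nm]]))
  }
  if (length(x$removed_points)) {
    cat("  removed points:", paste(x$removed_points, collapse = ", "), "\n")
  }
  cat(sprintf("  residual normality p = %.3g, homoscedasticity p = %.3g\n",
              x$diagnostics[["residual_shapiro_p"]],
              x$diagnostics[["breusch_pagan_p"]]))
  invisible(x)
}
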