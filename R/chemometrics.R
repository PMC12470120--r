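# PCA-LDA classification with leave-one-out cross-validation, PC-count
# selection, confusion metrics, and ROC analysis of the canonical variable.

#' Fit a principal component analysis model
#'
#' Mean-centered singular value decomposition of a subjects-by-features
#' matrix. Scores of a row are `(row - center) %*% loadings`.
#'
#' @param x Numeric matrix, subjects in rows, spectral features in columns.
#' @param n_components Number of components to retain,
#'   `<= min(nrow(x) - 1, ncol(x))`.
#' @return An object of class `pca_model`: `center`, `loadings`
#'   (features x k, orthonormal), `explained_variance_fraction` (length k,
#'   non-increasing, sums <= 1), `n_components`, and the training `scores`.
#' @export
fit_pca <- function(x, n_components) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  kmax <- min(n - 1L, p)
  if (n_components < 1L || n_components > kmax) {
    stop("n_components must be in 1..", kmax, ", got ", n_components,
         call. = FALSE)
  }
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc, nu = 0, nv = n_components)
  total_var <- sum(sv$d^2)
  structure(list(
    center = center,
    loadings = sv$v,
    explained_variance_fraction = sv$d[seq_len(n_components)]^2 / total_var,
    n_components = as.integer(n_components),
    scores = xc %*% sv$v
  ), class = "pca_model")
}

#' Project new rows into an existing PCA space
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param newdata Numeric matrix (or vector, treated as one row) with the
#'   same features as the training matrix.
#' @return Score matrix, rows matching `newdata`.
#' @export
pca_project <- function(model, newdata) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(model$center)) {
    stop("newdata has ", ncol(newdata), " features, model expects ",
         length(model$center), call. = FALSE)
  }
  sweep(newdata, 2, model$center) %*% model$loadings
}

#' Fit a two-class Fisher linear discriminant
#'
#' Computes the canonical axis `direction` proportional to
#' `solve(S_w, m_pos - m_neg)` (within-class scatter `S_w`), normalized to
#' unit length. The sign is fixed so that the mean score of the control
#' class (`control_label`) is positive, i.e. negative canonical-variable
#' scores indicate the disease class. The classification threshold is the
#' midpoint of the two class mean scores (equal priors).
#'
#' If `S_w` is numerically singular a ridge `1e-8 * trace(S_w)` is added to
#' its diagonal and a message is logged.
#'
#' @param scores Numeric matrix of PC scores, subjects in rows.
#' @param labels Character/factor vector of class labels, exactly two
#'   classes, both present.
#' @param positive_label Disease class (default `"OSAS"`).
#' @param control_label Class whose mean canonical score is oriented
#'   positive (default `"CTR"`).
#' @return An object of class `lda_model`: `direction`,
#'   `group_means_on_cv` (named), `threshold`, `positive_label`,
#'   `control_label`.
#' @export
fit_lda <- function(scores, labels, positive_label = "OSAS",
                    control_label = "CTR") {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop("fit_lda requires exactly two classes, got ",
         length(classes), call. = FALSE)
  }
  if (!positive_label %in% classes) {
    stop("positive_label ", sQuote(positive_label), " absent from labels",
         call. = FALSE)
  }
  neg_label <- setdiff(classes, positive_label)
  a <- scores[labels == positive_label, , drop = FALSE]
  b <- scores[labels == neg_label, , drop = FALSE]
  m1 <- colMeans(a)
  m2 <- colMeans(b)
  sw <- crossprod(sweep(a, 2, m1)) + crossprod(sweep(b, 2, m2))
  dir <- tryCatch(
    solve(sw, m1 - m2),
    error = function(e) {
      ridge <- 1e-8 * sum(diag(sw))
      message("fit_lda: singular within-class scatter; ridge ",
              format(ridge), " added to the diagonal")
      solve(sw + diag(ridge, nrow(sw)), m1 - m2)
    })
  nrm <- sqrt(sum(dir^2))
  if (!is.finite(nrm) || nrm < 1e-12) {
    stop("degenerate discriminant direction (identical class means?)",
         call. = FALSE)
  }
  dir <- dir / nrm
  proj <- drop(scores %*% dir)
  ctr_class <- if (control_label %in% classes) control_label else neg_label
  if (mean(proj[labels == ctr_class]) < 0) {
    dir <- -dir
    proj <- -proj
  }
  means <- c(mean(proj[labels == positive_label]),
             mean(proj[labels == neg_label]))
  names(means) <- c(positive_label, neg_label)
  structure(list(
    direction = dir,
    group_means_on_cv = means,
    threshold = mean(means),
    positive_label = positive_label,
    control_label = ctr_class
  ), class = "lda_model")
}

#' Canonical-variable scores of new PC-score rows
#'
#' @param model An `lda_model` from [fit_lda()].
#' @param scores PC-score matrix or vector (one row).
#' @return Numeric vector of canonical-variable scores.
#' @export
lda_score <- function(model, scores) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  drop(scores %*% model$direction)
}

#' Predicted labels from canonical-variable scores
#'
#' Scores on the side of the threshold where the class mean lies get that
#' class; a score exactly at the threshold is assigned the positive
#' (disease) class.
#'
#' @param model An `lda_model`.
#' @param cv Numeric vector of canonical-variable scores.
#' @return Character vector of predicted labels.
#' @export
lda_predict <- function(model, cv) {
  stopifnot(inherits(model, "lda_model"))
  means <- model$group_means_on_cv
  upper <- names(means)[which.max(means)]
  lower <- names(means)[which.min(means)]
  out <- ifelse(cv > model$threshold, upper, lower)
  out[cv == model$threshold] <- model$positive_label
  out
}

# Confusion counts for two classes.
.confusion_counts <- function(truth, predicted, positive_label) {
  pos <- truth == positive_label
  c(TP = sum(pos & predicted == positive_label),
    FN = sum(pos & predicted != positive_label),
    TN = sum(!pos & predicted != positive_label),
    FP = sum(!pos & predicted == positive_label))
}

#' Leave-one-out cross-validation of the PCA-LDA model
#'
#' For every held-out subject the PCA (center and loadings) and the LDA are
#' refit on the remaining subjects, the held-out row is projected and
#' scored, and classified by that fold's midpoint threshold. No information
#' from the held-out row enters its fold's model.
#'
#' The overall error is the balanced error rate: the unweighted mean of the
#' two per-group misclassification fractions.
#'
#' @param x Subjects-by-features matrix (row names = subject ids).
#' @param labels Class labels, two classes, at least 2 subjects each.
#' @param n_components Number of principal components fed to the LDA.
#' @param refit_pca Refit the PCA inside every fold (default `TRUE`, the
#'   leakage-free choice). `FALSE` fits PCA once on the full matrix and
#'   only refits the LDA per fold, mirroring a fixed-basis workflow.
#' @param positive_label,control_label Passed to [fit_lda()].
#' @return An object of class `cross_val_result`: `cv_scores`, `predicted`,
#'   `truth`, `confusion` (TP, FN, TN, FP), `per_group_error`,
#'   `overall_error`, `n_components_used`, `subject_id`.
#' @export
loocv <- function(x, labels, n_components, refit_pca = TRUE,
                  positive_label = "OSAS", control_label = "CTR") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  classes <- unique(labels)
  if (length(classes) != 2L || min(table(labels)) < 2L) {
    stop("loocv requires two classes with at least 2 subjects each",
         call. = FALSE)
  }
  fixed_pca <- if (!refit_pca) fit_pca(x, n_components) else NULL
  cv_scores <- numeric(n)
  predicted <- character(n)
  for (i in seq_len(n)) {
    tr_labels <- labels[-i]
    if (length(unique(tr_labels)) < 2L) {
      stop("LOOCV fold ", i, " has a single-class training set",
           call. = FALSE)
    }
    if (refit_pca) {
      pca <- fit_pca(x[-i, , drop = FALSE], n_components)
      tr_scores <- pca$scores
      te_scores <- pca_project(pca, x[i, , drop = FALSE])
    } else {
      tr_scores <- fixed_pca$scores[-i, , drop = FALSE]
      te_scores <- fixed_pca$scores[i, , drop = FALSE]
    }
    lda <- fit_lda(tr_scores, tr_labels, positive_label, control_label)
    cv <- lda_score(lda, te_scores)
    cv_scores[i] <- cv
    predicted[i] <- lda_predict(lda, cv)
  }
  conf <- .confusion_counts(labels, predicted, positive_label)
  neg_label <- setdiff(classes, positive_label)
  per_group <- c(conf[["FN"]] / sum(labels == positive_label),
                 conf[["FP"]] / sum(labels == neg_label))
  names(per_group) <- c(positive_label, neg_label)
  structure(list(
    subject_id = rownames(x),
    cv_scores = cv_scores,
    predicted = predicted,
    truth = labels,
    confusion = conf,
    per_group_error = per_group,
    overall_error = mean(per_group),
    n_components_used = as.integer(n_components)
  ), class = "cross_val_result")
}

#' @export
print.cross_val_result <- function(x, ...) {
  cat(sprintf("PCA-LDA LOOCV, %d PCs, %d subjects\n",
              x$n_components_used, length(x$truth)))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  cat(sprintf("  per-group error: %s\n",
              paste(sprintf("%s %.2f%%", names(x$per_group_error),
                            100 * x$per_group_error), collapse = ", ")))
  cat(sprintf("  overall (balanced) error: %.2f%%\n",
              100 * x$overall_error))
  invisible(x)
}

#' Select the number of principal components by LOOCV error
#'
#' Scans `k = 1 ... k_max` and returns the smallest `k` achieving the
#' minimum LOOCV balanced error (ties go to the smaller, more parsimonious
#' `k`). Inside each fold the PCA basis is computed once with `k_max`
#' components; truncating to the first `k` columns is identical to a
#' `k`-component refit, so the scan stays leakage-free.
#'
#' @param x Subjects-by-features matrix.
#' @param labels Class labels.
#' @param k_max Largest component count to try,
#'   `<= min(nrow(x) - 2, ncol(x))`.
#' @param positive_label,control_label Passed to [fit_lda()].
#' @return An object of class `pc_selection`: `selected` (integer) and
#'   `profile` (data.frame `n_components`, `overall_error`).
#' @export
select_n_components <- function(x, labels, k_max,
                                positive_label = "OSAS",
                                control_label = "CTR") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  kcap <- min(n - 2L, ncol(x))
  if (k_max < 1L || k_max > kcap) {
    stop("k_max must be in 1..", kcap, ", got ", k_max, call. = FALSE)
  }
  classes <- unique(labels)
  neg_label <- setdiff(classes, positive_label)
  predicted <- matrix(NA_character_, nrow = n, ncol = k_max)
  for (i in seq_len(n)) {
    pca <- fit_pca(x[-i, , drop = FALSE], k_max)
    te <- pca_project(pca, x[i, , drop = FALSE])
    for (k in seq_len(k_max)) {
      lda <- fit_lda(pca$scores[, seq_len(k), drop = FALSE], labels[-i],
                     positive_label, control_label)
      cv <- lda_score(lda, te[, seq_len(k), drop = FALSE])
      predicted[i, k] <- lda_predict(lda, cv)
    }
  }
  errs <- vapply(seq_len(k_max), function(k) {
    conf <- .confusion_counts(labels, predicted[, k], positive_label)
    mean(c(conf[["FN"]] / sum(labels == positive_label),
           conf[["FP"]] / sum(labels == neg_label)))
  }, numeric(1))
  structure(list(
    selected = which.min(errs),  # which.min returns the first (smallest k)
    profile = data.frame(n_components = seq_len(k_max),
                         overall_error = errs)
  ), class = "pc_selection")
}

#' @export
print.pc_selection <- function(x, ...) {
  cat(sprintf("PC-count selection: k = %d (LOOCV balanced error %.2f%%)\n",
              x$selected,
              100 * x$profile$overall_error[x$selected]))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Standard definitions: accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, plus the
#' balanced error rate `(FN/(TP+FN) + FP/(TN+FP))/2`.
#'
#' @param confusion Named numeric vector or list with `TP`, `FN`, `TN`,
#'   `FP` (all >= 0; both class margins and `TP+FP` must be positive).
#' @return An object of class `classification_metrics`: `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `balanced_error`.
#' @export
compute_metrics <- function(confusion) {
  conf <- unlist(confusion)[c("TP", "FN", "TN", "FP")]
  if (anyNA(conf) || any(conf < 0)) {
    stop("confusion must supply non-negative TP, FN, TN, FP",
         call. = FALSE)
  }
  if (conf[["TP"]] + conf[["FN"]] == 0 || conf[["TN"]] + conf[["FP"]] == 0) {
    stop("undefined metrics: a class margin is empty", call. = FALSE)
  }
  if (conf[["TP"]] + conf[["FP"]] == 0) {
    stop("undefined metric: precision has no predicted positives",
         call. = FALSE)
  }
  structure(list(
    accuracy = (conf[["TP"]] + conf[["TN"]]) / sum(conf),
    sensitivity = conf[["TP"]] / (conf[["TP"]] + conf[["FN"]]),
    specificity = conf[["TN"]] / (conf[["TN"]] + conf[["FP"]]),
    precision = conf[["TP"]] / (conf[["TP"]] + conf[["FP"]]),
    balanced_error = mean(c(conf[["FN"]] / (conf[["TP"]] + conf[["FN"]]),
                            conf[["FP"]] / (conf[["TN"]] + conf[["FP"]])))
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, precision %.2f%%, balanced error %.2f%%\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$precision, 100 * x$balanced_error))
  invisible(x)
}

#' Reconstruct a confusion matrix from per-group error rates
#'
#' Given published per-group misclassification rates and group sizes,
#' rounds `rate * n` to the nearest integer error count and rebuilds the
#' confusion counts (positives = disease class).
#'
#' @param error_positive Misclassification fraction of the positive
#'   (disease) group.
#' @param error_negative Misclassification fraction of the negative
#'   (control) group.
#' @param n_positive,n_negative Group sizes.
#' @return Named vector `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_from_group_errors <- function(error_positive, error_negative,
                                        n_positive, n_negative) {
  fn <- round(error_positive * n_positive)
  fp <- round(error_negative * n_negative)
  c(TP = n_positive - fn, FN = fn, TN = n_negative - fp, FP = fp)
}

#' ROC curve and AUC of canonical-variable scores
#'
#' Builds the stepwise ROC over all score thresholds. The AUC equals the
#' Mann-Whitney U statistic of the scores divided by `n1 * n2` (ties
#' counted 1/2); the two-sided asymptotic p-value for AUC = 0.5 uses the
#' tie-corrected normal approximation of the rank-sum null. Scores must be
#' oriented so that larger values indicate the positive class (pass the
#' negated canonical variable when disease scores are negative).
#'
#' Constant scores are not an error: they yield AUC 0.5 with p = 1.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Class labels, both classes present.
#' @param positive_label Label of the positive (disease) class.
#' @return An object of class `roc_result`: `fpr`, `tpr`, `thresholds`,
#'   `auc`, `asymptotic_p`, `n_positive`, `n_negative`.
#' @export
roc_of_scores <- function(scores, labels, positive_label = "OSAS") {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive_label
  n1 <- sum(pos)
  n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  # stepwise ROC: sweep thresholds from +Inf downward over unique scores
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- pos[o]
  uniq <- !duplicated(s)
  cum_tp <- cumsum(p)
  cum_fp <- cumsum(!p)
  last_of_tie <- c(uniq[-1], TRUE)
  tpr <- c(0, cum_tp[last_of_tie] / n1)
  fpr <- c(0, cum_fp[last_of_tie] / n2)
  thresholds <- c(Inf, s[last_of_tie])
  # AUC via the rank statistic, ties counted 1/2
  r <- rank(scores)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  nn <- n1 + n2
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  asymptotic_p <- if (sigma2 <= 0) {
    1
  } else {
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }
  structure(list(
    fpr = fpr, tpr = tpr, thresholds = thresholds,
    auc = auc, asymptotic_p = asymptotic_p,
    n_positive = n1, n_negative = n2
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (n+ = %d, n- = %d), asymptotic p = %.3g\n",
              x$auc, x$n_positive, x$n_negative, x$asymptotic_p))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
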