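# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately avoid the package's own code paths.

# ROC AUC by exhaustive pair counting; ties count 1/2.
oracle_auc_paircount <- function(scores, labels, positive = "OSAS") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) {
    for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Mann-Whitney U by exhaustive pair counting (U of sample a over b).
oracle_u_paircount <- function(a, b) {
  total <- 0
  for (x in a) for (y in b) total <- total + (x > y) + 0.5 * (x == y)
  total
}

# All permutations of 1..n as a list, by insertion recursion.
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# Spearman rho (no ties) and exact two-sided permutation p.
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  perms <- oracle_perms(n)
  rhos <- vapply(perms, function(p) {
    1 - 6 * sum((rx - ry[p])^2) / (n * (n^2 - 1))
  }, numeric(1))
  list(rho = rho,
       p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# From-scratch delete-one PCA-LDA cross-validation using prcomp and an
# explicitly assembled Fisher discriminant (midpoint threshold, control
# mean oriented positive).
oracle_loocv <- function(x, labels, k, positive = "OSAS",
                         control = "CTR") {
  n <- nrow(x)
  cv <- numeric(n)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- x[-i, , drop = FALSE]
    pc <- stats::prcomp(tr, center = TRUE, scale. = FALSE)
    str <- pc$x[, 1:k, drop = FALSE]
    ste <- scale(x[i, , drop = FALSE], center = pc$center,
                 scale = FALSE) %*% pc$rotation[, 1:k, drop = FALSE]
    lab <- labels[-i]
    m1 <- colMeans(str[lab == positive, , drop = FALSE])
    m2 <- colMeans(str[lab != positive, , drop = FALSE])
    sw <- crossprod(sweep(str[lab == positive, , drop = FALSE], 2, m1)) +
      crossprod(sweep(str[lab != positive, , drop = FALSE], 2, m2))
    d <- solve(sw, m1 - m2)
    d <- d / sqrt(sum(d^2))
    proj <- drop(str %*% d)
    if (mean(proj[lab == control]) < 0) {
      d <- -d
      proj <- -proj
    }
    thr <- (mean(proj[lab == positive]) + mean(proj[lab != positive])) / 2
    sc <- drop(ste %*% d)
    cv[i] <- sc
    upper <- if (mean(proj[lab == positive]) > thr) positive else control
    lower <- setdiff(c(positive, control), upper)
    pred[i] <- if (sc > thr) upper else lower
  }
  list(cv_scores = cv, predicted = pred)
}

# A synthetic spectrum at an arbitrary stage: Gaussian peaks on a given
# axis (no baseline, no noise unless supplied).
make_peak_spectrum <- function(wn, peaks, noise_sd = 0, stage = "raw",
                               subject_id = "S1") {
  y <- numeric(length(wn))
  for (p in peaks) {
    y <- y + p$amp * exp(-(wn - p$center)^2 / (2 * p$sigma^2))
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(wn), 0, noise_sd)
  raman_spectrum(wn, y, subject_id = subject_id, stage = stage)
}

# Small planted two-class matrix: class signal lives in the leading
# variance direction.
make_toy_matrix <- function(n1 = 4L, n2 = 4L, p = 20L, sep = 4,
                            seed = 42L) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n1 * p + n2 * p), n1 + n2, p)
  x[seq_len(n1), 1] <- x[seq_len(n1), 1] + sep
  rownames(x) <- sprintf("S%02d", seq_len(n1 + n2))
  list(x = x, labels = c(rep("OSAS", n1), rep("CTR", n2)))
}
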