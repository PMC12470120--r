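# Spectral preprocessing: QC gate, polynomial baseline, reference-peak
# alignment, common-grid resampling, normalization, replicate averaging,
# and group summaries.

#' Preprocessing configuration
#'
#' Defaults reproduce the standard saliva workflow: a third-degree
#' polynomial fluorescence baseline is subtracted, spectra are rigidly
#' aligned on the reference peak near 1000 cm^-1, resampled onto a common
#' 967-point grid starting at 400 cm^-1 with a 1.21 cm^-1 step, and
#' L2-normalized before per-subject averaging.
#'
#' @param baseline_degree Polynomial degree for the baseline (>= 0).
#' @param baseline_mode `"iterative_masked"` (default; peaks are iteratively
#'   clipped so they do not drag the fit upward) or `"plain_ls"` (single
#'   least-squares fit through all points).
#' @param qc_window `(lo, hi)` window in cm^-1 containing the reference peak
#'   used for the quality gate and alignment.
#' @param qc_min_snr Minimum signal-to-noise ratio for the QC gate.
#' @param align_reference Wavenumber the reference-peak apex is shifted to.
#' @param grid_start,grid_step,grid_points Common resampling grid:
#'   `grid_start + (0:(grid_points-1)) * grid_step` cm^-1.
#' @param normalization `"l2"` (unit Euclidean norm, default), `"area"`
#'   (unit trapezoid integral of |intensity|), or `"none"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_degree = 3L,
                              baseline_mode = c("iterative_masked", "plain_ls"),
                              qc_window = c(990, 1012),
                              qc_min_snr = 3.0,
                              align_reference = 1000.0,
                              grid_start = 400.0,
                              grid_step = 1.21,
                              grid_points = 967L,
                              normalization = c("l2", "area", "none")) {
  baseline_mode <- match.arg(baseline_mode)
  normalization <- match.arg(normalization)
  stopifnot(baseline_degree >= 0,
            length(qc_window) == 2L, qc_window[1] < qc_window[2],
            qc_min_snr > 0, grid_step > 0, grid_points >= 2L)
  structure(list(
    baseline_degree = as.integer(baseline_degree),
    baseline_mode = baseline_mode,
    qc_window = as.numeric(qc_window),
    qc_min_snr = qc_min_snr,
    align_reference = align_reference,
    grid_start = grid_start,
    grid_step = grid_step,
    grid_points = as.integer(grid_points),
    normalization = normalization
  ), class = "preprocess_config")
}

#' Common wavenumber grid of a preprocessing configuration
#'
#' @param config A [preprocess_config()].
#' @return Numeric vector `grid_start + (0:(grid_points-1)) * grid_step`.
#' @export
target_grid <- function(config) {
  config$grid_start + (seq_len(config$grid_points) - 1L) * config$grid_step
}

#' Quality-control gate on the reference peak
#'
#' Operationalizes the acquisition rule that spectra without a visible
#' reference (phenylalanine) peak near 1000 cm^-1 are discarded. The SNR is
#' `(max intensity inside qc_window - median of the flanking 20 cm^-1) /
#' (MAD of the flanks, scaled by 1.4826)`; the spectrum passes when
#' SNR >= `qc_min_snr`.
#'
#' @param spectrum A raw [raman_spectrum] covering `qc_window`.
#' @param config A [preprocess_config()].
#' @return A list with `pass` (logical), `snr`, `peak_height`,
#'   `noise_scale`, `subject_id`, `replicate_index`.
#' @export
qc_gate <- function(spectrum, config = preprocess_config()) {
  validate_raman_spectrum(spectrum)
  wn <- spectrum$wavenumbers
  win <- config$qc_window
  if (win[1] < wn[1] || win[2] > wn[length(wn)]) {
    stop("QC window ", win[1], "-", win[2],
         " cm^-1 not covered by spectrum axis", call. = FALSE)
  }
  inside <- wn >= win[1] & wn <= win[2]
  flank <- (wn >= win[1] - 20 & wn < win[1]) |
    (wn > win[2] & wn <= win[2] + 20)
  if (sum(flank) < 3L) {
    stop("QC flanks (20 cm^-1 beside the window) not covered by axis",
         call. = FALSE)
  }
  y <- spectrum$intensities
  peak_height <- max(y[inside]) - stats::median(y[flank])
  noise <- stats::mad(y[flank])  # MAD * 1.4826 (default constant)
  snr <- if (noise == 0) {
    if (peak_height > 0) Inf else 0
  } else {
    peak_height / noise
  }
  list(pass = snr >= config$qc_min_snr,
       snr = snr,
       peak_height = peak_height,
       noise_scale = noise,
       subject_id = spectrum$subject_id,
       replicate_index = spectrum$replicate_index)
}

# Fit a polynomial baseline on a conditioning-scaled axis. In
# iterative_masked mode the working intensities are clipped to the current
# fit after each pass, so peaks are progressively excluded from the fit;
# iteration stops when the maximum change falls below 1e-6 of the intensity
# range, or after 50 passes.
.fit_baseline <- function(wn, y, degree, mode) {
  if (length(y) < degree + 1L) {
    stop("baseline fit needs at least degree+1 = ", degree + 1L,
         " points, got ", length(y), call. = FALSE)
  }
  u <- (wn - mean(wn)) / (diff(range(wn)) / 2)
  X <- outer(u, 0:degree, `^`)
  # the design is fixed: factor once and apply the pseudo-inverse directly
  qx <- qr(X)
  pinv <- backsolve(qr.R(qx), t(qr.Q(qx)))
  fit_once <- function(target) {
    drop(X %*% (pinv %*% target))
  }
  if (mode == "plain_ls") {
    return(fit_once(y))
  }
  scale <- max(diff(range(y)), .Machine$double.eps)
  yw <- y
  base <- fit_once(yw)
  for (i in seq_len(50L)) {
    ynew <- pmin(yw, base)
    if (max(abs(ynew - yw)) < 1e-6 * scale) break
    yw <- ynew
    base <- fit_once(yw)
  }
  base
}

#' Subtract a polynomial fluorescence baseline
#'
#' Removes a degree-`baseline_degree` polynomial background (fluorescence /
#' photoluminescence) from a raw spectrum. The default iterative masked mode
#' repeatedly fits the polynomial and clips intensities above the fit, so
#' Raman peaks do not bias the baseline upward; `"plain_ls"` is a single
#' unmasked least-squares fit. Corrected intensities may be negative.
#'
#' @param spectrum A `raw` [raman_spectrum].
#' @param config A [preprocess_config()].
#' @return The baseline-corrected spectrum (stage `baseline_corrected`).
#' @export
subtract_baseline <- function(spectrum, config = preprocess_config()) {
  validate_raman_spectrum(spectrum)
  .assert_stage(spectrum, "raw", "subtract_baseline")
  base <- .fit_baseline(spectrum$wavenumbers, spectrum$intensities,
                        config$baseline_degree, config$baseline_mode)
  spectrum$intensities <- spectrum$intensities - base
  .advance_stage(spectrum, "baseline_corrected")
}

# Vertex of the parabola through three (x, y) points; NA when degenerate
# or not concave.
.parabola_apex <- function(x, y) {
  d <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  if (d == 0) return(NA_real_)
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / d
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / d
  if (a >= 0) return(NA_real_)
  -b / (2 * a)
}

#' Align a spectrum on the reference peak
#'
#' Locates the apex of the QC-window peak by parabolic interpolation over
#' the three points around the discrete maximum and rigidly shifts the
#' whole axis by `align_reference - apex`. Shifts larger than 10 cm^-1 in
#' magnitude indicate an implausible miscalibration and raise an error.
#'
#' @param spectrum A `baseline_corrected` [raman_spectrum] that passed
#'   [qc_gate()].
#' @param config A [preprocess_config()].
#' @return The aligned spectrum (stage `aligned`) with the applied shift
#'   recorded in `$alignment_shift`.
#' @export
align_spectrum <- function(spectrum, config = preprocess_config()) {
  validate_raman_spectrum(spectrum)
  .assert_stage(spectrum, "baseline_corrected", "align_spectrum")
  wn <- spectrum$wavenumbers
  win <- config$qc_window
  if (win[1] < wn[1] || win[2] > wn[length(wn)]) {
    stop("QC window not covered by spectrum axis", call. = FALSE)
  }
  idx <- which(wn >= win[1] & wn <= win[2])
  imax <- idx[which.max(spectrum$intensities[idx])]
  apex <- wn[imax]
  if (imax > 1L && imax < length(wn)) {
    ii <- (imax - 1L):(imax + 1L)
    refined <- .parabola_apex(wn[ii], spectrum$intensities[ii])
    if (!is.na(refined) && refined >= wn[imax - 1L] &&
        refined <= wn[imax + 1L]) {
      apex <- refined
    }
  }
  shift <- config$align_reference - apex
  if (abs(shift) > 10) {
    stop(sprintf(
      "alignment error: required shift %.2f cm^-1 exceeds 10 cm^-1 (apex at %.2f)",
      shift, apex), call. = FALSE)
  }
  spectrum$wavenumbers <- wn + shift
  spectrum$alignment_shift <- shift
  .advance_stage(spectrum, "aligned")
}

#' Resample a spectrum onto the common grid
#'
#' Linear interpolation onto `grid_start + k * grid_step`,
#' `k = 0 ... grid_points - 1`. The aligned axis must cover the whole grid.
#'
#' @param spectrum An `aligned` [raman_spectrum].
#' @param config A [preprocess_config()].
#' @return The resampled spectrum (stage `resampled`).
#' @export
resample_to_grid <- function(spectrum, config = preprocess_config()) {
  validate_raman_spectrum(spectrum)
  .assert_stage(spectrum, "aligned", "resample_to_grid")
  grid <- target_grid(config)
  wn <- spectrum$wavenumbers
  lo_uncovered <- grid[1] < wn[1]
  hi_uncovered <- grid[length(grid)] > wn[length(wn)]
  if (lo_uncovered || hi_uncovered) {
    ends <- c(if (lo_uncovered)
      sprintf("low end (grid %.2f < axis %.2f)", grid[1], wn[1]),
      if (hi_uncovered)
        sprintf("high end (grid %.2f > axis %.2f)",
                grid[length(grid)], wn[length(wn)]))
    stop("grid extends beyond spectrum axis at the ",
         paste(ends, collapse = " and "), call. = FALSE)
  }
  out <- stats::approx(wn, spectrum$intensities, xout = grid,
                       method = "linear", rule = 1)$y
  spectrum$wavenumbers <- grid
  spectrum$intensities <- out
  .advance_stage(spectrum, "resampled")
}

#' Normalize a resampled spectrum
#'
#' `"l2"` scales the intensity vector to unit Euclidean norm; `"area"` to a
#' unit trapezoid integral of |intensity|; `"none"` leaves intensities
#' unchanged (the stage still advances so the pipeline order is explicit).
#'
#' @param spectrum A `resampled` [raman_spectrum].
#' @param config A [preprocess_config()].
#' @return The normalized spectrum (stage `normalized`).
#' @export
normalize_spectrum <- function(spectrum, config = preprocess_config()) {
  validate_raman_spectrum(spectrum)
  .assert_stage(spectrum, "resampled", "normalize_spectrum")
  y <- spectrum$intensities
  if (all(y == 0)) {
    stop("cannot normalize an all-zero spectrum", call. = FALSE)
  }
  y <- switch(config$normalization,
    l2 = y / sqrt(sum(y^2)),
    area = y / pracma::trapz(spectrum$wavenumbers, abs(y)),
    none = y
  )
  spectrum$intensities <- y
  .advance_stage(spectrum, "normalized")
}

#' Average replicate spectra into one subject spectrum
#'
#' Pointwise arithmetic mean of replicates on an identical grid, yielding
#' the one-spectrum-per-subject unit that all downstream analysis uses.
#'
#' @param replicates Non-empty list of [raman_spectrum] objects at stage
#'   `resampled` or `normalized`, same subject, identical grids.
#' @return A [raman_spectrum] at stage `averaged`.
#' @export
average_subject <- function(replicates) {
  if (length(replicates) == 0L) {
    stop("no replicates to average", call. = FALSE)
  }
  lapply(replicates, validate_raman_spectrum)
  lapply(replicates, .assert_stage, expected = c("resampled", "normalized"),
         op = "average_subject")
  ids <- unique(vapply(replicates, `[[`, character(1), "subject_id"))
  if (length(ids) != 1L) {
    stop("replicates belong to different subjects: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  wn <- replicates[[1]]$wavenumbers
  for (s in replicates[-1]) {
    if (length(s$wavenumbers) != length(wn) ||
        max(abs(s$wavenumbers - wn)) > 1e-9) {
      stop("grid mismatch among replicates of subject ", ids, call. = FALSE)
    }
  }
  ymat <- do.call(rbind, lapply(replicates, `[[`, "intensities"))
  out <- replicates[[1]]
  out$intensities <- colMeans(ymat)
  out$replicate_index <- 1L
  .advance_stage(out, "averaged")
}

#' Run the full preprocessing chain over a cohort
#'
#' For every replicate: QC gate -> baseline subtraction -> reference-peak
#' alignment -> common-grid resampling -> normalization; then replicates of
#' each subject are averaged. Replicates failing QC are discarded and
#' recorded; subjects whose replicates all fail are dropped with a warning.
#'
#' @param cohort A `raman_cohort` of raw spectra (see [assemble_cohort()]).
#' @param config A [preprocess_config()].
#' @return The cohort with per-subject `averaged` spectra, the common
#'   `grid`, and a `qc_log` data.frame (one row per replicate: snr, pass).
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  stopifnot(inherits(cohort, "raman_cohort"))
  qc_rows <- list()
  for (sid in names(cohort$subjects)) {
    subj <- cohort$subjects[[sid]]
    kept <- list()
    for (rep in subj$replicates) {
      qc <- qc_gate(rep, config)
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        subject_id = sid, replicate_index = rep$replicate_index,
        snr = qc$snr, pass = qc$pass, stringsAsFactors = FALSE)
      if (!qc$pass) next
      s <- subtract_baseline(rep, config)
      s <- align_spectrum(s, config)
      s <- resample_to_grid(s, config)
      s <- normalize_spectrum(s, config)
      kept[[length(kept) + 1L]] <- s
    }
    if (length(kept) == 0L) {
      warning("all replicates of subject ", sid,
              " failed QC; subject dropped from analysis", call. = FALSE)
      cohort$subjects[[sid]]$averaged <- NULL
      next
    }
    cohort$subjects[[sid]]$averaged <- average_subject(kept)
  }
  cohort$grid <- target_grid(config)
  cohort$qc_log <- do.call(rbind, qc_rows)
  cohort
}

#' Group mean and SD spectrum
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator) across
#' the averaged spectra of one group's subjects.
#'
#' @param cohort A preprocessed `raman_cohort`.
#' @param group `"OSAS"` or `"CTR"`.
#' @return An object of class `group_spectrum_summary` with `group`,
#'   `wavenumbers`, `mean_spectrum`, `sd_spectrum`, `n`.
#' @export
group_summary <- function(cohort, group) {
  stopifnot(inherits(cohort, "raman_cohort"))
  mat <- spectral_matrix(cohort)
  grp <- cohort$clinical$group[match(rownames(mat),
                                     cohort$clinical$subject_id)]
  sel <- grp == group
  if (!any(sel)) {
    stop("no averaged spectra for group ", sQuote(group), call. = FALSE)
  }
  m <- mat[sel, , drop = FALSE]
  structure(list(
    group = group,
    wavenumbers = attr(mat, "wavenumbers"),
    mean_spectrum = colMeans(m),
    sd_spectrum = apply(m, 2, stats::sd),
    n = sum(sel)
  ), class = "group_spectrum_summary")
}

#' Subtraction spectrum between two group summaries
#'
#' Elementwise `mean_a - mean_b`; positive values mark bands more intense
#' in group `a`, negative values bands more intense in group `b`.
#'
#' @param summary_a,summary_b Objects from [group_summary()] on the same
#'   grid.
#' @return Numeric vector with attribute `wavenumbers`.
#' @export
subtraction_spectrum <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "group_spectrum_summary"),
            inherits(summary_b, "group_spectrum_summary"))
  if (length(summary_a$wavenumbers) != length(summary_b$wavenumbers) ||
      max(abs(summary_a$wavenumbers - summary_b$wavenumbers)) > 1e-9) {
    stop("group summaries are on different grids", call. = FALSE)
  }
  out <- summary_a$mean_spectrum - summary_b$mean_spectrum
  attr(out, "wavenumbers") <- summary_a$wavenumbers
  out
}

#' @export
plot.group_spectrum_summary <- function(x, ...) {
  graphics::plot(x$wavenumbers, x$mean_spectrum, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)",
                 main = sprintf("%s mean spectrum (n = %d)", x$group, x$n),
                 ...)
  graphics::lines(x$wavenumbers, x$mean_spectrum + x$sd_spectrum,
                  lty = 3)
  graphics::lines(x$wavenumbers, x$mean_spectrum - x$sd_spectrum,
                  lty = 3)
  invisible(x)
}
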