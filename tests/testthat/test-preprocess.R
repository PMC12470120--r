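# QC gate, baseline subtraction, alignment, resampling, normalization,
# averaging and group summaries.

default_axis <- seq(392, 1608, by = 1.21)

test_that("QC gate estimates the reference-peak SNR", {
  set.seed(21)
  s <- make_peak_spectrum(default_axis,
                          list(list(center = 1003, sigma = 4, amp = 10)),
                          noise_sd = 1)
  qc <- qc_gate(s, preprocess_config())
  expect_true(qc$pass)
  expect_gt(qc$snr, 5)
  expect_lt(qc$snr, 20)  # planted amplitude 10 over unit noise

  zero <- raman_spectrum(default_axis, rep(0, length(default_axis)))
  qc0 <- qc_gate(zero, preprocess_config())
  expect_false(qc0$pass)
  expect_identical(qc0$snr, 0)

  narrow <- raman_spectrum(seq(400, 900, 2), rnorm(251))
  expect_error(qc_gate(narrow, preprocess_config()), "not covered")
})

test_that("QC gate rejects pure noise most of the time", {
  # the gate takes the maximum over ~19 window points against a flank
  # noise estimate from ~33 points, so its false-pass rate on flat noise
  # sits near 10%, not at the pointwise 3-sigma tail; Monte Carlo under
  # the null fixes the ceiling asserted here
  set.seed(22)
  passes <- vapply(1:200, function(i) {
    s <- raman_spectrum(default_axis, rnorm(length(default_axis)))
    qc_gate(s, preprocess_config())$pass
  }, logical(1))
  expect_lt(mean(passes), 0.15)
})

test_that("baseline subtraction annihilates polynomials and preserves peaks", {
  u <- default_axis
  cubic <- 5 + 0.003 * u - 2e-6 * u^2 + 4e-10 * u^3
  s <- raman_spectrum(u, cubic)
  for (mode in c("plain_ls", "iterative_masked")) {
    out <- subtract_baseline(s, preprocess_config(baseline_mode = mode))
    expect_lt(max(abs(out$intensities)), 1e-8 * max(abs(cubic)))
    expect_identical(out$stage, "baseline_corrected")
  }

  # cubic + Gaussian: iterative masking recovers the analytic peak area
  amp <- 100; sigma <- 5
  peak <- amp * exp(-(u - 920)^2 / (2 * sigma^2))
  s2 <- raman_spectrum(u, cubic + peak)
  out2 <- subtract_baseline(s2, preprocess_config())
  sel <- u >= 920 - 4 * sigma & u <= 920 + 4 * sigma
  got <- pracma::trapz(u[sel], out2$intensities[sel])
  want <- amp * sigma * sqrt(2 * pi) *
    diff(pnorm(c(-4, 4)))  # truncated to +-4 sigma
  expect_lt(abs(got - want) / want, 0.05)

  const <- raman_spectrum(u, rep(7, length(u)))
  out3 <- subtract_baseline(const, preprocess_config(baseline_degree = 0L))
  expect_equal(max(abs(out3$intensities)), 0, tolerance = 1e-12)

  expect_error(
    subtract_baseline(raman_spectrum(c(1, 2), c(1, 2)),
                      preprocess_config()),
    "degree\\+1")
})

test_that("alignment recovers planted rigid shifts and rejects implausible ones", {
  base <- make_peak_spectrum(default_axis,
                             list(list(center = 1000, sigma = 4, amp = 10)),
                             stage = "baseline_corrected")
  out <- align_spectrum(base, preprocess_config())
  expect_equal(out$alignment_shift, 0, tolerance = 0.02)

  # displace by exactly two grid steps
  shifted <- make_peak_spectrum(default_axis,
                                list(list(center = 1002.42, sigma = 4,
                                          amp = 10)),
                                stage = "baseline_corrected")
  out2 <- align_spectrum(shifted, preprocess_config())
  expect_equal(out2$alignment_shift, -2.42, tolerance = 0.05)
  # after alignment the apex sits at the reference
  apex_wn <- out2$wavenumbers[which.max(out2$intensities)]
  expect_equal(apex_wn, 1000, tolerance = 1.3)

  far <- make_peak_spectrum(default_axis,
                            list(list(center = 1011.5, sigma = 3, amp = 10)),
                            stage = "baseline_corrected")
  expect_error(align_spectrum(far, preprocess_config()), "alignment error")
})

test_that("resampling is exact on the target grid and on affine intensities", {
  cfg <- preprocess_config()
  grid <- target_grid(cfg)
  expect_length(grid, 967L)

  s <- raman_spectrum(grid, sin(grid / 50), stage = "aligned")
  out <- resample_to_grid(s, cfg)
  expect_identical(out$intensities, s$intensities)

  ramp <- raman_spectrum(default_axis, 2 + 0.5 * default_axis,
                         stage = "aligned")
  out2 <- resample_to_grid(ramp, cfg)
  expect_equal(out2$intensities, 2 + 0.5 * grid, tolerance = 1e-12)
  expect_length(out2$intensities, 967L)

  short <- raman_spectrum(seq(500, 1600, 1.21),
                          rnorm(length(seq(500, 1600, 1.21))),
                          stage = "aligned")
  expect_error(resample_to_grid(short, cfg), "low end")
})

test_that("normalization modes satisfy their definitions", {
  cfg <- preprocess_config()
  grid <- target_grid(cfg)
  set.seed(31)
  y <- abs(rnorm(length(grid))) + 0.1
  s <- raman_spectrum(grid, y, stage = "resampled")
  out <- normalize_spectrum(s, cfg)
  expect_equal(sqrt(sum(out$intensities^2)), 1, tolerance = 1e-12)

  s7 <- raman_spectrum(grid, 7 * y, stage = "resampled")
  out7 <- normalize_spectrum(s7, cfg)
  expect_equal(out7$intensities, out$intensities, tolerance = 1e-12)

  area_cfg <- preprocess_config(normalization = "area")
  outa <- normalize_spectrum(s, area_cfg)
  expect_equal(pracma::trapz(grid, abs(outa$intensities)), 1,
               tolerance = 1e-12)

  zero <- raman_spectrum(grid, rep(0, length(grid)), stage = "resampled")
  expect_error(normalize_spectrum(zero, cfg), "all-zero")
})

test_that("replicate averaging is the pointwise mean with stage bookkeeping", {
  grid <- target_grid(preprocess_config())
  mk <- function(v) raman_spectrum(grid, rep(v, length(grid)),
                                   subject_id = "A", stage = "normalized")
  avg <- average_subject(list(mk(0), mk(2)))
  expect_true(all(avg$intensities == 1))
  expect_identical(avg$stage, "averaged")

  same <- replicate(10, mk(3), simplify = FALSE)
  expect_equal(average_subject(same)$intensities, rep(3, length(grid)))

  # balanced-batch associativity
  set.seed(32)
  reps <- replicate(4, raman_spectrum(grid, rnorm(length(grid)),
                                      subject_id = "A",
                                      stage = "normalized"),
                    simplify = FALSE)
  direct <- average_subject(reps)$intensities
  b1 <- average_subject(reps[1:2])
  b2 <- average_subject(reps[3:4])
  expect_equal((b1$intensities + b2$intensities) / 2, direct,
               tolerance = 1e-12)

  other <- raman_spectrum(grid, rnorm(length(grid)), subject_id = "B",
                          stage = "normalized")
  expect_error(average_subject(c(reps, list(other))), "different subjects")
  expect_error(average_subject(list()), "no replicates")
})

test_that("group summaries and subtraction spectra behave as sample statistics", {
  cfg <- synthetic_cohort_config(seed = 8, n_osas = 5L, n_ctr = 4L,
                                 replicates_per_subject = 2L)
  co <- preprocess_cohort(generate_cohort(cfg)$cohort)
  gs <- group_summary(co, "OSAS")
  expect_true(all(gs$sd_spectrum >= 0))
  expect_identical(gs$n, 5L)

  # hand-computable case through the public matrix
  mat <- spectral_matrix(co)
  sel <- co$clinical$group == "OSAS"
  expect_equal(gs$mean_spectrum, colMeans(mat[sel, ]), tolerance = 1e-12)

  gc <- group_summary(co, "CTR")
  d1 <- subtraction_spectrum(gs, gc)
  d2 <- subtraction_spectrum(gc, gs)
  expect_equal(d1, -d2, tolerance = 1e-12)
  expect_equal(as.numeric(subtraction_spectrum(gs, gs)),
               rep(0, length(gs$mean_spectrum)))
})

test_that("planted group effects appear with the right sign in the subtraction spectrum", {
  cfg <- synthetic_cohort_config(seed = 9, replicates_per_subject = 2L)
  co <- preprocess_cohort(generate_cohort(cfg)$cohort)
  d <- subtraction_spectrum(group_summary(co, "OSAS"),
                            group_summary(co, "CTR"))
  wn <- attr(d, "wavenumbers")
  # alignment moves the phenylalanine apex (1003) to the 1000 reference,
  # so planted bands appear 3 cm^-1 below their nominal centers
  at <- function(center) d[which.min(abs(wn - (center - 3)))]
  for (ctr_band in c(477, 589, 630, 1517)) expect_lt(at(ctr_band), 0)
  for (osas_band in c(920, 957, 1030, 1444)) expect_gt(at(osas_band), 0)
})

test_that("preprocessing is deterministic and recovers the pure peak component", {
  cfg <- synthetic_cohort_config(seed = 10, n_osas = 3L, n_ctr = 3L,
                                 replicates_per_subject = 2L)
  sim <- generate_cohort(cfg)
  p1 <- preprocess_cohort(sim$cohort)
  p2 <- preprocess_cohort(sim$cohort)
  expect_identical(spectral_matrix(p1), spectral_matrix(p2))

  # noise-free replicate: corrected spectrum correlates > 0.99 with the
  # planted peak-sum component
  lib <- default_peak_library()
  lib$osas_multiplier <- 1
  quiet <- synthetic_cohort_config(seed = 10, n_osas = 2L, n_ctr = 2L,
                                   replicates_per_subject = 1L,
                                   peak_library = lib,
                                   replicate_noise_sd = 0,
                                   wavenumber_jitter_sd = 0,
                                   subject_scale_cv = 1e-9)
  co <- preprocess_cohort(generate_cohort(quiet)$cohort)
  mat <- spectral_matrix(co)
  wn <- attr(mat, "wavenumbers")
  pure <- numeric(length(wn))
  for (j in seq_len(nrow(lib))) {
    pure <- pure + lib$base_amplitude[j] * lib$width[j]^2 /
      ((wn + 3 - lib$center[j])^2 + lib$width[j]^2)  # +3: alignment offset
  }
  expect_gt(cor(mat[1, ], pure), 0.99)
})

test_that("stage order is enforced", {
  grid <- target_grid(preprocess_config())
  s <- raman_spectrum(grid, rnorm(length(grid)), stage = "resampled")
  expect_error(subtract_baseline(s), "expects a spectrum at stage")
  expect_error(align_spectrum(s), "expects a spectrum at stage")
  raw <- raman_spectrum(grid, rnorm(length(grid)))
  expect_error(resample_to_grid(raw), "expects a spectrum at stage")
  expect_error(normalize_spectrum(raw), "expects a spectrum at stage")
})
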