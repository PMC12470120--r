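# Synthetic cohort generator: replicate saliva Raman spectra plus clinical
# covariates with the statistical structure the analysis pipeline assumes.

# Run expr with a private RNG stream seeded from `seed`, restoring any
# pre-existing .Random.seed afterwards (no hidden global state).
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default salivary Raman peak library
#'
#' One row per band: `center` (cm^-1), `width` (Lorentzian half-width at
#' half-maximum, or Gaussian sigma, cm^-1), `shape`, `base_amplitude`
#' (a.u.), `osas_multiplier` (group effect on amplitude; > 1 = elevated in
#' OSAS, < 1 = elevated in controls, 1 = neutral), and a molecular `label`.
#' Centers follow the standard saliva band assignments (proteins, lipids,
#' nucleic acids, carbohydrates, pigments), with the lactic-acid band at
#' 920 cm^-1, the phenylalanine reference at 1003 cm^-1, and a
#' group-neutral aluminum substrate band at 1250 cm^-1. OSAS-elevated
#' bands: 920, 957, 1030, 1444; control-elevated bands: 477, 589, 618,
#' 630, 640, 1517, 1548.
#'
#' @return A `data.frame` with one row per peak.
#' @export
default_peak_library <- function() {
  data.frame(
    center = c(477, 505, 589, 618, 630, 640, 755, 825, 853, 875, 920,
               957, 1003, 1030, 1095, 1120, 1153, 1250, 1308, 1444,
               1517, 1548),
    width = c(4.5, 5, 4.5, 4, 4, 4, 4.5, 5, 4.5, 4.5, 5,
              5, 3.5, 4.5, 5.5, 5, 5, 7, 6, 7, 4.5, 5),
    shape = "lorentzian",
    base_amplitude = c(0.22, 0.28, 0.22, 0.30, 0.22, 0.30, 0.35, 0.28,
                       0.40, 0.30, 0.45, 0.38, 1.00, 0.45, 0.30, 0.28,
                       0.28, 0.25, 0.33, 0.60, 0.28, 0.33),
    osas_multiplier = c(0.8, 1, 0.8, 0.8, 0.8, 0.8, 1, 1, 1, 1, 1.25,
                        1.25, 1, 1.25, 1, 1, 1, 1, 1, 1.25, 0.8, 0.8),
    label = c("saccharides", "methoxy", "hydroxyapatite_phosphate",
              "protein_cc_twist", "glycerol", "tyrosine_cs", "tryptophan",
              "phosphodiester", "tyrosine_proline", "phospholipids",
              "lactic_acid", "carotenoids", "phenylalanine",
              "collagen_phenylalanine", "phosphodioxy", "ribose_co",
              "carbohydrates", "aluminum_substrate", "aromatic_amines",
              "cholesterol_fatty_acids", "beta_carotene", "tryptophan_1548"),
    stringsAsFactors = FALSE
  )
}

# Solve a lognormal's (meanlog, sdlog) from a target median and IQR:
# median = exp(mu); IQR = exp(mu) * 2 * sinh(q * sigma), q = Phi^-1(0.75).
.lognormal_from_median_iqr <- function(med, iqr) {
  q <- stats::qnorm(0.75)
  sigma <- stats::uniroot(
    function(s) med * (exp(q * s) - exp(-q * s)) - iqr,
    interval = c(1e-8, 10))$root
  c(meanlog = log(med), sdlog = sigma)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the reference study's conditions: 51 OSAS and 34
#' control subjects, 10 replicate acquisitions each, the
#' [default_peak_library()] with OSAS-elevated bands at 920/957/1030/1444
#' cm^-1 and control-elevated bands at 477/589/618/630/640/1517/1548
#' cm^-1, cubic fluorescence-like baselines, additive noise, per-replicate
#' wavenumber jitter, AHI severity proportions 14:14:23, and per-group
#' lognormal lactate distributions whose (meanlog, sdlog) are root-found
#' from the target medians/IQRs of 13.23 uM (IQR 20.51, OSAS) and 37.76 uM
#' (IQR 54.04, CTR). A latent severity axis modulates the group
#' multipliers (`m^e`, `e ~ N(1, severity_sd)` for OSAS and `N(0,
#' severity_sd)` for controls) and is coupled to lactate through a
#' Gaussian copula with weight `latent_coupling`, oriented so that less
#' spectrally severe subjects carry more lactate.
#'
#' @param n_osas,n_ctr Group sizes.
#' @param replicates_per_subject Replicate acquisitions per subject.
#' @param peak_library Data frame as returned by [default_peak_library()].
#' @param subject_scale_cv Coefficient of variation of the lognormal
#'   per-subject overall intensity scale.
#' @param replicate_noise_sd SD of the additive Gaussian noise (a.u.).
#' @param baseline_coefficients_range List of `(lo, hi)` ranges for the
#'   four cubic baseline coefficients (constant, linear, quadratic, cubic
#'   on the scaled axis `(wavenumber - 1000)/600`).
#' @param wavenumber_jitter_sd SD (cm^-1) of the per-replicate rigid axis
#'   miscalibration that the alignment step must undo.
#' @param severity_sd SD of the latent severity axis within each group.
#' @param latent_coupling Copula weight in `[0, 1]` linking lactate to the
#'   latent severity axis.
#' @param ahi_proportions Named probabilities (mild, moderate, severe)
#'   summing to 1.
#' @param lactate_median_iqr,cortisol_median_iqr,sod3_median_iqr Per-group
#'   lists of `(median, iqr)` targets for the lognormal assay
#'   concentrations.
#' @param gen_range,gen_step Acquisition axis of the generated raw spectra
#'   (slightly wider than the 400-1600 cm^-1 analysis window so alignment
#'   and resampling stay covered).
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(
    n_osas = 51L, n_ctr = 34L,
    replicates_per_subject = 10L,
    peak_library = default_peak_library(),
    subject_scale_cv = 0.15,
    replicate_noise_sd = 0.02,
    baseline_coefficients_range = list(c(2, 6), c(-1, 1), c(-0.5, 0.5),
                                       c(-0.3, 0.3)),
    wavenumber_jitter_sd = 0.3,
    severity_sd = 0.55,
    latent_coupling = 0.40,
    ahi_proportions = c(mild = 14 / 51, moderate = 14 / 51,
                        severe = 23 / 51),
    lactate_median_iqr = list(OSAS = c(13.23, 20.51),
                              CTR = c(37.76, 54.04)),
    cortisol_median_iqr = list(OSAS = c(4.2, 3.5), CTR = c(2.8, 2.2)),
    sod3_median_iqr = list(OSAS = c(150, 110), CTR = c(105, 80)),
    gen_range = c(392, 1608),
    gen_step = 1.21,
    seed = 1L) {
  stopifnot(n_osas >= 1L, n_ctr >= 1L, replicates_per_subject >= 1L,
            subject_scale_cv > 0, replicate_noise_sd >= 0,
            wavenumber_jitter_sd >= 0, severity_sd > 0,
            latent_coupling >= 0, latent_coupling <= 1,
            length(baseline_coefficients_range) == 4L,
            gen_step > 0, gen_range[1] < gen_range[2])
  if (abs(sum(ahi_proportions) - 1) > 1e-8) {
    stop("ahi_proportions must sum to 1", call. = FALSE)
  }
  req <- c("center", "width", "shape", "base_amplitude", "osas_multiplier")
  if (!all(req %in% names(peak_library))) {
    stop("peak_library lacks columns: ",
         paste(setdiff(req, names(peak_library)), collapse = ", "),
         call. = FALSE)
  }
  if (any(peak_library$width <= 0) || any(peak_library$base_amplitude <= 0) ||
      any(peak_library$osas_multiplier <= 0)) {
    stop("peak widths, amplitudes and multipliers must be positive",
         call. = FALSE)
  }
  if (any(peak_library$center < gen_range[1]) ||
      any(peak_library$center > gen_range[2])) {
    stop("peak centers must lie inside gen_range", call. = FALSE)
  }
  structure(list(
    n_osas = as.integer(n_osas), n_ctr = as.integer(n_ctr),
    replicates_per_subject = as.integer(replicates_per_subject),
    peak_library = peak_library,
    subject_scale_cv = subject_scale_cv,
    replicate_noise_sd = replicate_noise_sd,
    baseline_coefficients_range = baseline_coefficients_range,
    wavenumber_jitter_sd = wavenumber_jitter_sd,
    severity_sd = severity_sd,
    latent_coupling = latent_coupling,
    ahi_proportions = ahi_proportions,
    lactate_median_iqr = lactate_median_iqr,
    cortisol_median_iqr = cortisol_median_iqr,
    sod3_median_iqr = sod3_median_iqr,
    gen_range = as.numeric(gen_range),
    gen_step = gen_step,
    seed = as.integer(seed)
  ), class = "synthetic_cohort_config")
}

# Evaluate the peak-sum model at axis positions x for given per-peak
# amplitudes (already including group effect and subject scale).
.peak_sum <- function(x, library, amplitudes) {
  y <- numeric(length(x))
  for (j in seq_len(nrow(library))) {
    c0 <- library$center[j]
    w <- library$width[j]
    y <- y + if (library$shape[j] == "gaussian") {
      amplitudes[j] * exp(-(x - c0)^2 / (2 * w^2))
    } else {
      amplitudes[j] * w^2 / ((x - c0)^2 + w^2)
    }
  }
  y
}

# Draw a lognormal sample from (median, iqr) targets with an optional
# Gaussian-copula latent component `latent` (standard normal scale).
.draw_lognormal <- function(n, med_iqr, latent = NULL, coupling = 0) {
  par <- .lognormal_from_median_iqr(med_iqr[1], med_iqr[2])
  z <- stats::rnorm(n)
  if (!is.null(latent) && coupling > 0) {
    z <- coupling * latent + sqrt(1 - coupling^2) * z
  }
  stats::qlnorm(stats::pnorm(z), meanlog = par[["meanlog"]],
                sdlog = par[["sdlog"]])
}

#' Generate a synthetic cohort of raw spectra and clinical covariates
#'
#' For every subject a lognormal intensity scale and a latent severity
#' score `e` are drawn (`e ~ N(1, severity_sd)` for OSAS, `N(0,
#' severity_sd)` for controls). Each replicate spectrum is the peak-sum
#' model with per-peak amplitude `base_amplitude * osas_multiplier^e *
#' scale`, plus a cubic fluorescence baseline with coefficients drawn
#' uniformly from `baseline_coefficients_range`, additive Gaussian noise,
#' and a rigid per-replicate wavenumber miscalibration `N(0,
#' wavenumber_jitter_sd)`. Covariates: AHI is drawn within the severity
#' bins per `ahi_proportions` (OSAS only, independent of the spectral
#' severity axis); BMI, ESS, age, sex and smoking from documented simple
#' distributions; lactate/cortisol/SOD3 from the per-group lognormals,
#' lactate coupled to the latent severity with weight `latent_coupling`
#' (oriented so spectrally milder subjects carry more lactate, matching
#' the discordance between the spectral 920 cm^-1 band and the assay
#' concentrations).
#'
#' @param config A [synthetic_cohort_config()].
#' @return An object of class `synthetic_cohort`: `cohort` (a
#'   `raman_cohort` of raw spectra), `ground_truth` (per-subject planted
#'   parameters), and the `config`.
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  .with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
  lib <- config$peak_library
  axis <- seq(config$gen_range[1], config$gen_range[2],
              by = config$gen_step)
  n1 <- config$n_osas
  n2 <- config$n_ctr
  n <- n1 + n2
  ids <- c(sprintf("OSAS_%03d", seq_len(n1)),
           sprintf("CTR_%03d", seq_len(n2)))
  group <- c(rep("OSAS", n1), rep("CTR", n2))

  sdlog_scale <- sqrt(log(1 + config$subject_scale_cv^2))
  scale <- stats::rlnorm(n, meanlog = -sdlog_scale^2 / 2,
                         sdlog = sdlog_scale)
  severity <- stats::rnorm(n, mean = ifelse(group == "OSAS", 1, 0),
                           sd = config$severity_sd)
  z_std <- (severity - ifelse(group == "OSAS", 1, 0)) / config$severity_sd

  # clinical covariates
  age <- round(ifelse(group == "OSAS",
                      pmin(pmax(stats::rnorm(n, 66, 10), 25), 82),
                      pmin(pmax(stats::rnorm(n, 61.5, 14), 31), 88)))
  sex <- ifelse(stats::runif(n) <
                  ifelse(group == "OSAS", 29 / 51, 15 / 34), "M", "F")
  ahi <- rep(NA_real_, n)
  cls <- sample(names(config$ahi_proportions), n1, replace = TRUE,
                prob = config$ahi_proportions)
  ahi[group == "OSAS"] <- ifelse(
    cls == "mild", stats::runif(n1, 5, 15),
    ifelse(cls == "moderate", stats::runif(n1, 15, 30),
           stats::runif(n1, 30.1, 70)))
  ahi <- round(ahi, 1)
  bmi <- round(pmax(stats::rnorm(n, mean = ifelse(group == "OSAS", 31, 27),
                                 sd = 4), 19), 1)
  ess <- pmin(pmax(round(stats::rnorm(
    n, mean = ifelse(group == "OSAS", 10, 5), sd = 4)), 0), 24)
  smoking <- sample(c("non_smoker", "former", "smoker"), n,
                    replace = TRUE, prob = c(0.55, 0.25, 0.20))

  # assay concentrations; lactate coupled to -severity (milder spectra,
  # more lactate), reproducing the spectral/assay discordance
  lactate <- numeric(n)
  cortisol <- numeric(n)
  sod3 <- numeric(n)
  for (g in c("OSAS", "CTR")) {
    sel <- group == g
    lactate[sel] <- .draw_lognormal(sum(sel), config$lactate_median_iqr[[g]],
                                    latent = -z_std[sel],
                                    coupling = config$latent_coupling)
    cortisol[sel] <- .draw_lognormal(sum(sel),
                                     config$cortisol_median_iqr[[g]])
    sod3[sel] <- .draw_lognormal(sum(sel), config$sod3_median_iqr[[g]])
  }

  clinical <- data.frame(
    subject_id = ids, group = group, age = age, sex = sex, ahi = ahi,
    bmi = bmi, ess = ess, smoking = smoking,
    lactate_uM = round(lactate, 2), cortisol_ng_ml = round(cortisol, 3),
    sod3_pg_ml = round(sod3, 2), stringsAsFactors = FALSE)

  # spectra
  u <- (axis - 1000) / 600
  spectra <- vector("list", n * config$replicates_per_subject)
  k <- 0L
  mult920 <- numeric(n)
  idx920 <- which.min(abs(lib$center - 920))
  for (i in seq_len(n)) {
    amps <- lib$base_amplitude * lib$osas_multiplier^severity[i] * scale[i]
    mult920[i] <- lib$osas_multiplier[idx920]^severity[i]
    for (r in seq_len(config$replicates_per_subject)) {
      delta <- stats::rnorm(1, 0, config$wavenumber_jitter_sd)
      cc <- vapply(config$baseline_coefficients_range,
                   function(rg) stats::runif(1, rg[1], rg[2]), numeric(1))
      baseline <- cc[1] + cc[2] * u + cc[3] * u^2 + cc[4] * u^3
      # a miscalibrated axis reports the true signal at (x - delta)
      y <- .peak_sum(axis - delta, lib, amps) + baseline +
        stats::rnorm(length(axis), 0, config$replicate_noise_sd)
      k <- k + 1L
      spectra[[k]] <- raman_spectrum(axis, y, subject_id = ids[i],
                                     replicate_index = r, stage = "raw")
    }
  }

  ground_truth <- data.frame(
    subject_id = ids, group = group, scale = scale, severity = severity,
    severity_std = z_std, multiplier_920 = mult920,
    lactate_uM = round(lactate, 2), stringsAsFactors = FALSE)

  structure(list(
    cohort = assemble_cohort(spectra, clinical),
    ground_truth = ground_truth,
    config = config
  ), class = "synthetic_cohort")
}

#' Generate a null cohort with all group effects neutralized
#'
#' Identical mechanics to [generate_cohort()] but every peak multiplier is
#' set to 1, the lactate/severity coupling is zeroed, the latent severity
#' axis is centered at 0 for both groups, and both groups draw their assay
#' concentrations from the OSAS distributions. Group labels are retained,
#' so the cohort supports type-I-error calibration of every downstream
#' test.
#'
#' @param config A [synthetic_cohort_config()].
#' @return A `synthetic_cohort` (see [generate_cohort()]).
#' @export
generate_null_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  null_cfg <- config
  null_cfg$peak_library$osas_multiplier <- 1
  null_cfg$latent_coupling <- 0
  null_cfg$lactate_median_iqr$CTR <- null_cfg$lactate_median_iqr$OSAS
  null_cfg$cortisol_median_iqr$CTR <- null_cfg$cortisol_median_iqr$OSAS
  null_cfg$sod3_median_iqr$CTR <- null_cfg$sod3_median_iqr$OSAS
  # the severity axis keeps its group means, but with all multipliers at 1
  # it has no spectral effect and with coupling 0 no covariate effect
  out <- .with_seed(null_cfg$seed, .generate_cohort_impl(null_cfg))
  out$config <- null_cfg
  out
}

#' Report the planted ground-truth parameters of a synthetic cohort
#'
#' @param x A `synthetic_cohort` produced by [generate_cohort()] or
#'   [generate_null_cohort()].
#' @return A `data.frame`, one row per subject: planted intensity scale,
#'   latent severity, effective 920 cm^-1 multiplier, lactate draw.
#' @export
ground_truth_report <- function(x) {
  if (!inherits(x, "synthetic_cohort")) {
    stop("ground_truth_report requires a cohort produced by this generator",
         call. = FALSE)
  }
  x$ground_truth
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort (seed ", x$config$seed, ")\n", sep = "")
  print(x$cohort)
  invisible(x)
}
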