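---
title: "Methods: saliva Raman chemometrics for sleep-apnea screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saliva Raman chemometrics for sleep-apnea screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Obstructive sleep apnea syndrome (OSAS) is diagnosed by polysomnography,
an expensive overnight study; no accessible molecular screen exists.
Dried-drop Raman micro-spectroscopy of saliva offers a label-free
biochemical fingerprint of the fluid: a single spectrum over the
400–1600 cm^-1 fingerprint region carries bands from proteins, lipids,
nucleic acids, carbohydrates and pigments, including a lactic-acid band at
920 cm^-1 that is of particular interest because nocturnal hypoxia drives
anaerobic glycolysis and lactate production. `salivaraman` implements the
complete analysis chain for such a study: spectral preprocessing, PCA-LDA
classification of OSAS versus control subjects validated by leave-one-out
cross-validation (LOOCV), the 920 cm^-1 peak-area biomarker with its
univariate and stratified statistics, correlation and linear-model
analyses against clinical covariates, and a synthetic cohort generator
that stands in for patient data, which is not publicly deposited in
studies of this kind.

## Preprocessing model

Each acquisition is a `raman_spectrum` (strictly ascending wavenumber axis
plus intensities). The chain is fixed in this order, and every stage
asserts its input stage so the order cannot silently change:

1. **Quality gate.** Acquisitions without a visible phenylalanine
   reference peak near 1000 cm^-1 are discarded. The rule is
   operationalized as a signal-to-noise ratio: the maximum intensity in
   the 990–1012 cm^-1 window minus the median of the two flanking
   20 cm^-1 strips, divided by the robust noise scale of the flanks
   (MAD × 1.4826), must reach `qc_min_snr = 3`. Because the numerator is
   a maximum over ~19 grid points and the noise scale is estimated from
   ~33 flank points, the gate is anticonservative on *pure flat noise*
   (false-pass rate near 10% rather than the pointwise 3-sigma tail);
   this is harmless in practice because real acquisitions always contain
   structure, and a subject whose replicates all fail is dropped with a
   warning.
2. **Baseline subtraction.** Fluorescence background is modeled as a
   third-degree polynomial. The default `iterative_masked` mode
   alternates a least-squares fit with clipping of intensities above the
   fit (up to 50 passes, stopping when the maximum change falls below
   1e-6 of the intensity range), so peaks do not drag the baseline
   upward; `plain_ls` reproduces a naive one-shot subtraction. On a pure
   cubic the residual is at machine precision; on cubic-plus-Gaussian
   input the recovered peak area is within 5% of the analytic value.
3. **Alignment.** A rigid axis shift moves the apex of the QC-window peak
   to `align_reference = 1000` cm^-1. The apex is refined by parabolic
   interpolation through the three points around the discrete maximum,
   which recovers sub-step shifts to a few hundredths of a cm^-1. Shifts
   above 10 cm^-1 indicate miscalibration and are an error. Note the
   deliberate 3 cm^-1 tension between the 1000 cm^-1 reference and the
   phenylalanine band's nominal 1003 cm^-1 position: the reference value
   follows the acquisition convention, is configurable, and — being
   identical for every spectrum — has no effect on classification.
4. **Resampling.** Linear interpolation onto the common grid
   `400 + k · 1.21` cm^-1 with 967 points. The companion convention of
   969 points for a single exported spectrum is reachable via
   `grid_points = 969`; the 967-point grid is the default because the
   subjects × features matrix that the classifier consumes is the
   authoritative object, with the 2-point difference attributable to
   edge loss after alignment.
5. **Normalization.** `l2` (unit Euclidean norm) by default; `area` and
   `none` are available. Dimensionless peak areas of order one require
   some intensity standardization, but no particular choice is implied by
   peak-area magnitudes reported elsewhere, so the absolute scale of
   `auc_920` is a configuration property and only group contrasts are
   asserted by the tests.
6. **Averaging.** The ~10 replicates of a subject are averaged pointwise
   into one spectrum per subject — the unit of all downstream analysis is
   the subject, never the acquisition.

## Classification model

PCA (mean-centered SVD) reduces the 967 features; the leading `k` scores
feed a two-class Fisher discriminant: direction `S_w^{-1}(m_1 - m_2)`
normalized to unit length, midpoint-of-class-means threshold (equal
priors), with a ridge of `1e-8 · trace(S_w)` added only if the
within-class scatter is singular (always logged). The canonical variable
(CV) is oriented so control subjects score positive — negative CV means
OSAS-like.

Validation is leave-one-out: PCA **and** LDA are refit on the 84 retained
subjects of every fold, and the held-out spectrum is projected into that
fold's basis. Refitting inside the fold is the leakage-free choice; a
fixed-basis mode (`refit_pca = FALSE`) exists for comparison with
workflows that decompose once. A dedicated test corrupts the held-out
label and verifies its fold's score is unchanged.

The **overall error is the balanced error rate** — the unweighted mean of
the two per-group misclassification fractions — not the pooled fraction;
with 51/34 subjects the two definitions differ and the balanced one is
what the package reports. PC count is chosen as the smallest `k`
minimizing the balanced LOOCV error over `k = 1..k_max` (ties go to the
more parsimonious model). ROC analysis uses the negated CV scores
(larger = more OSAS-like); the AUC is the Mann–Whitney U statistic over
`n_1 n_2` with ties counted 1/2, and its two-sided p-value uses the
tie-corrected normal approximation of the rank-sum null. Constant scores
yield AUC 0.5 and p = 1 rather than an error.

## The 920 cm^-1 biomarker and its statistics

`peak_auc()` integrates the preprocessed intensities over
910.75–930.13 cm^-1 by the trapezoid rule, with the window endpoints
snapped inward to grid points so the integration bounds are
bit-reproducible (on the default grid: 911.83–929.98 cm^-1). No local
baseline chord is subtracted by default — the global baseline is already
removed — but a chord mode exists because peak-area practice varies.

The downstream battery mirrors standard practice: Shapiro–Wilk normality
per group, then a pooled-variance two-sample t-test on the peak areas
(Welch by flag); one-way ANOVA across AHI severity classes (mild
`[5, 15)`, moderate `[15, 30]`, severe `> 30` events/h — 15 and 30 belong
to moderate) and a t-test across BMI classes (overweight 25–29.99, obese
≥ 30 kg/m^2; below 25 excluded and reported); Mann–Whitney tests on the
assay concentrations (lactate, cortisol, SOD3), which enter as input
columns; Spearman correlations (exact permutation p for n ≤ 9 without
ties, t-approximation otherwise). No multiplicity correction is applied
anywhere: nominal p-values are reported, matching how such batteries are
usually presented.

The linear-model pair: first `cv ~ lactate + lactate²` (centered
quadratic to limit collinearity) flags points with Cook's distance
`> 4/n` or |studentized residual| `> 3`, removes them and refits —
reporting raw-scale coefficients, residual Shapiro–Wilk and Breusch–Pagan
p-values; if the initial fit is essentially exact (residual sigma below
`1e-8 · sd(cv)`) no screening is done, since influence measures on
machine-noise residuals are meaningless. Then the joint model
`cv ~ lactate + auc_920` is fit on the retained points, with `beta1`
(lactate) and `beta2` (peak area) as the headline coefficients; perfect
predictor collinearity is a rank-deficiency error, not a silent drop.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates a
cohort of 51 OSAS / 34 control subjects with ~10 replicate spectra each:

* **Spectral model.** A 22-band library of Lorentzian lines (Lorentzian is
  the natural Raman line shape; Gaussian available per band) on a
  392–1608 cm^-1 axis at 1.21 cm^-1 steps, slightly wider than the
  analysis window so alignment and resampling stay covered. Bands at
  920/957/1030/1444 cm^-1 carry amplitude multipliers of 1.25 in OSAS;
  bands at 477/589/618/630/640/1517/1548 cm^-1 carry 0.8 (control-
  elevated); the 1250 cm^-1 aluminum substrate band is group-neutral so
  substrate signal can never drive classification.
* **Heterogeneity.** Each subject draws a lognormal overall intensity
  scale (CV 15%) and a latent severity `e ~ N(1, 0.55)` (OSAS) or
  `N(0, 0.55)` (controls); band amplitudes scale as `multiplier^e`, so
  the two groups overlap along one severity axis instead of being two
  point masses. The 0.55 width was calibrated once so the six-component
  LOOCV AUC averages ~0.88 — a realistic operating point for this assay
  — and was not adjusted afterward.
* **Nuisance structure.** Per replicate: a cubic fluorescence baseline
  with coefficients drawn uniformly from configurable ranges (magnitude
  several times the peak amplitudes), additive Gaussian noise
  (SD 0.02 a.u.), and a rigid axis miscalibration `N(0, 0.3 cm^-1)` that
  the alignment stage must undo.
* **Covariates.** AHI is drawn within the severity bins with proportions
  14:14:23 — *independently* of the spectral severity axis, since the
  motivating cohort showed no CV–AHI correlation. Lactate, cortisol and
  SOD3 are lognormal with per-group (median, IQR) targets; the
  (meanlog, sdlog) pair is root-found from those targets
  (`median = exp(mu)`, `IQR = median · 2 sinh(0.6745 sigma)`). Lactate is
  tied to the latent severity through a Gaussian copula with weight 0.40,
  oriented so spectrally *milder* subjects carry *more* lactate — this
  deliberately reproduces the observed discordance where the spectral
  920 cm^-1 band rises with disease while the assayed concentration
  falls, and the 0.40 weight was calibrated once against a target
  CV–lactate Spearman correlation of ~0.43.
* **Determinism.** All randomness flows from the single config seed
  through a private RNG scope; the caller's `.Random.seed` is untouched,
  and identical configs are byte-identical on disk.

`generate_null_cohort()` keeps the machinery but sets every multiplier to
1, zeroes the copula weight and gives both groups the same concentration
distributions, retaining labels — the substrate for type-I-error
calibration.

What the generator does **not** emulate: correlated (pink) noise, cosmic
rays, detector saturation, water bands, within-subject drift between
replicates, and any real joint distribution of BMI × AHI × lactate (the
couplings are explicit knobs). Passing tests therefore demonstrate the
pipeline's correctness and calibration under a clean generative model,
not clinical performance on real saliva spectra.

## Numerical choices and degenerate inputs

* Non-ascending axes are sorted on read with a warning; duplicate
  wavenumbers are refused (ambiguity, not a quirk).
* Baseline fitting uses a conditioning-scaled axis and a single QR
  factorization reused across masking iterations.
* Parabolic apex refinement falls back to the discrete maximum when the
  three-point parabola is degenerate or not concave.
* A score exactly at the LDA threshold is assigned the disease class
  (boundary cases should fail toward follow-up, not dismissal).
* PC-count ties break to the smaller k; `which.min` guarantees it.
* Identical class means give a degenerate-direction error rather than a
  spurious classifier.
* Mann–Whitney uses the tie-corrected normal approximation without
  continuity correction so identical samples give exactly p = 1.
* All-zero spectra: QC fails them (SNR 0); normalization refuses them.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to keep a complete
run in the tens of minutes on one core while retaining statistical
resolution: type-I calibration of the peak-area t-test uses 400 null
cohorts at the full 51/34 subject split with 2 replicates per subject
(replicate count affects only averaging noise, not test size); classifier
null calibration uses 20 such cohorts; planted-effect recovery uses 20
cohorts at the full default configuration (10 replicates) with the
six-component model; generator marginal checks (lactate medians, AHI
proportions) use single-replicate cohorts, which leave the covariate
draws unchanged.

## Known limitations

* The balanced-error definition, equal-priors threshold, outlier policy
  (Cook's 4/n, |studentized| > 3) and Breusch–Pagan homoscedasticity
  check are documented conventions; alternatives (pooled error,
  frequency priors, Welch t) are flags, not defaults.
* Absolute `auc_920` values depend on the normalization choice; only
  contrasts and directions are meaningful across configurations.
* The pooled t-test on peak areas holds close to nominal size at
  n = 51/34 despite the mild residual skew of normalized peak areas, but
  a single 400-cohort Monte-Carlo batch estimates that size with a
  standard error near one percentage point, so individual calibration
  batches can land a point or two off nominal; the Mann–Whitney path is
  available where distributional caution matters.
* No cosmic-ray despiking, smoothing or scatter correction is performed;
  spectra are assumed exported after detector-side cleanup.
* No vendor binary formats (SPC, JCAMP-DX, LabSpec) in this version.
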