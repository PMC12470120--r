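# Raman spectrum container and stage bookkeeping.

# Processing stages in pipeline order; transitions may only move forward.
.raman_stages <- c("raw", "baseline_corrected", "aligned", "resampled",
                   "normalized", "averaged")

#' Construct a Raman spectrum
#'
#' A `raman_spectrum` holds one acquisition: a strictly ascending Raman-shift
#' axis (cm^-1), an intensity vector (arbitrary units), and provenance
#' metadata (subject id, replicate index, processing stage).
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1, strictly
#'   ascending, length >= 2.
#' @param intensities Numeric vector of intensities, same length as
#'   `wavenumbers`.
#' @param subject_id Subject identifier (character scalar).
#' @param replicate_index Positive integer, 1-based replicate number.
#' @param stage One of `"raw"`, `"baseline_corrected"`, `"aligned"`,
#'   `"resampled"`, `"normalized"`, `"averaged"`.
#'
#' @return An object of class `raman_spectrum`.
#' @export
#' @examples
#' s <- raman_spectrum(c(400, 401.21), c(10, 12), subject_id = "S1")
#' print(s)
raman_spectrum <- function(wavenumbers, intensities,
                           subject_id = NA_character_,
                           replicate_index = 1L,
                           stage = "raw") {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  obj <- structure(
    list(
      wavenumbers = wavenumbers,
      intensities = intensities,
      subject_id = as.character(subject_id),
      replicate_index = as.integer(replicate_index),
      stage = stage,
      alignment_shift = NA_real_
    ),
    class = "raman_spectrum"
  )
  validate_raman_spectrum(obj)
  obj
}

#' Validate a Raman spectrum object
#'
#' Checks the class invariants: equal-length finite vectors, strictly
#' ascending axis with at least two points, a known stage, and a positive
#' replicate index. Called by the constructor and by every pipeline stage.
#'
#' @param x A `raman_spectrum`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_raman_spectrum <- function(x) {
  if (!inherits(x, "raman_spectrum")) {
    stop("not a raman_spectrum object", call. = FALSE)
  }
  n <- length(x$wavenumbers)
  if (n < 2L) {
    stop("spectrum must contain at least 2 points, got ", n, call. = FALSE)
  }
  if (length(x$intensities) != n) {
    stop("wavenumbers (", n, ") and intensities (", length(x$intensities),
         ") differ in length", call. = FALSE)
  }
  if (anyNA(x$wavenumbers) || anyNA(x$intensities)) {
    stop("spectrum contains missing values", call. = FALSE)
  }
  d <- diff(x$wavenumbers)
  if (any(d == 0)) {
    stop("duplicate wavenumber values in axis", call. = FALSE)
  }
  if (any(d < 0)) {
    stop("wavenumber axis must be strictly ascending", call. = FALSE)
  }
  if (!x$stage %in% .raman_stages) {
    stop("unknown stage '", x$stage, "'", call. = FALSE)
  }
  if (is.na(x$replicate_index) || x$replicate_index < 1L) {
    stop("replicate_index must be a positive integer", call. = FALSE)
  }
  invisible(x)
}

# Assert the spectrum is at (or before, when `at_most`) the expected stage,
# then return its stage index. Stage transitions only move forward.
.assert_stage <- function(spectrum, expected, op) {
  if (!spectrum$stage %in% expected) {
    stop(op, " expects a spectrum at stage ",
         paste(sQuote(expected), collapse = " or "),
         ", got ", sQuote(spectrum$stage), call. = FALSE)
  }
  invisible(spectrum)
}

# Advance the stage, enforcing forward-only transitions.
.advance_stage <- function(spectrum, new_stage) {
  old <- match(spectrum$stage, .raman_stages)
  new <- match(new_stage, .raman_stages)
  if (new < old) {
    stop("illegal stage transition ", sQuote(spectrum$stage), " -> ",
         sQuote(new_stage), call. = FALSE)
  }
  spectrum$stage <- new_stage
  spectrum
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf(
    "raman_spectrum: subject %s, replicate %d, stage %s\n  %d points, %.2f-%.2f cm^-1\n",
    x$subject_id, x$replicate_index, x$stage,
    length(x$wavenumbers), rng[1], rng[2]))
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumbers, x$intensities, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)",
                 main = sprintf("%s / replicate %d (%s)",
                                x$subject_id, x$replicate_index, x$stage),
                 ...)
  invisible(x)
}
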