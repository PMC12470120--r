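# Readers/writers for spectra and clinical tables, and cohort assembly.

.sr_dialects <- c("two_column_text", "csv_row")

#' Read a Raman spectrum from disk
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{`two_column_text`}{One acquisition per file: whitespace- or
#'     comma-separated `(wavenumber, intensity)` pairs, one pair per line.
#'     Lines starting with `#` are comments; metadata written by
#'     [write_spectrum()] (`# subject_id:`, `# replicate_index:`,
#'     `# stage:`) is recovered.}
#'   \item{`csv_row`}{Matrix exchange: a CSV with columns `subject_id`,
#'     `replicate_index`, `stage` followed by one column per wavenumber
#'     (column names are the wavenumber values); one spectrum per row.}
#' }
#'
#' A non-ascending axis is sorted with a warning; duplicate wavenumbers are
#' an error.
#'
#' @param path Path to the file.
#' @param dialect `"two_column_text"` (default) or `"csv_row"`.
#' @param row For `csv_row`, which data row to read (default 1).
#' @return A [raman_spectrum].
#' @seealso [write_spectrum()], [read_spectra_csv()]
#' @export
read_spectrum <- function(path, dialect = c("two_column_text", "csv_row"),
                          row = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (dialect == "two_column_text") {
    .read_spectrum_two_column(path)
  } else {
    specs <- read_spectra_csv(path)
    if (row < 1L || row > length(specs)) {
      stop("row ", row, " out of range: file has ", length(specs),
           " spectra", call. = FALSE)
    }
    specs[[row]]
  }
}

.read_spectrum_two_column <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list(subject_id = NA_character_, replicate_index = 1L,
               stage = "raw")
  wn <- numeric(0)
  y <- numeric(0)
  lineno <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*(subject_id|replicate_index|stage)\\s*:\\s*(\\S+)", ln))[[1]]
      if (length(m) == 3L) meta[[m[2]]] <- m[3]
      next
    }
    fields <- strsplit(ln, "[,[:space:]]+")[[1]]
    fields <- fields[nzchar(fields)]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || anyNA(vals)) {
      stop("parse error at line ", i, " of ", path, ": ", sQuote(lines[[i]]),
           call. = FALSE)
    }
    wn <- c(wn, vals[1])
    y <- c(y, vals[2])
    lineno <- c(lineno, i)
  }
  if (length(wn) < 2L) {
    stop("content error in ", path, ": fewer than 2 data points",
         call. = FALSE)
  }
  if (anyDuplicated(wn)) {
    stop("content error in ", path, ": duplicate wavenumber values",
         call. = FALSE)
  }
  if (is.unsorted(wn, strictly = TRUE)) {
    warning("wavenumber axis in ", path, " not ascending; sorted on read",
            call. = FALSE)
    o <- order(wn)
    wn <- wn[o]
    y <- y[o]
  }
  raman_spectrum(wn, y,
                 subject_id = meta$subject_id,
                 replicate_index = as.integer(meta$replicate_index),
                 stage = meta$stage)
}

#' Read all spectra from a csv_row dialect file
#'
#' @param path Path to a `csv_row` file (see [read_spectrum()]).
#' @return A list of [raman_spectrum] objects, one per data row.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta_cols <- c("subject_id", "replicate_index", "stage")
  if (!all(meta_cols %in% names(df))) {
    stop("csv_row file ", path, " lacks required columns ",
         paste(setdiff(meta_cols, names(df)), collapse = ", "),
         call. = FALSE)
  }
  wn_cols <- setdiff(names(df), meta_cols)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wn)) {
    stop("csv_row file ", path, ": non-numeric wavenumber column names",
         call. = FALSE)
  }
  if (anyDuplicated(wn)) {
    stop("content error in ", path, ": duplicate wavenumber values",
         call. = FALSE)
  }
  if (length(wn) < 2L) {
    stop("content error in ", path, ": fewer than 2 data points",
         call. = FALSE)
  }
  if (is.unsorted(wn, strictly = TRUE)) {
    warning("wavenumber axis in ", path, " not ascending; sorted on read",
            call. = FALSE)
  }
  o <- order(wn)
  lapply(seq_len(nrow(df)), function(i) {
    raman_spectrum(wn[o], as.numeric(df[i, wn_cols, drop = TRUE])[o],
                   subject_id = df$subject_id[i],
                   replicate_index = as.integer(df$replicate_index[i]),
                   stage = df$stage[i])
  })
}

#' Write a Raman spectrum to disk
#'
#' Round-trip contract: `read_spectrum(write_spectrum(s))` reproduces the
#' axis and intensities to within 1e-9 relative error and recovers the
#' subject id, replicate index and stage.
#'
#' @param spectrum A [raman_spectrum].
#' @param path Output path.
#' @param dialect `"two_column_text"` (default) or `"csv_row"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path,
                           dialect = c("two_column_text", "csv_row")) {
  dialect <- match.arg(dialect)
  validate_raman_spectrum(spectrum)
  if (dialect == "two_column_text") {
    lines <- c(
      sprintf("# subject_id: %s", spectrum$subject_id),
      sprintf("# replicate_index: %d", spectrum$replicate_index),
      sprintf("# stage: %s", spectrum$stage),
      sprintf("%.15g %.15g", spectrum$wavenumbers, spectrum$intensities)
    )
    ok <- tryCatch({
      writeLines(lines, path)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write spectrum to ", path, call. = FALSE)
  } else {
    write_spectra_csv(list(spectrum), path)
  }
  invisible(path)
}

#' Write a list of spectra as a csv_row dialect file
#'
#' All spectra must share an identical wavenumber axis.
#'
#' @param spectra List of [raman_spectrum] objects on a common axis.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1L)
  lapply(spectra, validate_raman_spectrum)
  wn <- spectra[[1]]$wavenumbers
  same <- vapply(spectra, function(s) {
    length(s$wavenumbers) == length(wn) && all(s$wavenumbers == wn)
  }, logical(1))
  if (!all(same)) {
    stop("csv_row export requires a common wavenumber axis", call. = FALSE)
  }
  df <- data.frame(
    subject_id = vapply(spectra, `[[`, character(1), "subject_id"),
    replicate_index = vapply(spectra, `[[`, integer(1), "replicate_index"),
    stage = vapply(spectra, `[[`, character(1), "stage"),
    stringsAsFactors = FALSE
  )
  mat <- do.call(rbind, lapply(spectra, `[[`, "intensities"))
  colnames(mat) <- sprintf("%.15g", wn)
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write spectra to ", path, call. = FALSE)
  invisible(path)
}

.clinical_groups <- c("OSAS", "CTR")
.smoking_levels <- c("non_smoker", "smoker", "former")

#' Read and validate a clinical covariate table
#'
#' The CSV must contain `subject_id` and `group` columns; recognized
#' optional columns are `age`, `sex`, `ahi`, `bmi`, `ess`, `smoking`,
#' `lactate_uM`, `cortisol_ng_ml`, `sod3_pg_ml`. Unknown columns are kept
#' untouched. Validation enforces: group in \{OSAS, CTR\}; AHI >= 0 when
#' present and >= 5 events/h for OSAS subjects (the mild-severity floor);
#' BMI > 0; ESS an integer score in 0-24; smoking in
#' \{non_smoker, smoker, former\}.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `clinical_table`, one row per subject.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical_table(df)
}

#' Validate an in-memory clinical table
#'
#' @param df A data.frame with at least `subject_id` and `group` columns.
#' @return `df` with class `clinical_table` prepended.
#' @export
validate_clinical_table <- function(df) {
  required <- c("subject_id", "group")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("clinical table lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in clinical table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- !df$group %in% .clinical_groups
  if (any(bad)) {
    stop("unknown group label(s): ",
         paste(unique(df$group[bad]), collapse = ", "),
         " (expected OSAS or CTR)", call. = FALSE)
  }
  if ("ahi" %in% names(df)) {
    present <- !is.na(df$ahi)
    if (any(present & df$ahi < 0)) {
      stop("negative AHI for subject(s): ",
           paste(df$subject_id[present & df$ahi < 0], collapse = ", "),
           call. = FALSE)
    }
    viol <- present & df$group == "OSAS" & df$ahi < 5
    if (any(viol)) {
      stop("OSAS subjects require AHI >= 5 events/h; violated by: ",
           paste(df$subject_id[viol], collapse = ", "), call. = FALSE)
    }
  }
  if ("bmi" %in% names(df)) {
    present <- !is.na(df$bmi)
    if (any(present & df$bmi <= 0)) {
      stop("BMI must be positive; violated by: ",
           paste(df$subject_id[present & df$bmi <= 0], collapse = ", "),
           call. = FALSE)
    }
  }
  if ("ess" %in% names(df)) {
    present <- !is.na(df$ess)
    ok <- df$ess[present] == round(df$ess[present]) &
      df$ess[present] >= 0 & df$ess[present] <= 24
    if (!all(ok)) {
      stop("ESS must be an integer score in 0-24; violated by: ",
           paste(df$subject_id[present][!ok], collapse = ", "),
           call. = FALSE)
    }
  }
  if ("smoking" %in% names(df)) {
    present <- !is.na(df$smoking) & nzchar(df$smoking)
    bad <- present & !df$smoking %in% .smoking_levels
    if (any(bad)) {
      stop("unknown smoking level(s): ",
           paste(unique(df$smoking[bad]), collapse = ", "), call. = FALSE)
    }
  }
  if (!inherits(df, "clinical_table")) {
    class(df) <- c("clinical_table", class(df))
  }
  df
}

#' Assemble a cohort from spectra and clinical records
#'
#' Groups replicate spectra by subject, renumbers replicate indices
#' contiguously from 1 (stable in replicate-index, then input, order), and
#' attaches each subject's clinical row. Every spectrum's subject id must
#' appear in the clinical table.
#'
#' @param spectra List of [raman_spectrum] objects.
#' @param clinical A `clinical_table` (see [read_clinical_table()]).
#' @return An object of class `raman_cohort` with elements `subjects`
#'   (named list of per-subject records), `clinical`, and `grid` (`NULL`
#'   until resampling).
#' @export
assemble_cohort <- function(spectra, clinical) {
  clinical <- validate_clinical_table(as.data.frame(clinical))
  lapply(spectra, validate_raman_spectrum)
  ids <- vapply(spectra, `[[`, character(1), "subject_id")
  orphan <- setdiff(unique(ids), clinical$subject_id)
  if (length(orphan)) {
    stop("spectra reference subject id(s) absent from the clinical table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  subjects <- list()
  for (sid in clinical$subject_id) {
    reps <- spectra[ids == sid]
    if (length(reps)) {
      o <- order(vapply(reps, `[[`, integer(1), "replicate_index"))
      reps <- reps[o]
      for (k in seq_along(reps)) reps[[k]]$replicate_index <- k
    }
    subjects[[sid]] <- list(
      subject_id = sid,
      group = clinical$group[clinical$subject_id == sid],
      replicates = reps,
      averaged = NULL
    )
  }
  structure(list(subjects = subjects, clinical = clinical, grid = NULL),
            class = "raman_cohort")
}

#' @export
print.raman_cohort <- function(x, ...) {
  nrep <- vapply(x$subjects, function(s) length(s$replicates), integer(1))
  navg <- sum(vapply(x$subjects, function(s) !is.null(s$averaged),
                     logical(1)))
  cat(sprintf(
    "raman_cohort: %d subjects (%d OSAS / %d CTR), %d replicate spectra, %d averaged\n",
    length(x$subjects),
    sum(x$clinical$group == "OSAS"), sum(x$clinical$group == "CTR"),
    sum(nrep), navg))
  if (!is.null(x$grid)) {
    cat(sprintf("  common grid: %d points, %.2f-%.2f cm^-1\n",
                length(x$grid), min(x$grid), max(x$grid)))
  }
  invisible(x)
}

#' Extract the subjects-by-wavenumbers matrix of a preprocessed cohort
#'
#' Rows are subjects (in clinical-table order, row names = subject ids),
#' columns are the common-grid wavenumbers of the per-subject averaged
#' spectra. This is the `n_subjects x n_features` object that enters
#' [fit_pca()] / [loocv()].
#'
#' @param cohort A `raman_cohort` whose subjects carry averaged spectra.
#' @return Numeric matrix with attribute `wavenumbers`.
#' @export
spectral_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "raman_cohort"))
  avg <- lapply(cohort$subjects, `[[`, "averaged")
  have <- !vapply(avg, is.null, logical(1))
  if (!any(have)) {
    stop("cohort has no averaged spectra; run preprocess_cohort() first",
         call. = FALSE)
  }
  avg <- avg[have]
  wn <- avg[[1]]$wavenumbers
  mat <- do.call(rbind, lapply(avg, `[[`, "intensities"))
  rownames(mat) <- names(avg)
  attr(mat, "wavenumbers") <- wn
  mat
}
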