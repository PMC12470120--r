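# Workflow glue: run configuration, the simulate/analyze/report entry
# points, and on-disk report assembly.

#' Run configuration for the pipeline entry points
#'
#' Bundles the stage configurations; the whole object is serialized into
#' every output directory so a run is reproducible from its config alone.
#'
#' @param preprocess A [preprocess_config()].
#' @param chemometrics List with `k_max` (largest PC count scanned),
#'   `n_components` (`NULL` to select by LOOCV error, or a fixed count)
#'   and `refit_pca`.
#' @param stats List with `peak_window` (cm^-1) and `chord` for
#'   [peak_auc()], and `welch` for the group t-test.
#' @param synthetic A [synthetic_cohort_config()] (used by
#'   [run_simulate()]), or `NULL`.
#' @param seed Integer seed; overrides the synthetic section's seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       chemometrics = list(k_max = 10L,
                                           n_components = NULL,
                                           refit_pca = TRUE),
                       stats = list(peak_window = c(910.75, 930.13),
                                    chord = FALSE, welch = FALSE),
                       synthetic = synthetic_cohort_config(),
                       seed = 1L) {
  stopifnot(inherits(preprocess, "preprocess_config"))
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synthetic_cohort_config"))
    synthetic$seed <- as.integer(seed)
  }
  structure(list(preprocess = preprocess,
                 chemometrics = chemometrics,
                 stats = stats,
                 synthetic = synthetic,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- rapply(unclass(config), function(v) v, how = "replace")
  x$preprocess <- unclass(config$preprocess)
  if (!is.null(config$synthetic)) {
    syn <- unclass(config$synthetic)
    syn$peak_library <- as.list(syn$peak_library)
    x$synthetic <- syn
  }
  x$package_version <- as.character(utils::packageVersion("salivaraman"))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Deserialize a run configuration from YAML
#'
#' @param path Path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(x$synthetic)) {
    s <- x$synthetic
    syn <- synthetic_cohort_config(
      n_osas = s$n_osas, n_ctr = s$n_ctr,
      replicates_per_subject = s$replicates_per_subject,
      peak_library = as.data.frame(s$peak_library,
                                   stringsAsFactors = FALSE),
      subject_scale_cv = s$subject_scale_cv,
      replicate_noise_sd = s$replicate_noise_sd,
      baseline_coefficients_range = s$baseline_coefficients_range,
      wavenumber_jitter_sd = s$wavenumber_jitter_sd,
      severity_sd = s$severity_sd,
      latent_coupling = s$latent_coupling,
      ahi_proportions = unlist(s$ahi_proportions),
      lactate_median_iqr = lapply(s$lactate_median_iqr, unlist),
      cortisol_median_iqr = lapply(s$cortisol_median_iqr, unlist),
      sod3_median_iqr = lapply(s$sod3_median_iqr, unlist),
      gen_range = unlist(s$gen_range), gen_step = s$gen_step,
      seed = s$seed)
  }
  p <- x$preprocess
  run_config(
    preprocess = preprocess_config(
      baseline_degree = p$baseline_degree,
      baseline_mode = p$baseline_mode,
      qc_window = unlist(p$qc_window),
      qc_min_snr = p$qc_min_snr,
      align_reference = p$align_reference,
      grid_start = p$grid_start, grid_step = p$grid_step,
      grid_points = p$grid_points,
      normalization = p$normalization),
    chemometrics = x$chemometrics,
    stats = x$stats,
    synthetic = syn,
    seed = x$seed)
}

#' Simulate a cohort and write it to disk
#'
#' Writes one two-column text file per replicate spectrum under
#' `out_dir/spectra/`, the clinical table as `clinical.csv`, the planted
#' parameters as `ground_truth.csv`, and the resolved configuration as
#' `config.yaml`. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config A [run_config()] with a non-`NULL` `synthetic` section.
#' @param out_dir Output directory (created if missing).
#' @return The `synthetic_cohort` object, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$synthetic)) {
    stop("run_simulate requires a synthetic section in the configuration",
         call. = FALSE)
  }
  dir.create(file.path(out_dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- generate_cohort(config$synthetic)
  for (subj in sim$cohort$subjects) {
    for (rep in subj$replicates) {
      write_spectrum(rep, file.path(
        out_dir, "spectra",
        sprintf("%s_rep%02d.txt", subj$subject_id, rep$replicate_index)))
    }
  }
  utils::write.csv(sim$cohort$clinical,
                   file.path(out_dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(sim$ground_truth,
                   file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(sim)
}

#' Read a cohort directory written by [run_simulate()]
#'
#' @param dir Directory containing `clinical.csv` and a `spectra/`
#'   subdirectory of two-column text files.
#' @return A `raman_cohort`.
#' @export
read_cohort_dir <- function(dir) {
  clinical <- read_clinical_table(file.path(dir, "clinical.csv"))
  files <- sort(list.files(file.path(dir, "spectra"), full.names = TRUE))
  if (!length(files)) {
    stop("no spectra found under ", file.path(dir, "spectra"),
         call. = FALSE)
  }
  spectra <- lapply(files, read_spectrum)
  assemble_cohort(spectra, clinical)
}

# Ordinal coding of the smoking factor for rank correlations.
.smoking_ordinal <- function(x) {
  match(x, c("non_smoker", "former", "smoker")) - 1L
}

#' Run the full analysis workflow on a cohort
#'
#' QC -> preprocessing -> per-subject averaging -> PCA-LDA LOOCV (with
#' PC-count selection unless a fixed count is configured) -> confusion
#' metrics and ROC of the canonical variable -> lactic-acid peak areas ->
#' group, stratified (AHI class, BMI class) and assay-concentration tests
#' -> Spearman correlations -> quadratic-lactate and joint linear models.
#' Analyses whose covariates are absent are skipped with a recorded note;
#' everything else runs.
#'
#' @param cohort A `raman_cohort` of raw spectra, a `synthetic_cohort`, or
#'   a directory path readable by [read_cohort_dir()].
#' @param config A [run_config()].
#' @return An object of class `osas_analysis` collecting every stage's
#'   result (see Details in the package vignette).
#' @export
analyze_cohort <- function(cohort, config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  stopifnot(inherits(cohort, "raman_cohort"))

  cohort <- preprocess_cohort(cohort, config$preprocess)
  mat <- spectral_matrix(cohort)
  clinical <- cohort$clinical[match(rownames(mat),
                                    cohort$clinical$subject_id), ]
  labels <- clinical$group

  km <- config$chemometrics$k_max
  km <- min(km, nrow(mat) - 2L, ncol(mat))
  selection <- NULL
  if (is.null(config$chemometrics$n_components)) {
    selection <- select_n_components(mat, labels, km)
    k <- selection$selected
  } else {
    k <- config$chemometrics$n_components
  }
  cv_result <- loocv(mat, labels, k,
                     refit_pca = isTRUE(config$chemometrics$refit_pca))
  metrics <- compute_metrics(cv_result$confusion)
  # canonical variable is oriented control-positive; negate for ROC
  roc <- roc_of_scores(-cv_result$cv_scores, labels,
                       positive_label = "OSAS")

  window <- config$stats$peak_window
  auc920 <- vapply(rownames(mat), function(sid) {
    peak_auc(cohort$subjects[[sid]]$averaged, window,
             chord = isTRUE(config$stats$chord))$auc
  }, numeric(1))

  stats_list <- list()
  notes <- character(0)
  osas <- labels == "OSAS"
  add_stat <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      notes[[name]] <<- res
      NULL
    } else {
      stats_list[[name]] <<- res
    }
    invisible(NULL)
  }

  add_stat("shapiro_auc920_osas", shapiro_wilk(auc920[osas]))
  add_stat("shapiro_auc920_ctr", shapiro_wilk(auc920[!osas]))
  add_stat("t_auc920_group",
           two_sample_t(auc920[osas], auc920[!osas],
                        welch = isTRUE(config$stats$welch),
                        group_names = c("OSAS", "CTR")))

  strata_ahi <- tryCatch(stratify(clinical[osas, ], "ahi_class"),
                         error = function(e) NULL)
  if (!is.null(strata_ahi)) {
    groups <- split(auc920[osas], strata_ahi$labels[rownames(mat)[osas]])
    groups <- groups[vapply(groups, length, integer(1)) >= 2L]
    if (length(groups) >= 2L) {
      add_stat("anova_auc920_ahi", anova_oneway(groups))
    } else {
      notes[["anova_auc920_ahi"]] <- "too few AHI strata with n >= 2"
    }
  } else {
    notes[["anova_auc920_ahi"]] <- "ahi column absent"
  }

  strata_bmi <- tryCatch(stratify(clinical[osas, ], "bmi_class"),
                         error = function(e) NULL)
  if (!is.null(strata_bmi)) {
    lab <- strata_bmi$labels[rownames(mat)[osas]]
    ow <- auc920[osas][lab == "overweight" & !is.na(lab)]
    ob <- auc920[osas][lab == "obese" & !is.na(lab)]
    if (length(ow) >= 2L && length(ob) >= 2L) {
      add_stat("t_auc920_bmi",
               two_sample_t(ow, ob, group_names = c("overweight", "obese")))
    } else {
      notes[["t_auc920_bmi"]] <- "too few subjects per BMI class"
    }
  } else {
    notes[["t_auc920_bmi"]] <- "bmi column absent"
  }

  for (assay in c("lactate_uM", "cortisol_ng_ml", "sod3_pg_ml")) {
    nm <- paste0("mw_", sub("_.*", "", assay))
    if (assay %in% names(clinical)) {
      add_stat(nm, mann_whitney(clinical[[assay]][osas],
                                clinical[[assay]][!osas],
                                group_names = c("OSAS", "CTR")))
    } else {
      notes[[nm]] <- paste(assay, "column absent")
    }
  }

  cvs <- cv_result$cv_scores
  correlations <- list()
  add_cor <- function(name, x, y, vars) {
    res <- tryCatch(spearman_cor(x, y, vars),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) notes[[name]] <<- res
    else correlations[[name]] <<- res
    invisible(NULL)
  }
  if ("ahi" %in% names(clinical)) {
    add_cor("cv_ahi", cvs[osas], clinical$ahi[osas], c("cv", "ahi"))
  }
  if ("ess" %in% names(clinical)) {
    add_cor("cv_ess", cvs[osas], clinical$ess[osas], c("cv", "ess"))
  }
  if ("smoking" %in% names(clinical)) {
    add_cor("cv_smoking", cvs[osas],
            .smoking_ordinal(clinical$smoking[osas]), c("cv", "smoking"))
  }
  has_lactate <- "lactate_uM" %in% names(clinical) &&
    sum(!is.na(clinical$lactate_uM[osas])) >= 4L
  if (has_lactate) {
    add_cor("cv_lactate", cvs[osas], clinical$lactate_uM[osas],
            c("cv", "lactate_uM"))
  } else {
    notes[["cv_lactate"]] <- "lactate column absent or too sparse"
  }
  add_cor("cv_auc920", cvs[osas], auc920[osas], c("cv", "auc_920"))
  if ("bmi" %in% names(clinical)) {
    add_cor("auc920_bmi", auc920[osas], clinical$bmi[osas],
            c("auc_920", "bmi"))
  }

  lm_quadratic <- NULL
  lm_joint <- NULL
  if (has_lactate && sum(osas) >= 10L) {
    lm_quadratic <- tryCatch(
      fit_lm_quadratic(cvs[osas], clinical$lactate_uM[osas],
                       rownames(mat)[osas]),
      error = function(e) {
        notes[["lm_quadratic"]] <<- conditionMessage(e)
        NULL
      })
    if (!is.null(lm_quadratic)) {
      lm_joint <- tryCatch(
        fit_lm_joint(cvs[osas], clinical$lactate_uM[osas], auc920[osas],
                     rownames(mat)[osas],
                     exclude = lm_quadratic$removed_points),
        error = function(e) {
          notes[["lm_joint"]] <<- conditionMessage(e)
          NULL
        })
    }
  } else {
    notes[["lm_quadratic"]] <- "lactate column absent or cohort too small"
  }

  structure(list(
    cohort = cohort,
    matrix = mat,
    clinical = clinical,
    qc_log = cohort$qc_log,
    selection = selection,
    cv_result = cv_result,
    metrics = metrics,
    roc = roc,
    auc920 = auc920,
    group_summaries = list(OSAS = group_summary(cohort, "OSAS"),
                           CTR = group_summary(cohort, "CTR")),
    stats = stats_list,
    correlations = correlations,
    lm_quadratic = lm_quadratic,
    lm_joint = lm_joint,
    notes = notes,
    config = config
  ), class = "osas_analysis")
}

#' @export
print.osas_analysis <- function(x, ...) {
  cat("Saliva Raman OSAS analysis\n")
  cat(sprintf("  %d subjects, %d features, %d PCs\n",
              nrow(x$matrix), ncol(x$matrix),
              x$cv_result$n_components_used))
  print(x$cv_result)
  print(x$metrics)
  print(x$roc)
  invisible(x)
}

# Flatten the stats/correlation results into one report table.
.stats_table <- function(analysis) {
  rows <- list()
  for (nm in names(analysis$stats)) {
    s <- analysis$stats[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = nm, test = s$test, statistic = s$statistic,
      p_value = s$p_value,
      n = sum(s$group_summaries$n), stringsAsFactors = FALSE)
  }
  for (nm in names(analysis$correlations)) {
    s <- analysis$correlations[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = nm, test = "spearman", statistic = s$rho,
      p_value = s$p_value, n = s$n, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Run the analysis workflow and write a report directory
#'
#' Executes [analyze_cohort()] stage by stage and writes CSV/text reports:
#' the resolved `config.yaml`, `qc_report.csv`, `spectral_matrix.csv`,
#' `group_summary.csv`, `pc_selection.csv`, `crossval_scores.csv`,
#' `classification_report.txt`, `roc.csv`, `peak_auc.csv`,
#' `stats_report.csv`, `linear_models.txt`, a `summary.txt`, and a
#' `MANIFEST` listing completed stages. On a stage failure the MANIFEST of
#' completed stages is still written and the error (classed with the stage
#' name) is re-raised.
#'
#' @param input Cohort directory path, `raman_cohort`, or
#'   `synthetic_cohort`.
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()].
#' @return The `osas_analysis` object, invisibly.
#' @export
run_analyze <- function(input, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  completed <- character(0)
  fail <- function(stage, e) {
    writeLines(c(completed, paste0("FAILED: ", stage)),
               file.path(out_dir, "MANIFEST"))
    stop(structure(class = c(paste0("stage_error_", stage),
                             "pipeline_stage_error", "error", "condition"),
                   list(message = sprintf("[%s] %s", stage,
                                          conditionMessage(e)),
                        call = NULL)))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) fail(name, e))
    completed <<- c(completed, name)
    res
  }

  write_run_config(config, file.path(out_dir, "config.yaml"))
  analysis <- stage("analysis", analyze_cohort(input, config))

  stage("reports", {
    utils::write.csv(analysis$qc_log,
                     file.path(out_dir, "qc_report.csv"),
                     row.names = FALSE)
    mat_df <- data.frame(subject_id = rownames(analysis$matrix),
                         analysis$matrix, check.names = FALSE,
                         stringsAsFactors = FALSE)
    colnames(mat_df) <- c("subject_id",
                          sprintf("%.6f",
                                  attr(analysis$matrix, "wavenumbers")))
    utils::write.csv(mat_df, file.path(out_dir, "spectral_matrix.csv"),
                     row.names = FALSE)
    gs <- analysis$group_summaries
    utils::write.csv(data.frame(
      wavenumber = gs$OSAS$wavenumbers,
      mean_OSAS = gs$OSAS$mean_spectrum, sd_OSAS = gs$OSAS$sd_spectrum,
      mean_CTR = gs$CTR$mean_spectrum, sd_CTR = gs$CTR$sd_spectrum,
      difference = gs$OSAS$mean_spectrum - gs$CTR$mean_spectrum),
      file.path(out_dir, "group_summary.csv"), row.names = FALSE)
    if (!is.null(analysis$selection)) {
      utils::write.csv(analysis$selection$profile,
                       file.path(out_dir, "pc_selection.csv"),
                       row.names = FALSE)
    }
    cvr <- analysis$cv_result
    utils::write.csv(data.frame(
      subject_id = cvr$subject_id, cv_score = cvr$cv_scores,
      predicted = cvr$predicted, truth = cvr$truth),
      file.path(out_dir, "crossval_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(
      threshold = analysis$roc$thresholds, fpr = analysis$roc$fpr,
      tpr = analysis$roc$tpr),
      file.path(out_dir, "roc.csv"), row.names = FALSE)
    utils::write.csv(data.frame(
      subject_id = names(analysis$auc920),
      group = analysis$clinical$group,
      auc_920 = unname(analysis$auc920)),
      file.path(out_dir, "peak_auc.csv"), row.names = FALSE)
    st <- .stats_table(analysis)
    if (!is.null(st)) {
      utils::write.csv(st, file.path(out_dir, "stats_report.csv"),
                       row.names = FALSE)
    }
    con <- textConnection("cls_lines", "w", local = TRUE)
    sink(con)
    print(analysis$cv_result)
    print(analysis$metrics)
    print(analysis$roc)
    sink()
    close(con)
    writeLines(cls_lines, file.path(out_dir, "classification_report.txt"))
    lm_lines <- character(0)
    for (fit in list(analysis$lm_quadratic, analysis$lm_joint)) {
      if (is.null(fit)) next
      con <- textConnection("fit_lines", "w", local = TRUE)
      sink(con)
      print(fit)
      sink()
      close(con)
      lm_lines <- c(lm_lines, fit_lines, "")
    }
    if (length(lm_lines)) {
      writeLines(lm_lines, file.path(out_dir, "linear_models.txt"))
    }
  })

  stage("summary", {
    writeLines(.summary_lines(analysis), file.path(out_dir, "summary.txt"))
  })

  writeLines(completed, file.path(out_dir, "MANIFEST"))
  invisible(analysis)
}

.summary_lines <- function(analysis) {
  cvr <- analysis$cv_result
  m <- analysis$metrics
  qc <- analysis$qc_log
  lines <- c(
    "Saliva Raman OSAS analysis summary",
    sprintf("package version: %s",
            as.character(utils::packageVersion("salivaraman"))),
    sprintf("subjects analyzed: %d (%d OSAS / %d CTR)",
            nrow(analysis$matrix),
            sum(analysis$clinical$group == "OSAS"),
            sum(analysis$clinical$group == "CTR")),
    sprintf("spectral matrix: %d x %d", nrow(analysis$matrix),
            ncol(analysis$matrix)),
    sprintf("QC: %d/%d replicate spectra passed (%d discarded)",
            sum(qc$pass), nrow(qc), sum(!qc$pass)),
    if (sum(!qc$pass)) sprintf(
      "QC discards: %s",
      paste(sprintf("%s/rep%d", qc$subject_id[!qc$pass],
                    qc$replicate_index[!qc$pass]), collapse = ", ")),
    sprintf("principal components used: %d%s", cvr$n_components_used,
            if (!is.null(analysis$selection)) " (selected by LOOCV error)"
            else " (fixed by configuration)"),
    sprintf("confusion: TP=%d FN=%d TN=%d FP=%d",
            cvr$confusion["TP"], cvr$confusion["FN"],
            cvr$confusion["TN"], cvr$confusion["FP"]),
    sprintf("per-group error: OSAS %.2f%%, CTR %.2f%%",
            100 * cvr$per_group_error[["OSAS"]],
            100 * cvr$per_group_error[["CTR"]]),
    sprintf("overall (balanced) error: %.2f%%", 100 * cvr$overall_error),
    sprintf("accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, precision %.2f%%",
            100 * m$accuracy, 100 * m$sensitivity, 100 * m$specificity,
            100 * m$precision),
    sprintf("ROC AUC of the canonical variable: %.3f (asymptotic p = %.3g)",
            analysis$roc$auc, analysis$roc$asymptotic_p),
    sprintf("lactic-acid peak area (920 cm^-1 window %.2f-%.2f): OSAS mean %.4g, CTR mean %.4g",
            analysis$config$stats$peak_window[1],
            analysis$config$stats$peak_window[2],
            mean(analysis$auc920[analysis$clinical$group == "OSAS"]),
            mean(analysis$auc920[analysis$clinical$group == "CTR"]))
  )
  if (length(analysis$notes)) {
    lines <- c(lines, "skipped analyses:",
               sprintf("  %s: %s", names(analysis$notes),
                       unlist(analysis$notes)))
  }
  lines[!vapply(lines, is.null, logical(1))]
}

#' Collate a results directory into one human-readable report
#'
#' @param results_dir Directory written by [run_analyze()].
#' @param out_file Output path (default `report.txt` inside
#'   `results_dir`).
#' @return `out_file`, invisibly.
#' @export
run_report <- function(results_dir,
                       out_file = file.path(results_dir, "report.txt")) {
  manifest_path <- file.path(results_dir, "MANIFEST")
  if (!file.exists(manifest_path)) {
    stop("no MANIFEST in ", results_dir, "; run run_analyze() first",
         call. = FALSE)
  }
  manifest <- readLines(manifest_path)
  expected <- c("analysis", "reports", "summary")
  missing <- setdiff(expected, manifest)
  lines <- c("=== Saliva Raman pipeline report ===",
             paste("completed stages:", paste(manifest, collapse = ", ")))
  if (length(missing)) {
    lines <- c(lines, paste("missing stages:",
                            paste(missing, collapse = ", ")))
  }
  for (f in c("summary.txt", "classification_report.txt",
              "linear_models.txt")) {
    p <- file.path(results_dir, f)
    if (file.exists(p)) {
      lines <- c(lines, "", paste0("--- ", f, " ---"), readLines(p))
    }
  }
  st <- file.path(results_dir, "stats_report.csv")
  if (file.exists(st)) {
    tab <- utils::read.csv(st)
    lines <- c(lines, "", "--- statistical tests ---",
               utils::capture.output(print(tab, row.names = FALSE)))
  }
  writeLines(lines, out_file)
  invisible(out_file)
}
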