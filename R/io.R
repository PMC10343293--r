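#' Read a concentration table CSV
#'
#' Expected layout: columns `sample_id`, `group`, then one numeric column
#' per metabolite (mmol/mol creatinine); empty cells (or `NA`/`NaN`) mark
#' below-LOD values. Duplicate sample ids and non-numeric cells are
#' rejected with the offending row/column named.
#'
#' @param path CSV file.
#' @return data.frame with the layout above.
#' @export
read_concentration_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       na.strings = c("", "NA", "NaN"))
  if (!all(c("sample_id", "group") %in% names(d)))
    abort(sprintf("%s: need 'sample_id' and 'group' columns", path),
          "format_error")
  dup <- d$sample_id[duplicated(d$sample_id)]
  if (length(dup))
    abort(sprintf("%s: duplicate sample_id: %s", path,
                  paste(unique(dup), collapse = ", ")), "format_error")
  for (m in metabolite_columns(d)) {
    if (!is.numeric(d[[m]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[m]]))) & !is.na(d[[m]]))
      abort(sprintf("%s: non-numeric cell in column '%s' (row %s)", path, m,
                    paste(bad, collapse = ", ")), "format_error")
    }
  }
  d$sample_id <- as.character(d$sample_id)
  d
}

#' Write a concentration table CSV
#'
#' Missing (below-LOD) values are written as empty cells; the round trip
#' through [read_concentration_table()] is lossless.
#'
#' @param table concentration data.frame.
#' @param path output file.
#' @export
write_concentration_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full pipeline on a synthetic (or supplied) cohort
#'
#' Stages, in order: simulate (or load) a concentration table plus
#' metadata; targeted comparison ([compare_groups()]); optionally
#' synthesize spectra, bin them ([assemble_bucket_table()]) and estimate
#' classification accuracy by [mccv()] on the classical-case versus control
#' subset, projecting the remaining (mild/undetermined) cases into the
#' model; phenotype stratification summaries. Deterministic under a fixed
#' `seed`.
#'
#' @param cohort a [cohort_config()], or a list with `table` and `metadata`
#'   for pre-existing data.
#' @param stats_cfg,classifier_cfg,binning_cfg,phenotype_cfg stage
#'   configurations.
#' @param classify run the untargeted spectral classification stage
#'   (slowest stage; default `TRUE`).
#' @param outdir optional directory; when given, CSV/JSON artifacts are
#'   written there.
#' @return A `run_report` list: configs, per-stage dimensions, the
#'   comparison table, confusion matrix + accuracy, projection summary,
#'   phenotype summaries, and any warnings (e.g. phenotype-label flags).
#' @export
run_pipeline <- function(cohort = cohort_config(),
                         stats_cfg = stats_config(),
                         classifier_cfg = classifier_config(),
                         binning_cfg = binning_config(),
                         phenotype_cfg = phenotype_config(),
                         classify = TRUE, outdir = NULL) {
  warnings <- character()
  if (inherits(cohort, "cohort_config")) {
    sim <- simulate_cohort(cohort, spectra = classify)
    tab <- sim$table; meta <- sim$metadata; spectra <- sim$spectra
  } else {
    tab <- cohort$table; meta <- cohort$metadata; spectra <- cohort$spectra
    if (is.null(tab)) abort("cohort must supply `table`", "invalid_parameter")
  }
  report <- list(package_version = as.character(utils::packageVersion("pkunmr")),
                 seed = if (inherits(cohort, "cohort_config")) cohort$seed,
                 stages = list())
  report$stages$input <- list(n_samples = nrow(tab),
                              n_metabolites = length(metabolite_columns(tab)))

  comparison <- compare_groups(tab, config = stats_cfg)
  report$comparison <- comparison
  report$stages$targeted <- list(n_retained = length(lod_filter(tab, stats_cfg)),
                                 n_significant = nrow(comparison))

  if (classify && !is.null(spectra)) {
    bt <- assemble_bucket_table(spectra, binning_cfg,
                                sample_ids = tab$sample_id)
    is_cpku <- meta$phenotype == "cPKU"
    is_ctrl <- meta$phenotype == "control"
    model_rows <- is_cpku | is_ctrl
    lab <- factor(ifelse(is_cpku[model_rows], "cPKU", "control"))
    cm <- mccv(bt$matrix[model_rows, , drop = FALSE], lab, classifier_cfg)
    model <- pcaca_fit(bt$matrix[model_rows, , drop = FALSE], lab,
                       classifier_cfg)
    proj <- NULL
    if (any(!model_rows)) {
      pr <- project(model, bt$matrix[!model_rows, , drop = FALSE])
      proj <- data.frame(sample_id = tab$sample_id[!model_rows],
                         phenotype = meta$phenotype[!model_rows],
                         predicted = as.character(pr$class),
                         pr$display)
    }
    report$confusion <- cm
    report$accuracy <- confusion_accuracy(cm)
    report$projection <- proj
    report$stages$untargeted <- list(n_bins = ncol(bt$matrix),
                                     n_model_samples = sum(model_rows))
  }

  # the GPV rule only speaks to PKU cases; controls carry no GPV
  meta_chk <- check_phenotype_consistency(
    meta[meta$group == "case", , drop = FALSE], phenotype_cfg)
  if (any(meta_chk$phenotype_flag))
    warnings <- c(warnings, sprintf(
      "%d record(s) whose recorded phenotype contradicts the GPV rule: %s",
      sum(meta_chk$phenotype_flag),
      paste(meta_chk$patient_id[meta_chk$phenotype_flag], collapse = ", ")))
  report$phenotype_summary <- group_summary(
    meta[meta$group == "case", , drop = FALSE], "phe_serum")
  report$warnings <- warnings
  class(report) <- "run_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_concentration_table(tab, file.path(outdir, "concentrations.csv"))
    utils::write.csv(meta, file.path(outdir, "metadata.csv"), row.names = FALSE)
    utils::write.csv(comparison, file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
    write_run_report(report, file.path(outdir, "report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  samples: %d, metabolites: %d\n",
              x$stages$input$n_samples, x$stages$input$n_metabolites))
  cat(sprintf("  targeted: %d retained, %d significant\n",
              x$stages$targeted$n_retained, x$stages$targeted$n_significant))
  if (!is.null(x$accuracy))
    cat(sprintf("  untargeted accuracy: %.1f%%\n", x$accuracy))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Serialize / load a run report (lossless JSON round trip)
#'
#' @param report a `run_report`.
#' @param path JSON path.
#' @export
write_run_report <- function(report, path) {
  out <- report
  if (!is.null(out$confusion))
    out$confusion <- list(matrix = unclass(out$confusion$matrix),
                          labels = rownames(out$confusion$matrix),
                          accuracy = out$confusion$accuracy,
                          per_run_accuracy = out$confusion$per_run_accuracy)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$confusion)) {
    m <- as.matrix(x$confusion$matrix)
    dimnames(m) <- list(true = x$confusion$labels,
                        predicted = x$confusion$labels)
    x$confusion <- structure(list(matrix = m, accuracy = x$confusion$accuracy,
                                  per_run_accuracy = x$confusion$per_run_accuracy),
                             class = "confusion_matrix")
  }
  class(x) <- "run_report"
  x
}
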