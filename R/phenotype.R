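#' Phenotype stratification configuration
#'
#' Genotype/phenotype-value (GPV) cut-offs for PKU severity: GPV 0-2.7 is
#' classical PKU (cPKU), GPV above 2.7 up to 7 is mild PKU/HPA (mPKU).
#' Where the GPV is unavailable, a serum phenylalanine above 1200 umol/L
#' defines classical PKU.
#'
#' @param cpku_gpv_max inclusive upper GPV bound for cPKU (default 2.7).
#' @param mpku_gpv_max inclusive upper GPV bound for mPKU (default 7).
#' @param classical_phe_threshold serum Phe (umol/L) above which a patient
#'   without GPV is classified cPKU (default 1200).
#' @return A `phenotype_config` object.
#' @export
phenotype_config <- function(cpku_gpv_max = 2.7, mpku_gpv_max = 7,
                             classical_phe_threshold = 1200) {
  check_number(cpku_gpv_max, "cpku_gpv_max", lower = 0, strict_lower = TRUE)
  if (mpku_gpv_max <= cpku_gpv_max)
    abort("mpku_gpv_max must exceed cpku_gpv_max", "invalid_parameter")
  check_number(classical_phe_threshold, "classical_phe_threshold", lower = 0)
  structure(list(cpku_gpv_max = cpku_gpv_max, mpku_gpv_max = mpku_gpv_max,
                 classical_phe_threshold = classical_phe_threshold),
            class = "phenotype_config")
}

#' Stratify a patient by GPV (with serum-Phe fallback)
#'
#' Deterministic and total: GPV in \[0, 2.7\] gives `cPKU`; GPV in
#' (2.7, 7\] gives `mPKU`; with GPV missing, serum Phe above 1200 umol/L
#' gives `cPKU`; anything else is `undetermined` (a candidate for
#' metabolome projection via [project()]).
#'
#' @param gpv genotype/phenotype value in \[0, 10\] or `NA`.
#' @param phe_serum serum phenylalanine, umol/L (used only when `gpv` is
#'   missing).
#' @param config a [phenotype_config].
#' @return one of `"cPKU"`, `"mPKU"`, `"undetermined"` (vectorized).
#' @export
stratify_gpv <- function(gpv, phe_serum = NA_real_,
                         config = phenotype_config()) {
  if (any(gpv < 0, na.rm = TRUE))
    abort("negative GPV", "invalid_parameter")
  n <- max(length(gpv), length(phe_serum))
  gpv <- rep_len(gpv, n); phe_serum <- rep_len(phe_serum, n)
  out <- rep("undetermined", n)
  out[!is.na(gpv) & gpv <= config$cpku_gpv_max] <- "cPKU"
  out[!is.na(gpv) & gpv > config$cpku_gpv_max &
        gpv <= config$mpku_gpv_max] <- "mPKU"
  out[is.na(gpv) & !is.na(phe_serum) &
        phe_serum > config$classical_phe_threshold] <- "cPKU"
  out
}

#' Per-phenotype summary of a numeric field
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of `field` within each
#' phenotype group. Groups of size 1 report the value as mean and `NA` SD
#' with a warning.
#'
#' @param records data.frame with a `phenotype` column (e.g.
#'   [reference_cohort()] or [generate_metadata()] output).
#' @param field name of the numeric column to summarize.
#' @return data.frame with `phenotype`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(records, field) {
  if (!field %in% names(records))
    abort(sprintf("no column '%s'", field), "invalid_parameter")
  groups <- split(records[[field]], records$phenotype)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]][!is.na(groups[[g]])]
    if (length(x) < 2L)
      warning(sprintf("phenotype group '%s' has <2 records; SD undefined", g))
    data.frame(phenotype = g, n = length(x), mean = mean(x),
               sd = if (length(x) >= 2L) stats::sd(x) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Bundled reference PKU cohort (n = 51)
#'
#' The packaged metadata fixture for 51 early-treated PKU patients: serum
#' phenylalanine (umol/L plasma), GPV, assigned phenotype, both PAH alleles
#' where detected, sapropterin treatment and natural protein intake
#' (g/kg bodyweight/day). Labels are preserved exactly as printed in the
#' source table, including one record (patient 176) whose recorded
#' phenotype contradicts its GPV; see [check_phenotype_consistency()].
#'
#' @return data.frame with 51 rows.
#' @export
reference_cohort <- function() {
  d <- utils::read.csv(pkg_file("reference_cohort.csv"),
                       check.names = FALSE,
                       colClasses = c(patient_id = "character"))
  d$sapropterin <- d$sapropterin == "yes"
  d
}

#' Flag recorded phenotypes that contradict the GPV rule
#'
#' Re-derives the phenotype of every record with [stratify_gpv()] and
#' reports disagreements with the recorded label. Labels are flagged, never
#' overwritten.
#'
#' @param records data.frame with `gpv`, `phe_serum` and `phenotype`.
#' @param config a [phenotype_config].
#' @return `records` with columns `phenotype_rule` (derived) and
#'   `phenotype_flag` (`TRUE` where recorded and derived disagree).
#' @export
check_phenotype_consistency <- function(records,
                                        config = phenotype_config()) {
  records$phenotype_rule <- stratify_gpv(records$gpv, records$phe_serum,
                                         config)
  records$phenotype_flag <- records$phenotype_rule != records$phenotype
  records
}
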