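#' Metabolite specification
#'
#' Describes one urinary metabolite for the cohort simulator: group moments
#' (arithmetic mean and SD, mmol/mol creatinine), a limit of detection, and
#' the resonance positions used when synthesizing spectra. A "null"
#' metabolite has identical case and control moments.
#'
#' @param name metabolite name.
#' @param mean_control,sd_control control-group arithmetic mean / SD
#'   (mmol/mol creatinine). Means must be positive, SDs non-negative.
#' @param mean_case,sd_case case-group moments; default to the control
#'   moments (a null metabolite).
#' @param lod limit of detection; simulated values below it are reported as
#'   missing.
#' @param peak_list data.frame with columns `ppm` and `rel_area`: resonance
#'   positions (0.6-9.4 ppm) and relative areas per unit concentration.
#' @return A `metabolite_spec` object.
#' @export
metabolite_spec <- function(name, mean_control, sd_control,
                            mean_case = mean_control, sd_case = sd_control,
                            lod = 0, peak_list = NULL) {
  check_number(mean_control, "mean_control", lower = 0, strict_lower = TRUE)
  check_number(mean_case, "mean_case", lower = 0, strict_lower = TRUE)
  check_number(sd_control, "sd_control", lower = 0)
  check_number(sd_case, "sd_case", lower = 0)
  check_number(lod, "lod", lower = 0)
  if (!is.null(peak_list)) {
    stopifnot(is.data.frame(peak_list), all(c("ppm", "rel_area") %in% names(peak_list)))
    if (nrow(peak_list) && (any(peak_list$ppm < 0.6) || any(peak_list$ppm > 9.4)))
      abort(sprintf("%s: peak shifts must lie in 0.6-9.4 ppm", name),
            "invalid_parameter")
  }
  structure(list(name = name,
                 mean_control = mean_control, sd_control = sd_control,
                 mean_case = mean_case, sd_case = sd_case,
                 lod = lod, peak_list = peak_list),
            class = "metabolite_spec")
}

is_null_metabolite <- function(spec) {
  spec$mean_case == spec$mean_control && spec$sd_case == spec$sd_control
}

panel_from_df <- function(df, peaks = NULL) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    pk <- if (!is.null(peaks)) peaks[peaks$name == r$name, c("ppm", "rel_area")]
    metabolite_spec(r$name, r$mean_control, r$sd_control,
                    r$mean_case, r$sd_case, lod = r$lod,
                    peak_list = pk)
  })
}

#' Bundled metabolite panel
#'
#' The default simulation panel: 24 metabolites whose group moments are
#' calibrated to the published PKU-versus-control concentration table
#' (mmol/mol creatinine), plus 74 null metabolites whose moments are drawn
#' once (fixed fixture) from the span of the calibrated control moments, for
#' 98 metabolites in total. Resonance positions come from a bundled,
#' editable shift library; no result depends on the specific shifts.
#'
#' @param include_null if `FALSE`, return only the 24 calibrated metabolites.
#' @return A list of [metabolite_spec] objects.
#' @export
default_panel <- function(include_null = TRUE) {
  peaks <- utils::read.csv(pkg_file("peak_library.csv"))
  cal <- utils::read.csv(pkg_file("calibrated_panel.csv"), check.names = FALSE)
  panel <- panel_from_df(cal, peaks)
  if (include_null) {
    null <- utils::read.csv(pkg_file("null_panel.csv"), check.names = FALSE)
    panel <- c(panel, panel_from_df(null, peaks))
  }
  panel
}

#' Intermediate ("mild-case-like") panel
#'
#' Derives a panel whose per-metabolite case means sit at the geometric
#' midpoint of the case and control means of `panel` (SDs likewise), which
#' emulates a biochemically intermediate phenotype for projection tests.
#'
#' @param panel a list of [metabolite_spec] objects.
#' @return A panel in which each case mean is `sqrt(mean_case * mean_control)`.
#' @export
midpoint_panel <- function(panel) {
  lapply(panel, function(sp) {
    sd_mid <- if (sp$sd_case > 0 && sp$sd_control > 0)
      sqrt(sp$sd_case * sp$sd_control) else (sp$sd_case + sp$sd_control) / 2
    metabolite_spec(sp$name, sp$mean_control, sp$sd_control,
                    mean_case = sqrt(sp$mean_case * sp$mean_control),
                    sd_case = sd_mid, lod = sp$lod, peak_list = sp$peak_list)
  })
}

pkg_file <- function(...) {
  f <- system.file("extdata", ..., package = "pkunmr")
  if (!nzchar(f)) abort(paste0("missing packaged file: ", ...), "format_error")
  f
}

#' Creatinine peak positions used by the simulator
#'
#' @return data.frame with the creatinine CH3 (reference) and CH2 singlets.
#' @export
creatinine_peaks <- function() {
  pk <- utils::read.csv(pkg_file("peak_library.csv"))
  pk[pk$name == "Creatinine", c("ppm", "rel_area")]
}
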