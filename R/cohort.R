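#' Cohort simulation configuration
#'
#' Stated-world defaults: 51 cases and 51 age-matched controls aged
#' 0.25-33 years; a 98-metabolite panel of which 24 carry the calibrated
#' case/control moment differences and 74 are null; serum phenylalanine
#' drawn per phenotype (classical PKU mean 777, SD 467 umol/L; mild PKU
#' mean 421, SD 255 umol/L) with a positive age trend; natural protein
#' intake lower in classical than in mild PKU.
#'
#' @param n_case,n_control group sizes (each >= 2).
#' @param panel list of [metabolite_spec]; defaults to [default_panel()].
#' @param seed integer master seed; a fixed seed gives bit-identical output.
#' @param age_range numeric length-2, years.
#' @param phe_distributions named list of `c(mean, sd)` serum Phe (umol/L)
#'   per phenotype stratum.
#' @param case_mix expected phenotype composition of the case group
#'   (proportions, normalized internally).
#' @param phe_age_cor correlation between age and serum Phe within each
#'   case stratum (drives the increasing-with-age trend).
#' @param protein_distributions named list of `c(mean, sd)` natural protein
#'   intake (g/kg bodyweight/day) per stratum.
#' @param noise_sd Gaussian baseline noise level of synthetic spectra
#'   (intensity units; creatinine reference height is ~1.6e5).
#' @return A `cohort_config` object (validated list).
#' @export
cohort_config <- function(n_case = 51L, n_control = 51L,
                          panel = default_panel(), seed = 1L,
                          age_range = c(0.25, 33),
                          phe_distributions = list(
                            cPKU = c(mean = 777, sd = 467),
                            mPKU = c(mean = 421, sd = 255),
                            undetermined = c(mean = 1100, sd = 450),
                            control = c(mean = 55, sd = 15)),
                          case_mix = c(cPKU = 36, mPKU = 12,
                                       undetermined = 3),
                          phe_age_cor = 0.35,
                          protein_distributions = list(
                            cPKU = c(mean = 0.40, sd = 0.30),
                            mPKU = c(mean = 1.10, sd = 0.75),
                            undetermined = c(mean = 0.60, sd = 0.40),
                            control = c(mean = 1.20, sd = 0.35)),
                          noise_sd = 2) {
  check_count(n_case, "n_case", lower = 2L)
  check_count(n_control, "n_control", lower = 2L)
  if (!is.list(panel) || length(panel) == 0L)
    abort("`panel` must be a non-empty list of metabolite_spec", "invalid_parameter")
  stopifnot(all(vapply(panel, inherits, TRUE, "metabolite_spec")))
  check_number(age_range[1], "age_range[1]", lower = 0)
  if (age_range[2] <= age_range[1])
    abort("`age_range` must be increasing", "invalid_parameter")
  check_number(phe_age_cor, "phe_age_cor", lower = -1, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 panel = panel, seed = as.integer(seed), age_range = age_range,
                 phe_distributions = phe_distributions,
                 case_mix = case_mix / sum(case_mix),
                 phe_age_cor = phe_age_cor,
                 protein_distributions = protein_distributions,
                 noise_sd = noise_sd),
            class = "cohort_config")
}

#' Moment-matched lognormal parameters
#'
#' Urinary concentrations are positive and right-skewed (several calibrated
#' metabolites have SD > mean), so group distributions are modelled as
#' lognormal with the stated arithmetic mean and SD:
#' `log_sd^2 = log(1 + sd^2/mean^2)`, `log_mean = log(mean) - log_sd^2/2`.
#'
#' @param mean arithmetic mean (> 0).
#' @param sd arithmetic standard deviation (>= 0); `sd = 0` gives a point
#'   mass at `mean`.
#' @return `c(log_mean, log_sd)` such that `rlnorm(n, log_mean, log_sd)` has
#'   the requested arithmetic moments.
#' @export
lognormal_params_from_moments <- function(mean, sd) {
  check_number(mean, "mean", lower = 0, strict_lower = TRUE)
  check_number(sd, "sd", lower = 0)
  s2 <- log(1 + (sd / mean)^2)
  c(log_mean = log(mean) - s2 / 2, log_sd = sqrt(s2))
}

draw_group <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p <- lognormal_params_from_moments(mean, sd)
  stats::rlnorm(n, p[1], p[2])
}

#' Simulate a case/control concentration table
#'
#' Draws one row per sample and one column per panel metabolite from the
#' per-group moment-matched lognormals (independent across metabolites);
#' values below a metabolite's limit of detection are reported as missing.
#'
#' @param config a [cohort_config].
#' @return list with `table` (data.frame: `sample_id`, `group`, then one
#'   numeric column per metabolite, mmol/mol creatinine) and `labels`
#'   (factor `case`/`control` per row).
#' @export
generate_concentrations <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seeds(config$seed, 1L))
  n <- config$n_case + config$n_control
  labels <- factor(rep(c("case", "control"),
                       c(config$n_case, config$n_control)),
                   levels = c("case", "control"))
  cols <- lapply(config$panel, function(sp) {
    x <- numeric(n)
    x[labels == "case"] <- draw_group(config$n_case, sp$mean_case, sp$sd_case)
    x[labels == "control"] <- draw_group(config$n_control,
                                         sp$mean_control, sp$sd_control)
    x[x < sp$lod] <- NA_real_
    x
  })
  names(cols) <- vapply(config$panel, `[[`, "", "name")
  tab <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    group = as.character(labels), cols,
                    check.names = FALSE)
  list(table = tab, labels = labels)
}

#' Simulate patient/control metadata
#'
#' Ages are uniform over the configured range. Serum Phe is drawn per
#' phenotype stratum with correlation `phe_age_cor` to age within case
#' strata (the clinically observed drift toward dietary non-compliance with
#' age); draws are floored at 1 umol/L. Natural protein intake is drawn
#' lognormally per stratum, with the classical-PKU mean below the mild-PKU
#' mean. An `allantoin_response` column is generated as a unit-variance
#' linear response with standardized coefficients -0.5 on age, +0.4 on
#' protein intake and 0 on serum Phe, so multifactorial regression recovery
#' is testable against planted truth.
#'
#' @param config a [cohort_config].
#' @return data.frame of patient records (one row per sample, cases first,
#'   same order as [generate_concentrations()]).
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seeds(config$seed, 2L))
  n <- config$n_case + config$n_control
  mix <- config$case_mix
  n_strata <- floor(mix * config$n_case)
  rem <- config$n_case - sum(n_strata)
  if (rem > 0) { # largest-remainder rounding
    frac <- mix * config$n_case - n_strata
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_strata[add] <- n_strata[add] + 1L
  }
  phenotype <- c(rep(names(mix), n_strata), rep("control", config$n_control))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  age_sd <- sqrt(diff(config$age_range)^2 / 12)
  phe <- numeric(n); gpv <- rep(NA_real_, n); protein <- numeric(n)
  sapro <- rep(FALSE, n)
  r <- config$phe_age_cor
  for (ph in unique(phenotype)) {
    i <- which(phenotype == ph)
    pd <- config$phe_distributions[[ph]]
    rr <- if (ph == "control") 0 else r
    mu <- pd["mean"] + rr * pd["sd"] / age_sd * (age[i] - mean(config$age_range))
    phe[i] <- pmax(stats::rnorm(length(i), mu, pd["sd"] * sqrt(1 - rr^2)), 1)
    id <- config$protein_distributions[[ph]]
    protein[i] <- draw_group(length(i), id["mean"], id["sd"])
    gpv[i] <- switch(ph,
      cPKU = ifelse(stats::runif(length(i)) < 0.7, 0,
                    stats::runif(length(i), 0, 2.7)),
      mPKU = stats::runif(length(i), 2.8, 6.9),
      undetermined = NA_real_,
      control = NA_real_)
    sapro[i] <- switch(ph,
      cPKU = stats::runif(length(i)) < 0.08,
      mPKU = stats::runif(length(i)) < 0.5,
      rep(FALSE, length(i)))
  }
  zc <- function(x) (x - mean(x)) / stats::sd(x)
  resp <- -0.5 * zc(age) + 0.4 * zc(protein) + 0 * zc(phe) +
    stats::rnorm(n, 0, sqrt(1 - (0.25 + 0.16)))
  data.frame(patient_id = sprintf("S%03d", seq_len(n)),
             group = group, phenotype = phenotype,
             age = age, sex = sample(c("F", "M"), n, replace = TRUE),
             phe_serum = phe, gpv = gpv, sapropterin = sapro,
             protein_intake = protein, allantoin_response = resp,
             stringsAsFactors = FALSE)
}

#' Synthesize a 1D urine NMR spectrum from metabolite concentrations
#'
#' Builds an intensity trace on a fixed ascending ppm grid as a sum of
#' Lorentzian lines: each metabolite contributes, at every entry of its peak
#' list, a line with area `concentration * rel_area`. A creatinine doublet of
#' singlets (CH3 at 3.05 ppm - the scaling reference - and CH2 at 4.06 ppm)
#' is always present with area proportional to `creatinine` (1000 mmol/mol
#' by definition of the creatinine-relative unit). A smooth, compactly
#' supported artifact inside the 4.5-6.0 ppm residual-water window is added
#' so water exclusion is exercisable. Missing concentrations contribute
#' nothing.
#'
#' @param concentrations named numeric vector, mmol/mol creatinine; names
#'   must match panel metabolite names. Negative values are an error.
#' @param panel list of [metabolite_spec] with non-empty peak lists.
#' @param noise_sd SD of additive Gaussian baseline noise (0 = noiseless).
#' @param seed optional seed for the noise draw.
#' @param creatinine creatinine reference area scale (default 1000).
#' @param n_points grid size (>= 2^14), `ppm_range` grid span.
#' @param ppm_range numeric length-2 ppm span of the grid.
#' @param linewidth Lorentzian half-width at half-maximum, ppm.
#' @param water_artifact logical; include the residual-water bump.
#' @return An [nmr_spectrum].
#' @export
synthesize_spectrum <- function(concentrations, panel, noise_sd = 0,
                                seed = NULL, creatinine = 1000,
                                n_points = 2^15, ppm_range = c(0.5, 9.5),
                                linewidth = 0.002, water_artifact = TRUE) {
  if (any(concentrations < 0, na.rm = TRUE))
    abort("concentrations must be non-negative", "invalid_parameter")
  check_number(noise_sd, "noise_sd", lower = 0)
  if (n_points < 2^14) abort("n_points must be >= 2^14", "invalid_parameter")
  ppm <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  y <- numeric(n_points)
  gam <- linewidth
  add_lorentz <- function(x0, area) {
    if (area == 0) return()
    y <<- y + area * (gam / pi) / ((ppm - x0)^2 + gam^2)
  }
  for (sp in panel) {
    conc <- concentrations[[sp$name]]
    if (is.null(conc) || is.na(conc) || conc == 0) next
    if (is.null(sp$peak_list) || nrow(sp$peak_list) == 0L)
      abort(sprintf("%s: empty peak list", sp$name), "invalid_parameter")
    for (j in seq_len(nrow(sp$peak_list)))
      add_lorentz(sp$peak_list$ppm[j], conc * sp$peak_list$rel_area[j])
  }
  crp <- creatinine_peaks()
  for (j in seq_len(nrow(crp)))
    add_lorentz(crp$ppm[j], creatinine * crp$rel_area[j])
  if (water_artifact) {
    # raised-cosine bump, support [4.55, 5.25] strictly inside (4.5, 6.0)
    ctr <- 4.9; hw <- 0.35
    in_w <- abs(ppm - ctr) < hw
    y[in_w] <- y[in_w] + 500 * cos(pi * (ppm[in_w] - ctr) / (2 * hw))^2
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(n_points, 0, noise_sd)
  }
  nmr_spectrum(ppm, y, meta = list(creatinine = creatinine,
                                   linewidth = linewidth,
                                   noise_sd = noise_sd))
}

#' Simulate a full cohort: concentrations, metadata and (optionally) spectra
#'
#' @param config a [cohort_config].
#' @param spectra logical; also synthesize one spectrum per sample.
#' @return list with `table`, `labels`, `metadata` and (if requested)
#'   `spectra` (list of [nmr_spectrum], same order as rows).
#' @export
simulate_cohort <- function(config = cohort_config(), spectra = FALSE) {
  conc <- generate_concentrations(config)
  meta <- generate_metadata(config)
  out <- list(table = conc$table, labels = conc$labels, metadata = meta,
              config = config)
  if (spectra) {
    mets <- vapply(config$panel, `[[`, "", "name")
    seeds <- derive_seeds(config$seed, nrow(conc$table) + 2L)[-(1:2)]
    out$spectra <- lapply(seq_len(nrow(conc$table)), function(i) {
      row <- unlist(conc$table[i, mets, drop = TRUE])
      synthesize_spectrum(row, config$panel, noise_sd = config$noise_sd,
                          seed = seeds[i])
    })
  }
  out
}
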