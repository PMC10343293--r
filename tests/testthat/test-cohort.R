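test_that("lognormal moment matching is exact and validated", {
  p <- lognormal_params_from_moments(10.8, 10.2)
  expect_equal(unname(p), c(2.0606, 0.7986), tolerance = 1e-4)
  # back-substitute: arithmetic moments of the lognormal equal the inputs
  m <- exp(p[1] + p[2]^2 / 2)
  s2 <- exp(2 * p[1] + p[2]^2) * (exp(p[2]^2) - 1)
  expect_equal(unname(m), 10.8, tolerance = 1e-12)
  expect_equal(unname(sqrt(s2)), 10.2, tolerance = 1e-12)

  expect_equal(unname(lognormal_params_from_moments(5, 0)), c(log(5), 0))
  expect_error(lognormal_params_from_moments(0, 1), class = "invalid_parameter")
  expect_error(lognormal_params_from_moments(-2, 1), class = "invalid_parameter")

  set.seed(1) # Monte-Carlo oracle at 1e6 draws
  x <- rlnorm(1e6, p[1], p[2])
  expect_lt(abs(mean(x) - 10.8) / 10.8, 0.01)
  expect_lt(abs(sd(x) - 10.2) / 10.2, 0.01)
})

test_that("generate_concentrations hits group moments and respects LOD", {
  panel <- toy_panel("Glycine", 117.8, 124.1, 282.6, 342.2)
  cfg <- cohort_config(n_case = 20000, n_control = 20000, panel = panel,
                       seed = 3)
  g <- generate_concentrations(cfg)
  expect_equal(nrow(g$table), 40000)
  ctrl <- g$table$Glycine[g$labels == "control"]
  case <- g$table$Glycine[g$labels == "case"]
  # law-of-large-numbers check at 4 standard errors of the target moments
  expect_lt(abs(mean(ctrl) - 117.8), 4 * 124.1 / sqrt(20000))
  expect_lt(abs(mean(case) - 282.6), 4 * 342.2 / sqrt(20000))

  # zero SD: every value is its group mean
  cfg0 <- cohort_config(panel = toy_panel(sd_c = 0, sd_x = 0, mean_x = 50),
                        seed = 1)
  g0 <- generate_concentrations(cfg0)
  expect_true(all(g0$table$Glycine[g0$labels == "case"] == 50))
  expect_true(all(g0$table$Glycine[g0$labels == "control"] == 100))

  # below-LOD values are reported missing, never emitted
  cfgl <- cohort_config(panel = toy_panel(mean_c = 5, sd_c = 5, mean_x = 5,
                                          sd_x = 5, lod = 3), seed = 2)
  gl <- generate_concentrations(cfgl)
  v <- gl$table$Glycine
  expect_true(anyNA(v))
  expect_true(all(v[!is.na(v)] >= 3))

  expect_error(cohort_config(panel = list()), class = "invalid_parameter")
})

test_that("generator output is bit-identical under a fixed seed", {
  cfg <- cohort_config(n_case = 10, n_control = 10,
                       panel = default_panel(include_null = FALSE), seed = 99)
  expect_identical(generate_concentrations(cfg), generate_concentrations(cfg))
  expect_identical(generate_metadata(cfg), generate_metadata(cfg))
  r <- unlist(generate_concentrations(cfg)$table[1, -(1:2)])
  expect_identical(synthesize_spectrum(r, cfg$panel, noise_sd = 1, seed = 5),
                   synthesize_spectrum(r, cfg$panel, noise_sd = 1, seed = 5))
})

test_that("null metabolite has nominal Mann-Whitney rejection rate", {
  panel <- toy_panel("Null", 20, 15, 20, 15)
  rej <- vapply(1:400, function(i) {
    g <- generate_concentrations(cohort_config(panel = panel, seed = i))
    mann_whitney_u(g$table$Null[g$labels == "case"],
                   g$table$Null[g$labels == "control"])$p_value < 0.05
  }, logical(1))
  # binomial 99% band around 0.05 at 400 replicates
  expect_gt(mean(rej), 0.05 - 2.576 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(rej), 0.05 + 2.576 * sqrt(0.05 * 0.95 / 400))
})

test_that("generate_metadata reproduces the configured clinical structure", {
  cfg <- cohort_config(n_case = 5000, n_control = 2, seed = 8)
  m <- generate_metadata(cfg)
  cp <- m[m$phenotype == "cPKU", ]
  expect_lt(abs(mean(cp$phe_serum) - 777) / 777, 0.05)
  mp <- m[m$phenotype == "mPKU", ]
  expect_lt(abs(mean(mp$phe_serum) - 421) / 421, 0.05)
  # positive age trend in serum Phe within cases
  fit <- summary(lm(phe_serum ~ age, data = m[m$group == "case", ]))
  expect_gt(coef(fit)["age", "Estimate"], 0)
  expect_lt(coef(fit)["age", "Pr(>|t|)"], 0.01)
  # protein intake lower in classical than mild PKU
  expect_lt(mean(cp$protein_intake), mean(mp$protein_intake))
  expect_true(all(m$age >= 0.25 & m$age <= 33))
  expect_false(anyNA(m[, c("patient_id", "phenotype", "age", "phe_serum",
                           "protein_intake")]))

  m2 <- generate_metadata(cohort_config(n_case = 2, n_control = 2, seed = 1))
  expect_equal(nrow(m2), 4)
  expect_false(anyNA(m2$phe_serum))
})

test_that("synthesized spectra integrate to peak areas and are linear", {
  panel <- toy_panel(rel_area = 0.8)
  s <- synthesize_spectrum(c(Glycine = 50), panel, noise_sd = 0,
                           creatinine = 0, water_artifact = FALSE)
  a <- spectrum_integral(s, 0.5, 9.5)
  expect_lt(abs(a - 50 * 0.8) / (50 * 0.8), 0.005)  # quadrature oracle

  # zero concentrations: flat outside creatinine + water artifact
  s0 <- synthesize_spectrum(c(Glycine = 0), panel, noise_sd = 0)
  outside <- s0$ppm < 2.9 | (s0$ppm > 3.3 & s0$ppm < 3.9) | s0$ppm > 6.2
  expect_lt(max(abs(s0$intensity[outside])),
            1e-3 * max(s0$intensity))
  expect_gt(spectrum_integral(s0, 3.0, 3.1), 0)     # creatinine reference
  expect_gt(spectrum_integral(s0, 4.6, 5.2), 0)     # water artifact

  # doubling concentrations (incl. creatinine) doubles every bin outside
  # the water region, before creatinine scaling
  r1 <- unlist(generate_concentrations(
    cohort_config(panel = default_panel(FALSE), seed = 4))$table[1, -(1:2)])
  s1 <- synthesize_spectrum(r1, default_panel(FALSE), creatinine = 1000)
  s2 <- synthesize_spectrum(2 * r1, default_panel(FALSE), creatinine = 2000)
  b1 <- bin_spectrum(s1)
  b2 <- bin_spectrum(s2)
  expect_equal(as.numeric(b2), as.numeric(2 * b1), tolerance = 1e-9)

  expect_error(synthesize_spectrum(c(Glycine = -1), panel),
               class = "invalid_parameter")
  empty <- metabolite_spec("Glycine", 1, 0, peak_list =
                             data.frame(ppm = numeric(0),
                                        rel_area = numeric(0)))
  expect_error(synthesize_spectrum(c(Glycine = 1), list(empty)),
               class = "invalid_parameter")
})
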