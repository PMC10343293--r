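test_that("lod_filter applies the strict >min_values rule", {
  mk <- function(n_present, n_total = 102) c(rep(1, n_present),
                                             rep(NA, n_total - n_present))
  tab <- data.frame(sample_id = sprintf("S%03d", 1:102),
                    group = rep(c("case", "control"), 51),
                    ten = mk(10), eleven = mk(11), none = mk(0),
                    check.names = FALSE)
  expect_equal(lod_filter(tab), "eleven")
  expect_equal(lod_filter(tab, stats_config(min_values = 0)),
               c("ten", "eleven"))
  expect_error(lod_filter(tab[, 1:2]), class = "invalid_parameter")
})

test_that("a 149-metabolite table with LODs set so 98 pass retains 98", {
  # 98 metabolites fully quantified, 51 reported in <= 10 samples
  set.seed(12)
  cols <- c(lapply(1:98, function(i) rlnorm(102)),
            lapply(1:51, function(i) c(rlnorm(sample(0:10, 1)),
                                       rep(NA, 102))[1:102]))
  names(cols) <- sprintf("m%03d", 1:149)
  tab <- data.frame(sample_id = sprintf("S%03d", 1:102),
                    group = rep(c("case", "control"), 51), cols)
  expect_length(lod_filter(tab), 98)
})

test_that("mann_whitney_u agrees with exact enumeration for small samples", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4)),
               list(u = 0, p_value = 1 / 3))
  x <- c(5, 5, 7); expect_equal(mann_whitney_u(x, x)$p_value, 1)

  set.seed(13)
  for (i in 1:25) {  # all sizes up to 8, with ties
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    got <- mann_whitney_u(x, y)
    expect_equal(got$u, oracle_u(x, y))
    expect_equal(got$p_value, oracle_exact_p(x, y), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(), 1:3), class = "invalid_parameter")
})

test_that("large-sample p-values match the tie-corrected normal oracle", {
  set.seed(14)
  for (i in 1:50) {
    x <- sample(1:12, 20, replace = TRUE)
    y <- sample(1:15, 30, replace = TRUE)
    got <- mann_whitney_u(x, y)$p_value
    want <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_equal(got, want, tolerance = 1e-10)
  }
  # identical constant samples: documented p = 1 convention
  expect_equal(mann_whitney_u(rep(2, 20), rep(2, 30))$p_value, 1)
})

test_that("fold_change reproduces printed ratios and rejects zero control", {
  expect_equal(round(fold_change(38.8, 27.8), 3), 1.396)
  expect_equal(round(fold_change(74.1, 93.1), 3), 0.796)
  expect_equal(fold_change(5, 5), 1)
  expect_error(fold_change(1, 0), class = "undefined_ratio")
})

test_that("compare_groups screens, ranks and is label/order invariant", {
  set.seed(15)
  n <- 51
  tab <- data.frame(
    sample_id = sprintf("S%03d", 1:(2 * n)),
    group = rep(c("case", "control"), each = n),
    shifted = c(rlnorm(n, 3, 0.3), rlnorm(n, 1, 0.3)),
    null1 = rlnorm(2 * n, 2, 0.5), null2 = rlnorm(2 * n, 0, 0.5),
    check.names = FALSE)
  res <- compare_groups(tab)
  expect_equal(res$metabolite[1], "shifted")
  expect_true(all(diff(res$fold_change) <= 0))
  expect_true(all(res$p_value < 0.05))
  expect_equal(res$n_case[1], n)

  # identical groups: empty result
  tab0 <- tab; tab0$shifted <- rep(rlnorm(n), 2)
  tab0$null1 <- rep(tab0$null1[1:n], 2); tab0$null2 <- rep(tab0$null2[1:n], 2)
  expect_equal(nrow(compare_groups(tab0)), 0)

  # row order invariance
  perm <- sample(nrow(tab))
  res2 <- compare_groups(tab[perm, ])
  expect_equal(res2, res)

  # swapping group labels inverts fold changes, keeps p-values
  swapped <- tab
  swapped$group <- ifelse(tab$group == "case", "control", "case")
  res3 <- compare_groups(swapped)
  i <- match(res$metabolite, res3$metabolite)
  expect_equal(res3$fold_change[i], 1 / res$fold_change)
  expect_equal(res3$p_value[i], res$p_value)

  expect_error(compare_groups(tab[tab$group == "case", ]),
               class = "invalid_parameter")
})

test_that("the strongest planted analytes dominate the screen ranking", {
  top <- vapply(1:40, function(i) {
    r <- compare_groups(generate_concentrations(cohort_config(seed = i))$table)
    r$metabolite[1]
  }, "")
  # the two largest planted fold changes (6.85 and 4.76) trade first place
  # depending on the draw; phenylpyruvate wins the majority
  expect_true(all(top %in% c("Phenylpyruvic acid", "D-Mandelic acid")))
  expect_gt(mean(top == "Phenylpyruvic acid"), 0.5)
})

test_that("adding a constant to case values never lowers the fold change", {
  set.seed(16)
  x <- rlnorm(30, 2, 0.6); y <- rlnorm(30, 2, 0.6)
  f0 <- fold_change(mean(x), mean(y))
  for (d in c(0.1, 1, 10))
    expect_gte(fold_change(mean(x + d), mean(y)), f0)
})

test_that("standardized_regression returns standardized betas", {
  set.seed(17)
  x1 <- rnorm(100); x2 <- rnorm(100)
  # perfect fit: summary.lm warns about unreliable p-values, betas are exact
  r <- suppressWarnings(
    standardized_regression(x1, data.frame(x1 = x1, x2 = x2)))
  expect_equal(r$beta[r$term == "x1"], 1, tolerance = 1e-8)
  expect_equal(r$beta[r$term == "x2"], 0, tolerance = 1e-8)

  # consistency: independent predictor has near-zero beta
  y <- rnorm(10000)
  rz <- standardized_regression(y, data.frame(z = rnorm(10000)))
  expect_lt(abs(rz$beta), 0.05)

  expect_error(
    standardized_regression(x1, data.frame(a = x2, b = 2 * x2)),
    class = "rank_deficiency")
  expect_error(
    standardized_regression(x1, data.frame(a = x2, b = 2 * x2)),
    regexp = "b")
  expect_error(standardized_regression(1:3, data.frame(a = 1:3, b = 3:1)),
               class = "invalid_parameter")
})

test_that("planted covariate structure is recovered from metadata", {
  set.seed(18)
  est <- replicate(40, {
    cc <- cohort_config(n_case = 250, n_control = 250,
                        panel = default_panel(include_null = FALSE),
                        seed = sample.int(1e6, 1))
    m <- generate_metadata(cc)
    standardized_regression(
      m$allantoin_response,
      m[, c("age", "protein_intake", "phe_serum")])$beta
  })
  expect_equal(rowMeans(est), c(-0.5, 0.4, 0), tolerance = 0.05)
})
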