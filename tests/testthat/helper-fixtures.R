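# Shared builders for small deterministic fixtures.

# single-peak metabolite panel
toy_panel <- function(name = "Glycine", mean_c = 100, sd_c = 10,
                      mean_x = mean_c, sd_x = sd_c, lod = 0,
                      ppm = 3.56, rel_area = 1) {
  list(metabolite_spec(name, mean_c, sd_c, mean_x, sd_x, lod = lod,
                       peak_list = data.frame(ppm = ppm, rel_area = rel_area)))
}

# constant-intensity spectrum covering the default binning region
flat_spectrum <- function(value = 1, n = 2^14) {
  nmr_spectrum(seq(0.5, 9.5, length.out = n), rep(value, n))
}

# two Gaussian clouds in `p` dimensions separated along the first axis
gaussian_clouds <- function(n_per = 40, p = 2, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             cbind(rnorm(n_per, sep), matrix(rnorm(n_per * (p - 1)), n_per)))
  list(X = X, labels = factor(rep(c("a", "b"), each = n_per)))
}

# brute-force U statistic by pair counting (independent of midrank formula)
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided permutation p-value for the U statistic
oracle_exact_p <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  mu <- n1 * length(y) / 2
  us <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(oracle_u(x, y) - mu) - 1e-9)
}

# the default end-to-end synthetic cohort, binned; computed once per session
cached_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(seed = 1)
      sim <- simulate_cohort(cfg, spectra = TRUE)
      bt <- assemble_bucket_table(sim$spectra, sample_ids = sim$table$sample_id)
      cache <<- list(config = cfg, sim = sim, buckets = bt,
                     model_rows = sim$metadata$phenotype %in% c("cPKU", "control"))
    }
    cache
  }
})
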