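#' Targeted-screen configuration
#'
#' @param min_values sufficiency threshold: a metabolite is analysed only if
#'   its total number of quantified (above-LOD) values across both groups is
#'   strictly greater than this (default 10).
#' @param alpha significance level for the group comparison (default 0.05).
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()];
#'   `"none"` by default (matching the published screen), `"BH"` available.
#' @return A `stats_config` object.
#' @export
stats_config <- function(min_values = 10L, alpha = 0.05, p_adjust = "none") {
  check_count(min_values, "min_values", lower = 0L)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) abort("`alpha` must be < 1", "invalid_parameter")
  structure(list(min_values = as.integer(min_values), alpha = alpha,
                 p_adjust = p_adjust),
            class = "stats_config")
}

metabolite_columns <- function(table) {
  setdiff(names(table), c("sample_id", "group"))
}

#' Limit-of-detection sufficiency filter
#'
#' Retains metabolites with strictly more than `min_values` quantified
#' values in total across both groups; below-LOD entries are missing and do
#' not count.
#'
#' @param table concentration data.frame (`sample_id`, `group`, metabolite
#'   columns) as from [generate_concentrations()] or
#'   [read_concentration_table()].
#' @param config a [stats_config].
#' @return character vector of retained metabolite names.
#' @export
lod_filter <- function(table, config = stats_config()) {
  mets <- metabolite_columns(table)
  if (!length(mets)) abort("table has no metabolite columns", "invalid_parameter")
  counts <- vapply(mets, function(m) sum(!is.na(table[[m]])), integer(1))
  mets[counts > config$min_values]
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midranks. For small samples (both n <= 8) the
#' two-sided p-value is exact, by enumeration of all assignments of the
#' pooled values to the two groups (ties handled naturally); otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used. Two identical constant samples give p = 1 by
#' convention.
#'
#' @param x,y numeric samples (each non-empty; NAs dropped).
#' @return list with `u` (U statistic of `x`) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) abort("both samples must be non-empty", "invalid_parameter")
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= 8L && n2 <= 8L) {
    # exact permutation null of U given the observed pooled values
    idx <- utils::combn(n1 + n2, n1)
    u_perm <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_perm - mu) >= abs(u - mu) - 1e-9)
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    s2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- max(abs(u - mu) - 0.5, 0) / sqrt(s2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  list(u = u, p_value = p)
}

#' Fold change (case over control)
#'
#' @param mean_case,mean_control group arithmetic means; the control mean
#'   must be positive.
#' @return `mean_case / mean_control`.
#' @export
fold_change <- function(mean_case, mean_control) {
  if (!is.finite(mean_control) || mean_control <= 0)
    abort("control mean must be positive for a fold change", "undefined_ratio")
  mean_case / mean_control
}

#' Targeted group comparison with fold-change ranking
#'
#' For every metabolite that passes [lod_filter()], computes per-group n,
#' arithmetic mean and sample SD on the quantified values, the two-sided
#' Mann-Whitney p-value, and the case/control fold change; keeps metabolites
#' with p below `alpha` and ranks them by decreasing fold change.
#'
#' @param table concentration data.frame (see [lod_filter()]).
#' @param labels optional case/control factor; defaults to the table's
#'   `group` column.
#' @param config a [stats_config].
#' @param case,control the two label values.
#' @return data.frame with columns `metabolite`, `n_control`, `mean_control`,
#'   `sd_control`, `n_case`, `mean_case`, `sd_case`, `u_statistic`,
#'   `p_value`, `fold_change`, sorted by decreasing fold change.
#' @export
compare_groups <- function(table, labels = NULL, config = stats_config(),
                           case = "case", control = "control") {
  labels <- labels %||% table$group
  if (is.null(labels)) abort("no group labels supplied", "invalid_parameter")
  labels <- as.character(labels)
  if (!any(labels == case) || !any(labels == control))
    abort(sprintf("both groups ('%s', '%s') must be present", case, control),
          "invalid_parameter")
  mets <- lod_filter(table, config)
  rows <- lapply(mets, function(m) {
    xs <- table[[m]][labels == case]; xs <- xs[!is.na(xs)]
    ys <- table[[m]][labels == control]; ys <- ys[!is.na(ys)]
    if (!length(xs) || !length(ys)) return(NULL)
    mw <- mann_whitney_u(xs, ys)
    data.frame(metabolite = m,
               n_control = length(ys), mean_control = mean(ys),
               sd_control = stats::sd(ys),
               n_case = length(xs), mean_case = mean(xs),
               sd_case = stats::sd(xs),
               u_statistic = mw$u, p_value = mw$p_value,
               fold_change = fold_change(mean(xs), mean(ys)))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty_comparison())
  res$p_value <- stats::p.adjust(res$p_value, method = config$p_adjust)
  res <- res[res$p_value < config$alpha, , drop = FALSE]
  res <- res[order(-res$fold_change), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_comparison <- function() {
  data.frame(metabolite = character(), n_control = integer(),
             mean_control = numeric(), sd_control = numeric(),
             n_case = integer(), mean_case = numeric(), sd_case = numeric(),
             u_statistic = numeric(), p_value = numeric(),
             fold_change = numeric())
}

#' Standardized multifactorial regression
#'
#' Ordinary least squares of the z-scored response on z-scored predictors;
#' the coefficients are standardized betas with t-test p-values. Rows with
#' any missing value are dropped; rank-deficient designs are an error that
#' names the collinear columns.
#'
#' @param response numeric vector.
#' @param predictors data.frame (or named matrix) of numeric predictors.
#' @return data.frame with `term`, `beta`, `se`, `p_value`.
#' @export
standardized_regression <- function(response, predictors) {
  predictors <- as.data.frame(predictors)
  if (!nrow(predictors) || nrow(predictors) != length(response))
    abort("response and predictors must have matching rows",
          "invalid_parameter")
  keep <- stats::complete.cases(predictors) & !is.na(response)
  if (sum(keep) < ncol(predictors) + 2L)
    abort("need at least p + 2 complete cases", "invalid_parameter")
  y <- drop(scale(response[keep]))
  Xz <- scale(as.matrix(predictors[keep, , drop = FALSE]))
  if (any(!is.finite(Xz)))
    abort("constant predictor cannot be standardized", "invalid_parameter")
  q <- qr(Xz)
  if (q$rank < ncol(Xz)) {
    bad <- colnames(Xz)[q$pivot[(q$rank + 1L):ncol(Xz)]]
    abort(sprintf("collinear predictors: %s", paste(bad, collapse = ", ")),
          "rank_deficiency")
  }
  fit <- stats::lm(y ~ Xz)
  co <- summary(fit)$coefficients[-1L, , drop = FALSE]
  data.frame(term = colnames(Xz), beta = co[, "Estimate"],
             se = co[, "Std. Error"], p_value = co[, "Pr(>|t|)"],
             row.names = NULL)
}
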