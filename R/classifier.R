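#' Classifier configuration
#'
#' Defaults follow the published untargeted workflow: PCA retaining 99%
#' explained variance, 16 Monte-Carlo runs of stratified 8-fold
#' cross-validation; k = 3 nearest neighbours (k is not fixed by the
#' workflow description; an odd default avoids most voting ties).
#'
#' @param explained_variance_threshold cumulative explained-variance
#'   fraction retained by PCA (0 < t <= 1).
#' @param mc_runs number of Monte-Carlo shuffles (>= 1).
#' @param cv_folds folds per shuffle (>= 2).
#' @param k_neighbors neighbours for k-NN voting.
#' @param manova_alpha significance level for the Wilks' lambda dimension
#'   test.
#' @param seed integer seed driving the Monte-Carlo shuffles.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(explained_variance_threshold = 0.99,
                              mc_runs = 16L, cv_folds = 8L,
                              k_neighbors = 3L, manova_alpha = 0.05,
                              seed = 1L) {
  check_number(explained_variance_threshold, "explained_variance_threshold",
               lower = 0, upper = 1, strict_lower = TRUE)
  check_count(mc_runs, "mc_runs", lower = 1L)
  check_count(cv_folds, "cv_folds", lower = 2L)
  check_count(k_neighbors, "k_neighbors", lower = 1L)
  check_number(manova_alpha, "manova_alpha", lower = 0, upper = 1,
               strict_lower = TRUE)
  structure(list(explained_variance_threshold = explained_variance_threshold,
                 mc_runs = as.integer(mc_runs), cv_folds = as.integer(cv_folds),
                 k_neighbors = as.integer(k_neighbors),
                 manova_alpha = manova_alpha, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Fit a PCA dimension reduction
#'
#' Column-mean centering followed by an SVD of the centered matrix; the
#' principal axes are the eigenvectors of the sample covariance ordered by
#' decreasing eigenvalue, and the minimal number of leading components whose
#' cumulative explained variance reaches `threshold` is retained.
#'
#' @param X numeric sample x feature matrix (>= 2 rows, finite).
#' @param threshold cumulative explained-variance fraction (default 0.99).
#' @return list with `center`, `loadings` (feature x retained, orthonormal),
#'   `eigenvalues` (all), `explained` (fractions, all), `n_components`.
#' @export
pca_fit <- function(X, threshold = 0.99) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) abort("need >= 2 samples", "invalid_parameter")
  if (!all(is.finite(X))) abort("X must be finite", "invalid_parameter")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  ev <- sv$d^2 / (nrow(X) - 1)
  tot <- sum(ev)
  if (tot <= 0 || max(ev) <= 1e-12 * ncol(X))
    abort("zero total variance: all rows identical", "degenerate_data")
  frac <- ev / tot
  ncomp <- which(cumsum(frac) >= threshold - 1e-12)[1]
  if (is.na(ncomp)) ncomp <- length(frac)
  list(center = center, loadings = sv$v[, seq_len(ncomp), drop = FALSE],
       eigenvalues = ev, explained = frac, n_components = ncomp)
}

pca_scores <- function(pca, X) {
  sweep(as.matrix(X), 2, pca$center) %*% pca$loadings
}

#' Canonical analysis with a MANOVA dimension test
#'
#' Solves the generalized eigenproblem of between-class versus within-class
#' scatter (canonical variates / Fisher discriminant directions) and tests
#' how many canonical dimensions are significant with Wilks' lambda using
#' Bartlett's chi-square approximation. The within-class scatter is
#' ridge-regularized by `1e-8 * trace/dim` when near-singular.
#'
#' @param scores numeric sample x component matrix (PCA scores).
#' @param labels class labels (>= 2 classes, each >= 2 samples).
#' @param alpha significance level of the dimension test.
#' @return list with `axes` (columns, scaled to unit pooled within-class
#'   variance), `eigenvalues`, `wilks` (lambda, chi-square, df, p per
#'   dimension test), `dimension` (significant axes, minimum 1), `means`
#'   (class means in score space).
#' @export
ca_fit <- function(scores, labels, alpha = 0.05) {
  X <- as.matrix(scores)
  labels <- factor(labels)
  g <- nlevels(labels); n <- nrow(X); p <- ncol(X)
  if (g < 2L) abort("need >= 2 classes", "invalid_parameter")
  if (any(table(labels) < 2L))
    abort("each class needs >= 2 samples", "invalid_parameter")
  grand <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  means <- matrix(NA_real_, g, p, dimnames = list(levels(labels), NULL))
  for (lv in levels(labels)) {
    Xi <- X[labels == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    means[lv, ] <- mi
    W <- W + crossprod(sweep(Xi, 2, mi))
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
  }
  eps <- 1e-8 * sum(diag(W)) / p
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) R <- tryCatch(chol(W + eps * diag(p)),
                                error = function(e) NULL)
  if (is.null(R))
    abort("within-class scatter singular even after regularization",
          "degenerate_data")
  Rinv <- backsolve(R, diag(p))
  M <- crossprod(Rinv, B %*% Rinv)          # symmetric whitened between-scatter
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  s <- min(g - 1L, p)                       # rank of between-class scatter
  lam <- pmax(es$values[seq_len(s)], 0)
  axes <- Rinv %*% es$vectors[, seq_len(s), drop = FALSE]
  # scale each axis to unit pooled within-class variance
  for (j in seq_len(s)) {
    wv <- drop(crossprod(axes[, j], W %*% axes[, j])) / (n - g)
    if (wv > 0) axes[, j] <- axes[, j] / sqrt(wv)
  }
  # Bartlett's chi-square test of "dimensions > k are null", k = 0..s-1
  wilks <- data.frame(k = seq_len(s) - 1L, lambda = NA_real_,
                      chisq = NA_real_, df = NA_real_, p = NA_real_)
  cfac <- n - 1 - (p + g) / 2
  for (k in seq_len(s) - 1L) {
    idx <- (k + 1L):s
    wilks$lambda[k + 1L] <- prod(1 / (1 + lam[idx]))
    wilks$chisq[k + 1L] <- cfac * sum(log1p(lam[idx]))
    wilks$df[k + 1L] <- (p - k) * (g - 1 - k)
    wilks$p[k + 1L] <- stats::pchisq(wilks$chisq[k + 1L],
                                     wilks$df[k + 1L], lower.tail = FALSE)
  }
  dimension <- 0L
  for (k in seq_len(s)) {
    if (wilks$p[k] < alpha) dimension <- k else break
  }
  dimension <- max(dimension, 1L)
  list(axes = axes, eigenvalues = lam, wilks = wilks,
       dimension = dimension, means = means)
}

#' k-nearest-neighbour classification
#'
#' Euclidean-distance majority vote among the `k` nearest training points;
#' a vote tie is broken in favour of the class of the single nearest
#' neighbour among the tied classes.
#'
#' @param train_scores,train_labels training coordinates and labels.
#' @param test_scores matrix (or vector, one sample) of query coordinates.
#' @param k neighbours (1 <= k <= number of training samples).
#' @return factor of predicted labels.
#' @export
knn_classify <- function(train_scores, train_labels, test_scores, k = 3L) {
  Tr <- as.matrix(train_scores)
  if (nrow(Tr) == 0L) abort("empty training set", "invalid_parameter")
  if (k > nrow(Tr)) abort("k exceeds training-set size", "invalid_parameter")
  labels <- factor(train_labels)
  Te <- as.matrix(test_scores)
  if (ncol(Te) != ncol(Tr)) Te <- matrix(test_scores, ncol = ncol(Tr))
  d2 <- outer(rowSums(Te^2), rep(1, nrow(Tr))) +
    outer(rep(1, nrow(Te)), rowSums(Tr^2)) - 2 * Te %*% t(Tr)
  pred <- character(nrow(Te))
  for (i in seq_len(nrow(Te))) {
    ord <- order(d2[i, ])
    nn <- labels[ord[seq_len(k)]]
    votes <- table(nn)
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1L) top else
      as.character(nn[match(TRUE, as.character(nn) %in% top)])
  }
  factor(pred, levels = levels(labels))
}

#' Fit the full PCA/canonical-analysis model
#'
#' The trained object holds everything needed to place and classify new
#' samples: centering vector, PCA basis, canonical axes, MANOVA result and
#' training coordinates. When a single canonical axis is significant, a
#' second display-only axis (the leading within-class residual direction
#' orthogonal to the canonical axis) is stored for 2-D score plots.
#'
#' @param X sample x feature matrix (or `bucket_table`).
#' @param labels class labels.
#' @param config a [classifier_config].
#' @return A `classifier_model`.
#' @export
pcaca_fit <- function(X, labels, config = classifier_config()) {
  if (inherits(X, "bucket_table")) X <- X$matrix
  X <- as.matrix(X)
  labels <- factor(labels)
  pca <- pca_fit(X, config$explained_variance_threshold)
  sc <- pca_scores(pca, X)
  ca <- ca_fit(sc, labels, alpha = config$manova_alpha)
  d <- ca$dimension
  train_canon <- sc %*% ca$axes[, seq_len(d), drop = FALSE]
  display_axes <- ca$axes[, seq_len(min(2L, ncol(ca$axes))), drop = FALSE]
  if (d == 1L && ncol(sc) > 1L) {
    # within-class residual direction orthogonal to CA1, display only
    a1 <- ca$axes[, 1] / sqrt(sum(ca$axes[, 1]^2))
    res <- sc
    for (lv in levels(labels))
      res[labels == lv, ] <- sweep(res[labels == lv, , drop = FALSE], 2,
                                   colMeans(res[labels == lv, , drop = FALSE]))
    res <- res - (res %*% a1) %*% t(a1)
    u <- svd(res, nu = 0, nv = 1)$v[, 1]
    display_axes <- cbind(CA1 = ca$axes[, 1], resid1 = u)
  }
  structure(list(pca = pca, ca = ca, config = config,
                 train_scores = train_canon,
                 train_display = sc %*% display_axes,
                 display_axes = display_axes,
                 labels = labels),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf(paste0("<classifier_model> %d samples, %d classes; %d PCA",
                     " components (%.1f%% variance), %d canonical axis(es)",
                     " (Wilks p = %.3g)\n"),
              nrow(x$train_scores), nlevels(x$labels), x$pca$n_components,
              100 * sum(x$pca$explained[seq_len(x$pca$n_components)]),
              x$ca$dimension, x$ca$wilks$p[1]))
  invisible(x)
}

#' Project new samples into a fitted model and classify them
#'
#' Centers with the training centering vector, projects through the PCA
#' basis and the canonical axes, and assigns class membership by k-NN
#' against the stored training coordinates.
#'
#' @param model a `classifier_model`.
#' @param new_samples matrix (or `bucket_table`) with the training feature
#'   dimension.
#' @return list with `coordinates` (canonical coordinates used for
#'   classification), `display` (2-D display coordinates) and `class`
#'   (factor of predictions).
#' @export
project <- function(model, new_samples) {
  stopifnot(inherits(model, "classifier_model"))
  if (inherits(new_samples, "bucket_table")) new_samples <- new_samples$matrix
  Xn <- as.matrix(new_samples)
  if (is.null(dim(new_samples))) Xn <- matrix(new_samples, nrow = 1L)
  if (ncol(Xn) != length(model$pca$center))
    abort(sprintf("feature dimension %d does not match model (%d)",
                  ncol(Xn), length(model$pca$center)), "invalid_parameter")
  sc <- pca_scores(model$pca, Xn)
  d <- model$ca$dimension
  canon <- sc %*% model$ca$axes[, seq_len(d), drop = FALSE]
  cls <- knn_classify(model$train_scores, model$labels, canon,
                      k = model$config$k_neighbors)
  list(coordinates = canon, display = sc %*% model$display_axes, class = cls)
}

stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    i <- which(labels == lv)
    fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  fold
}

#' Monte-Carlo embedded cross-validation
#'
#' For each of `mc_runs` seeded shuffles, a stratified `cv_folds`-fold
#' partition is drawn; for every fold the full PCA + canonical-analysis
#' model is fitted on the training folds only, the held-out fold is
#' projected into it and classified by k-NN, and all held-out predictions
#' (each sample predicted once per run) are pooled into one confusion
#' matrix. Set `aggregate = "per_run"` for the mean of per-run accuracies
#' instead of the pooled accuracy (the matrix itself is always pooled).
#'
#' @param X feature matrix or `bucket_table`.
#' @param labels class labels; each class must have at least `cv_folds`
#'   samples.
#' @param config a [classifier_config].
#' @param aggregate `"pooled"` (default) or `"per_run"` accuracy.
#' @return A `confusion_matrix`: list with `matrix` (true x predicted
#'   counts), `accuracy` (percent), `per_run_accuracy`, `config`.
#' @export
mccv <- function(X, labels, config = classifier_config(),
                 aggregate = c("pooled", "per_run")) {
  aggregate <- match.arg(aggregate)
  if (inherits(X, "bucket_table")) X <- X$matrix
  X <- as.matrix(X)
  labels <- factor(labels)
  if (any(table(labels) < config$cv_folds))
    abort("every class needs at least `cv_folds` samples", "invalid_parameter")
  lv <- levels(labels)
  cm <- matrix(0L, length(lv), length(lv), dimnames = list(true = lv,
                                                           predicted = lv))
  seeds <- derive_seeds(config$seed, config$mc_runs)
  per_run <- numeric(config$mc_runs)
  for (run in seq_len(config$mc_runs)) {
    set.seed(seeds[run])
    fold <- stratified_folds(labels, config$cv_folds)
    run_cm <- matrix(0L, length(lv), length(lv))
    for (f in seq_len(config$cv_folds)) {
      tr <- fold != f
      model <- pcaca_fit(X[tr, , drop = FALSE], labels[tr], config)
      pred <- project(model, X[!tr, , drop = FALSE])$class
      tt <- table(factor(labels[!tr], levels = lv), factor(pred, levels = lv))
      run_cm <- run_cm + tt
    }
    cm <- cm + run_cm
    per_run[run] <- 100 * sum(diag(run_cm)) / sum(run_cm)
  }
  out <- structure(list(matrix = cm,
                        accuracy = 100 * sum(diag(cm)) / sum(cm),
                        per_run_accuracy = per_run, config = config),
                   class = "confusion_matrix")
  if (aggregate == "per_run") out$accuracy <- mean(per_run)
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> accuracy %.1f%%\n", x$accuracy))
  print(x$matrix)
  invisible(x)
}

#' Accuracy of a confusion matrix, in percent
#'
#' @param cm a `confusion_matrix` or a square count matrix.
#' @return `100 * trace / total`.
#' @export
confusion_accuracy <- function(cm) {
  m <- if (inherits(cm, "confusion_matrix")) cm$matrix else as.matrix(cm)
  if (nrow(m) != ncol(m) || sum(m) <= 0)
    abort("confusion matrix must be square with positive total",
          "invalid_parameter")
  100 * sum(diag(m)) / sum(m)
}
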