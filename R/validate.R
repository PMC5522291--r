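resolve_xy <- function(benchmark, properties, lambda, include_kmer, k) {
  if (inherits(benchmark, "m5c_benchmark")) {
    tab <- if (is_standardized(properties)) properties else
      standardize_properties(properties)
    X <- encode_benchmark(benchmark, tab, lambda, include_kmer, k)
  } else if (is.matrix(benchmark)) {
    X <- benchmark
  } else stop("`benchmark` must be an m5c_benchmark or an encoded matrix")
  y <- attr(X, "labels")
  if (is.null(y)) stop("feature matrix lacks a 'labels' attribute")
  list(X = X, y = as_binary_labels(y))
}

cv_result <- function(y, score, threshold, method, config) {
  pred <- factor(ifelse(score >= threshold, "pos", "neg"),
                 levels = c("pos", "neg"))
  structure(list(method = method, scores = score, labels = y,
                 predictions = pred,
                 metrics = metrics_from_predictions(y, pred),
                 roc = roc_curve(y, score), config = config),
            class = "m5c_cv")
}

#' Jackknife (leave-one-out) cross-validation
#'
#' For each of the N windows, a fresh forest is trained on the other
#' N - 1 and scores the held-out window; the fold seed is
#' `seed + fold index`, so the whole procedure is reproducible while the
#' per-fold forests differ.  Metrics and the ROC curve are computed from
#' the N pooled out-of-fold vote fractions.
#'
#' @inheritParams m5c_forest
#' @param threshold decision threshold on the vote fraction.
#' @return object of class `m5c_cv`: out-of-fold `scores`, `labels`,
#'   `predictions`, pooled `metrics` (an `m5c_metrics`) and `roc`
#'   (an `m5c_roc`).
#' @export
m5c_jackknife <- function(benchmark, lambda = 5L, ntree = 100L, mtry = 22L,
                          properties = load_property_table(), seed = 1L,
                          subspace = c("per_split", "per_tree"),
                          threshold = 0.5, include_kmer = FALSE, k = 2L) {
  subspace <- match.arg(subspace)
  d <- resolve_xy(benchmark, properties, lambda, include_kmer, k)
  X <- d$X; y <- d$y
  n <- nrow(X)
  if (min(table(y)) < 2L)
    stop("jackknife needs at least 2 samples per class")
  score <- numeric(n)
  for (i in seq_len(n)) {
    ens <- fit_forest(X[-i, , drop = FALSE], y[-i], ntree = ntree,
                      mtry = mtry, subspace = subspace,
                      seed = as.integer(seed) + i)
    score[i] <- forest_votes(ens, X[i, , drop = FALSE])
  }
  cv_result(y, score, threshold, "jackknife",
            list(lambda = lambda, ntree = ntree, mtry = mtry,
                 subspace = subspace, seed = seed, threshold = threshold))
}

# stratified fold assignment; k == N degenerates to leave-one-out with
# fold i = sample i so that the jackknife is recovered exactly
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  if (k < 2L || k > n) stop("`k` must be in 2..N")
  if (k == n) return(seq_len(n))
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Class-proportional folds (seeded shuffle); each window is held out
#' exactly once, each fold's forest uses seed `seed + fold`, and metrics
#' are pooled over all N held-out predictions.  `k = N` reduces exactly
#' to [m5c_jackknife()].
#'
#' @inheritParams m5c_jackknife
#' @param k number of folds (default 10).
#' @return an `m5c_cv`, as for [m5c_jackknife()].
#' @export
m5c_kfold <- function(benchmark, k = 10L, lambda = 5L, ntree = 100L,
                      mtry = 22L, properties = load_property_table(),
                      seed = 1L, subspace = c("per_split", "per_tree"),
                      threshold = 0.5, include_kmer = FALSE, kmer_k = 2L) {
  subspace <- match.arg(subspace)
  d <- resolve_xy(benchmark, properties, lambda, include_kmer, kmer_k)
  X <- d$X; y <- d$y
  fold <- stratified_folds(y, as.integer(k), seed)
  score <- numeric(nrow(X))
  for (f in sort(unique(fold))) {
    hold <- fold == f
    ytr <- y[!hold]
    if (nlevels(droplevels(ytr)) < 2L)
      stop("a training fold lost one class; use fewer folds")
    ens <- fit_forest(X[!hold, , drop = FALSE], ytr, ntree = ntree,
                      mtry = mtry, subspace = subspace,
                      seed = as.integer(seed) + f)
    score[hold] <- forest_votes(ens, X[hold, , drop = FALSE])
  }
  cv_result(y, score, threshold, sprintf("%d-fold", as.integer(k)),
            list(k = k, lambda = lambda, ntree = ntree, mtry = mtry,
                 subspace = subspace, seed = seed, threshold = threshold))
}

#' @export
print.m5c_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation over %d windows\n",
              x$method, length(x$scores)))
  print(x$metrics)
  cat(sprintf("AUC = %.4f\n", x$roc$auc))
  invisible(x)
}

#' @export
plot.m5c_cv <- function(x, ...) plot(x$roc, ...)
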