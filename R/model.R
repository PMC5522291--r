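MODEL_FORMAT_VERSION <- 1L

# internal: fit a vote ensemble on an encoded matrix.  subspace = "per_split"
# is the usual forest (mtry candidate features per split); "per_tree"
# restricts each tree to its own random feature subset of that size.
fit_forest <- function(X, y, ntree = 100L, mtry = 22L,
                       subspace = c("per_split", "per_tree"), seed = 1L) {
  subspace <- match.arg(subspace)
  y <- as_binary_labels(y, "y")
  if (nrow(X) != length(y)) stop("X rows must match y length")
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class")
  if (mtry < 1L || mtry > ncol(X))
    stop("`mtry` (random-subspace dimension) must be in 1..", ncol(X))
  if (subspace == "per_split") {
    set.seed(as.integer(seed))
    fit <- randomForest::randomForest(X, y, ntree = ntree, mtry = mtry)
    list(mode = "per_split", fit = fit, ntree = ntree)
  } else {
    trees <- vector("list", ntree)
    for (t in seq_len(ntree)) {
      set.seed(as.integer(seed) + t)
      cols <- sample.int(ncol(X), mtry)
      rows <- sample.int(nrow(X), nrow(X), replace = TRUE)
      if (nlevels(droplevels(y[rows])) < 2L) rows <- seq_len(nrow(X))
      trees[[t]] <- list(
        cols = cols,
        fit = randomForest::randomForest(X[rows, cols, drop = FALSE],
                                         y[rows], ntree = 1L, mtry = mtry,
                                         replace = FALSE,
                                         sampsize = length(rows)))
    }
    list(mode = "per_tree", trees = trees, ntree = ntree)
  }
}

forest_votes <- function(ens, X) {
  if (ens$mode == "per_split") {
    v <- stats::predict(ens$fit, X, type = "vote", norm.votes = TRUE)
    unname(v[, "pos"])
  } else {
    vote <- matrix(0, nrow(X), length(ens$trees))
    for (t in seq_along(ens$trees)) {
      tr <- ens$trees[[t]]
      p <- stats::predict(tr$fit, X[, tr$cols, drop = FALSE])
      vote[, t] <- as.integer(p == "pos")
    }
    rowMeans(vote)
  }
}

#' Fit an m5C site classifier
#'
#' Trains the full predictor on a benchmark of labeled C-centered windows:
#' each window is encoded as a pseudo dinucleotide composition vector
#' (auto/cross-covariance over the standardized property table, maximum
#' lag `lambda`) and a random forest of `ntree` trees is grown, each tree
#' on a bootstrap resample, considering `mtry` randomly drawn features at
#' every split (the random-subspace dimension).  The prediction score of a
#' window is the fraction of trees voting "site".
#'
#' @param benchmark an `m5c_benchmark` (see [build_benchmark()] or
#'   [simulate_benchmark()]) with both classes present, or a feature
#'   matrix from [encode_benchmark()].
#' @param lambda maximum covariance lag; the feature dimension is
#'   `100 * lambda` (default 5 -> 500).
#' @param ntree number of trees (default 100).
#' @param mtry random-subspace dimension (default 22, approximately the
#'   square root of 500).
#' @param properties dinucleotide property table; standardized internally.
#' @param seed integer seed; training is fully reproducible given
#'   (data, seed).
#' @param subspace `"per_split"` (default: `mtry` candidate features at
#'   each split) or `"per_tree"` (each tree confined to its own `mtry`
#'   features).
#' @param include_kmer,k append a k-mer frequency block to the encoding.
#' @return object of class `m5c_forest`.
#' @examples
#' bm <- simulate_benchmark(n_pos = 20, n_neg = 40, xi = 10, seed = 7)
#' fit <- m5c_forest(bm, lambda = 2, ntree = 30, mtry = 14, seed = 7)
#' predict(fit, bm[1:3, ], type = "score")
#' @export
m5c_forest <- function(benchmark, lambda = 5L, ntree = 100L, mtry = 22L,
                       properties = load_property_table(), seed = 1L,
                       subspace = c("per_split", "per_tree"),
                       include_kmer = FALSE, k = 2L) {
  subspace <- match.arg(subspace)
  tab <- if (is_standardized(properties)) properties else
    standardize_properties(properties)
  if (inherits(benchmark, "m5c_benchmark")) {
    X <- encode_benchmark(benchmark, tab, lambda, include_kmer, k)
    y <- attr(X, "labels")
  } else if (is.matrix(benchmark)) {
    X <- benchmark
    y <- attr(X, "labels")
    if (is.null(y)) stop("feature matrix lacks a 'labels' attribute")
  } else stop("`benchmark` must be an m5c_benchmark or an encoded matrix")
  ens <- fit_forest(X, y, ntree = ntree, mtry = mtry, subspace = subspace,
                    seed = seed)
  structure(list(
    ensemble = ens,
    feature_dim = ncol(X),
    layout_version = LAYOUT_VERSION,
    property_checksum = property_checksum(tab),
    properties = tab,
    config = list(lambda = as.integer(lambda), ntree = as.integer(ntree),
                  mtry = as.integer(mtry), subspace = subspace,
                  seed = as.integer(seed), include_kmer = include_kmer,
                  k = as.integer(k)),
    n_pos = sum(y == "pos"), n_neg = sum(y == "neg"),
    format_version = MODEL_FORMAT_VERSION,
    call = match.call()), class = "m5c_forest")
}

encode_newdata <- function(object, newdata) {
  if (inherits(newdata, "m5c_benchmark"))
    newdata <- newdata$window
  if (is.character(newdata)) {
    X <- do.call(rbind, lapply(newdata, encode_window,
                               tab = object$properties,
                               lambda = object$config$lambda,
                               include_kmer = object$config$include_kmer,
                               k = object$config$k))
  } else if (is.matrix(newdata)) {
    X <- newdata
    lv <- attr(X, "layout_version")
    if (!is.null(lv) && !identical(lv, object$layout_version))
      stop("incompatible feature layout: matrix has '", lv,
           "', model expects '", object$layout_version, "'")
    ck <- attr(X, "property_checksum")
    if (!is.null(ck) && !identical(ck, object$property_checksum))
      stop("incompatible property table: checksum mismatch between ",
           "encoded matrix and model")
  } else stop("`newdata` must be windows, an m5c_benchmark, or a matrix")
  if (ncol(X) != object$feature_dim)
    stop("feature dimension mismatch: got ", ncol(X), ", model expects ",
         object$feature_dim)
  X
}

#' Predict m5C sites with a fitted classifier
#'
#' @param object an `m5c_forest`.
#' @param newdata windows to score: a character vector of C-centered
#'   windows, an `m5c_benchmark`, or an encoded feature matrix matching
#'   the model's layout and property table.
#' @param type `"class"` for pos/neg labels, `"score"` for the vote
#'   fraction in \[0, 1\] (a multiple of 1/ntree).
#' @param threshold decision threshold on the vote fraction; a score
#'   exactly at the threshold is called positive.  Must lie in \[0, 1\].
#' @param ... unused.
#' @return factor of labels or numeric score vector.
#' @export
predict.m5c_forest <- function(object, newdata,
                               type = c("class", "score"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single number in [0, 1]")
  X <- encode_newdata(object, newdata)
  score <- forest_votes(object$ensemble, X)
  if (type == "score") return(score)
  factor(ifelse(score >= threshold, "pos", "neg"), levels = c("pos", "neg"))
}

#' Scan a sequence set for candidate m5C sites
#'
#' Applies a fitted model to every cytosine of the input sequences:
#' extracts the model's window around each C (nearest-neighbor edge fill),
#' encodes and scores it.  Cs whose window contains a non-ACGU symbol are
#' skipped.
#'
#' @param object an `m5c_forest`.
#' @param seqs named character vector of RNA sequences (see
#'   [read_fasta()]).
#' @param xi flank size used for extraction; window length `2 * xi + 1`
#'   must satisfy the model's encoder (default reconstructs nothing --
#'   supply the xi the model was trained with).
#' @param threshold decision threshold (default 0.5).
#' @return data frame with columns `seq_id`, `position`, `score`, `label`
#'   (possibly zero rows).
#' @export
scan_sequences <- function(object, seqs, xi = 20L, threshold = 0.5) {
  stopifnot(inherits(object, "m5c_forest"))
  rows <- list()
  for (id in names(seqs)) {
    for (p in scan_c_sites(seqs[[id]])) {
      w <- extract_window(seqs[[id]], p, xi)
      if (grepl("[^ACGU]", w)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, position = p, window = w, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(seq_id = character(), position = integer(),
                      score = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  sc <- predict(object, df$window, type = "score")
  data.frame(seq_id = df$seq_id, position = df$position, score = sc,
             label = ifelse(sc >= threshold, "pos", "neg"),
             stringsAsFactors = FALSE)
}

#' @export
print.m5c_forest <- function(x, ...) {
  cfg <- x$config
  cat("m5C site classifier (pseudo dinucleotide composition + random forest)\n")
  cat(sprintf("  trees: %d   subspace dim: %d (%s)   lambda: %d   features: %d\n",
              cfg$ntree, cfg$mtry, cfg$subspace, cfg$lambda, x$feature_dim))
  cat(sprintf("  trained on %d positive / %d negative windows (seed %d)\n",
              x$n_pos, x$n_neg, cfg$seed))
  invisible(x)
}

#' @export
summary.m5c_forest <- function(object, ...) {
  print(object)
  if (object$ensemble$mode == "per_split") {
    oob <- object$ensemble$fit$confusion
    cat("  out-of-bag confusion (rows = truth):\n")
    print(oob)
  }
  invisible(object)
}

#' Save / load a fitted classifier
#'
#' The on-disk artifact is a versioned RDS carrying the ensemble together
#' with its encoder configuration, feature layout tag and property-table
#' checksum, so that an incompatible model/encoder pairing is caught at
#' load or predict time rather than silently mis-scoring.
#'
#' @param object an `m5c_forest`.
#' @param path file path.
#' @return `write_m5c_forest()` returns `path` invisibly;
#'   `read_m5c_forest()` returns the model.
#' @export
write_m5c_forest <- function(object, path) {
  stopifnot(inherits(object, "m5c_forest"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_m5c_forest
#' @export
read_m5c_forest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  if (!inherits(obj, "m5c_forest"))
    stop("file does not contain an m5c_forest model")
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION))
    stop("incompatible model format version: ", obj$format_version)
  obj
}
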