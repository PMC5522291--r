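#' k-mer composition of a window
#'
#' Normalized occurrence frequencies of all 4^k k-mers over {A, C, G, U},
#' in alphabetical order (AA < AC < AG < AU < CA < ... for k = 2).  Each
#' component is the k-mer count divided by L - k + 1, so the vector sums
#' to one.
#'
#' @param window sequence string over {A, C, G, U}.
#' @param k k-mer order (k = 1 gives mononucleotide frequencies).
#' @return named numeric vector of length 4^k summing to 1.
#' @export
kmer_composition <- function(window, k = 2L) {
  stopifnot(is.character(window), length(window) == 1L)
  k <- as.integer(k)
  L <- nchar(window)
  if (k < 1L || k > L) stop("`k` must be between 1 and the window length")
  alph <- c("A", "C", "G", "U")
  kmers <- alph
  if (k > 1L) for (i in 2:k) kmers <- as.vector(t(outer(kmers, alph, paste0)))
  kmers <- sort(kmers)
  obs <- substring(window, 1:(L - k + 1L), k:L)
  if (any(!obs %in% kmers)) stop("window contains symbols outside {A,C,G,U}")
  cnt <- table(factor(obs, levels = kmers))
  out <- as.vector(cnt) / (L - k + 1L)
  names(out) <- kmers
  out
}

# 10 x (L-1) matrix of property values along the window's dinucleotides
dinucleotide_profile <- function(window, tab) {
  L <- nchar(window)
  if (L < 2L) stop("window shorter than one dinucleotide")
  di <- substring(window, 1:(L - 1L), 2:L)
  if (any(!di %in% DINUCLEOTIDES))
    stop("window contains symbols outside {A,C,G,U}")
  unclass(tab)[, di, drop = FALSE]
}

check_lag <- function(g, L) {
  g <- as.integer(g)
  if (g < 1L || g > L - 2L)
    stop("lag must satisfy 1 <= g <= L - 2 (g = ", g, ", L = ", L,
         "): no summand otherwise")
  g
}

#' Auto-covariance of one property along a window
#'
#' Lagged covariance of the property-m profile over the window's
#' dinucleotides: deviations are taken from the window mean of that
#' property (over all L - 1 dinucleotides) and the products are averaged
#' over the L - 1 - g available pairs.
#'
#' @param window sequence string over {A, C, G, U}, length L.
#' @param m property row index (1..nrow(tab)).
#' @param g lag, 1 <= g <= L - 2.
#' @param tab a standardized `m5c_properties` table.
#' @return a single number.
#' @export
auto_covariance <- function(window, m, g, tab) {
  if (!is_standardized(tab)) stop("property table must be standardized")
  g <- check_lag(g, nchar(window))
  p <- dinucleotide_profile(window, tab)[m, ]
  d <- p - mean(p)
  n <- length(d)
  sum(d[1:(n - g)] * d[(1 + g):n]) / (n - g)
}

#' Cross-covariance of two properties along a window
#'
#' As [auto_covariance()], but correlating the profile of property `mu1`
#' at position i with that of property `mu2` at position i + g; the two
#' property indices must differ, and the statistic is asymmetric in them.
#'
#' @param window sequence string over {A, C, G, U}.
#' @param mu1,mu2 distinct property row indices.
#' @param g lag, 1 <= g <= L - 2.
#' @param tab a standardized `m5c_properties` table.
#' @return a single number.
#' @export
cross_covariance <- function(window, mu1, mu2, g, tab) {
  if (!is_standardized(tab)) stop("property table must be standardized")
  if (mu1 == mu2) stop("`mu1` and `mu2` must differ (use auto_covariance)")
  g <- check_lag(g, nchar(window))
  p <- dinucleotide_profile(window, tab)[c(mu1, mu2), , drop = FALSE]
  d1 <- p[1, ] - mean(p[1, ])
  d2 <- p[2, ] - mean(p[2, ])
  n <- length(d1)
  sum(d1[1:(n - g)] * d2[(1 + g):n]) / (n - g)
}

LAYOUT_VERSION <- "acc-lagmajor-1"

#' Encode a window as a pseudo dinucleotide composition vector
#'
#' The feature vector concatenates, lag-major, the auto-covariances
#' AC(m, g) for g = 1..lambda and m = 1..10 (components 1..10*lambda) and
#' the cross-covariances CC(mu1, mu2, g) for g = 1..lambda over the 90
#' ordered property pairs in lexicographic (mu1, mu2) order (components
#' 10*lambda + 1 .. 100*lambda).  With the default lambda = 5 the vector
#' has 500 components.  Optionally a k-mer composition block is appended.
#'
#' @param window sequence string over {A, C, G, U}, length >= lambda + 2.
#' @param tab an `m5c_properties` table (standardized automatically if not
#'   already).
#' @param lambda maximum lag (default 5).
#' @param include_kmer append a k-mer frequency block (default off).
#' @param k k-mer order for the optional block.
#' @return named numeric vector of length `100 * lambda`
#'   (+ 4^k if `include_kmer`).
#' @export
encode_window <- function(window, tab = load_property_table(), lambda = 5L,
                          include_kmer = FALSE, k = 2L) {
  if (!is_standardized(tab)) tab <- standardize_properties(tab)
  lambda <- as.integer(lambda)
  L <- nchar(window)
  if (lambda < 1L) stop("`lambda` must be >= 1")
  if (L < lambda + 2L)
    stop("window length ", L, " < lambda + 2 = ", lambda + 2L)
  p <- dinucleotide_profile(window, tab)
  np <- nrow(p)
  d <- p - rowMeans(p)
  n <- ncol(d)
  # ordered property pairs, lexicographic in (mu1, mu2), diagonal excluded
  pairs <- cbind(rep(seq_len(np), each = np), rep(seq_len(np), times = np))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  ac <- matrix(0, np, lambda)
  cc <- matrix(0, nrow(pairs), lambda)
  for (g in seq_len(lambda)) {
    M <- tcrossprod(d[, 1:(n - g), drop = FALSE],
                    d[, (1 + g):n, drop = FALSE]) / (n - g)
    ac[, g] <- diag(M)
    cc[, g] <- M[pairs]
  }
  out <- c(as.vector(ac), as.vector(cc))
  names(out) <- c(
    as.vector(outer(seq_len(np), seq_len(lambda),
                    function(m, g) sprintf("AC.p%d.g%d", m, g))),
    as.vector(vapply(seq_len(lambda), function(g)
      sprintf("CC.p%d.p%d.g%d", pairs[, 1], pairs[, 2], g),
      character(nrow(pairs)))))
  if (include_kmer) out <- c(out, kmer_composition(window, k))
  out
}

#' Encode a benchmark dataset into a feature matrix
#'
#' @param bm an `m5c_benchmark` (all windows the same length); rows keep
#'   the benchmark's order (positives first).
#' @param tab property table (standardized automatically).
#' @param lambda maximum lag.
#' @param include_kmer,k optional k-mer block, as in [encode_window()].
#' @return numeric matrix (windows x features) with attributes `labels`
#'   (factor pos/neg aligned to rows), `lambda`, `layout_version` and
#'   `property_checksum`.
#' @export
encode_benchmark <- function(bm, tab = load_property_table(), lambda = 5L,
                             include_kmer = FALSE, k = 2L) {
  stopifnot(inherits(bm, "m5c_benchmark"))
  if (nrow(bm) == 0L) stop("empty dataset")
  if (length(unique(nchar(bm$window))) != 1L)
    stop("mixed window lengths in dataset")
  if (!is_standardized(tab)) tab <- standardize_properties(tab)
  rows <- lapply(bm$window, encode_window, tab = tab, lambda = lambda,
                 include_kmer = include_kmer, k = k)
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  attr(X, "labels") <- bm$label
  attr(X, "lambda") <- as.integer(lambda)
  attr(X, "layout_version") <- LAYOUT_VERSION
  attr(X, "property_checksum") <- property_checksum(tab)
  X
}
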