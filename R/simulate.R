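#' Simulate a benchmark of C-centered windows
#'
#' Generates a seeded synthetic benchmark with the structure the
#' predictor assumes: (2*xi + 1)-nt windows with C fixed at the center,
#' negatives drawn i.i.d. from a background nucleotide composition, and
#' positives drawn from a mixture -- with probability `signal_strength` a
#' window carries the class signal (flanks from `signal_background`, and
#' the `motif`, if any, planted at `motif_offset`), otherwise it is pure
#' background.  At `signal_strength = 0` the two classes are
#' exchangeable.  All windows are distinct (collisions are resampled), so
#' the per-subset deduplication invariant holds by construction.
#'
#' The defaults mirror the structure of the real m5C benchmark this
#' pipeline targets: 475 positives vs 1,425 negatives (1:3 imbalance),
#' 41-nt windows (xi = 20); they emulate class-dependent flank
#' composition, not real m5C biology.
#'
#' @param n_pos,n_neg class sizes (defaults 475 / 1425).
#' @param xi flank size (default 20 -> 41-nt windows).
#' @param signal_strength probability in \[0, 1\] that a positive window
#'   carries the planted signal (default 0.9).
#' @param background nucleotide probabilities over A, C, G, U (must sum
#'   to 1); default uniform.
#' @param signal_background flank composition of signal-bearing
#'   positives; default shifts mass toward C and G.
#' @param motif optional subsequence over {A, C, G, U} planted in
#'   signal-bearing positives.
#' @param motif_offset 1-based start of the motif within the window;
#'   default places it immediately upstream of the center.  The motif
#'   must fit inside one flank (it may not cover the center).
#' @param seed integer seed; the dataset is a deterministic function of
#'   the configuration and seed.
#' @param max_retries resampling attempts per window before a collision
#'   is reported as an error.
#' @return an `m5c_benchmark` (positives first), with provenance ids
#'   `sim_pos_<i>` / `sim_neg_<i>` and position `xi + 1`.
#' @export
simulate_benchmark <- function(n_pos = 475L, n_neg = 1425L, xi = 20L,
                               signal_strength = 0.9,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, U = 0.25),
                               signal_background = c(A = 0.15, C = 0.35,
                                                     G = 0.35, U = 0.15),
                               motif = NULL, motif_offset = NULL,
                               seed = 1L, max_retries = 1000L) {
  nuc <- c("A", "C", "G", "U")
  check_comp <- function(p, what) {
    if (!setequal(names(p), nuc)) stop(what, " must be named A, C, G, U")
    if (abs(sum(p) - 1) > 1e-8) stop(what, " probabilities must sum to 1")
    if (any(p < 0)) stop(what, " probabilities must be non-negative")
    p[nuc]
  }
  background <- check_comp(background, "background")
  signal_background <- check_comp(signal_background, "signal_background")
  if (signal_strength < 0 || signal_strength > 1)
    stop("`signal_strength` must lie in [0, 1]")
  xi <- as.integer(xi)
  if (xi < 1L) stop("`xi` must be >= 1")
  W <- 2L * xi + 1L
  center <- xi + 1L
  if (!is.null(motif)) {
    mlen <- nchar(motif)
    if (mlen > xi) stop("motif longer than the flank (xi = ", xi, ")")
    if (!grepl("^[ACGU]+$", motif)) stop("motif must be over {A,C,G,U}")
    if (is.null(motif_offset)) motif_offset <- center - mlen
    motif_offset <- as.integer(motif_offset)
    if (motif_offset < 1L || motif_offset + mlen - 1L > W)
      stop("motif does not fit in the window at offset ", motif_offset)
    if (motif_offset <= center && motif_offset + mlen - 1L >= center)
      stop("motif may not cover the center position")
  }
  set.seed(as.integer(seed))
  draw <- function(p) {
    res <- sample(nuc, W, replace = TRUE, prob = p)
    res[center] <- "C"
    res
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  gen_one <- function(positive) {
    for (try in seq_len(max_retries)) {
      signal <- positive && stats::runif(1) < signal_strength
      res <- draw(if (signal) signal_background else background)
      if (signal && !is.null(motif)) {
        res[motif_offset:(motif_offset + nchar(motif) - 1L)] <-
          strsplit(motif, "")[[1]]
      }
      w <- paste(res, collapse = "")
      if (is.null(seen[[w]])) {
        seen[[w]] <- TRUE
        return(w)
      }
    }
    stop("could not generate a distinct window after ", max_retries,
         " attempts; composition too restrictive for the requested size")
  }
  pos <- vapply(seq_len(n_pos), function(i) gen_one(TRUE), "")
  neg <- vapply(seq_len(n_neg), function(i) gen_one(FALSE), "")
  df <- data.frame(
    window = c(pos, neg),
    label = rep(c("pos", "neg"), c(n_pos, n_neg)),
    seq_id = c(sprintf("sim_pos_%d", seq_len(n_pos)),
               sprintf("sim_neg_%d", seq_len(n_neg))),
    position = center, stringsAsFactors = FALSE)
  new_m5c_benchmark(df, xi)
}

#' Permute the labels of a benchmark
#'
#' Uniformly permutes the pos/neg labels over the windows (class sizes
#' and the window multiset are preserved) and restores the
#' positives-first row order.  Used for null calibration: on a
#' label-shuffled benchmark any cross-validated MCC should be near zero.
#'
#' @param bm an `m5c_benchmark`.
#' @param seed integer seed.
#' @return an `m5c_benchmark` with permuted labels.
#' @export
shuffle_labels <- function(bm, seed = 1L) {
  stopifnot(inherits(bm, "m5c_benchmark"))
  if (nrow(bm) == 0L) stop("empty dataset")
  set.seed(as.integer(seed))
  df <- as.data.frame(bm)
  df$label <- as.character(df$label)[sample.int(nrow(df))]
  new_m5c_benchmark(df[order(df$label != "pos"), , drop = FALSE],
                    attr(bm, "xi"))
}
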