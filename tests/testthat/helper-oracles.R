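# Independent oracles and small fixture builders used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

DINUCS <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))

# property table with chosen values for a few dinucleotides, default 0 elsewhere
toy_property_table <- function(..., n_props = NULL, standardized = TRUE) {
  rows <- list(...)
  vals <- t(vapply(rows, function(r) {
    v <- stats::setNames(rep(0, 16), DINUCS)
    v[names(r)] <- r
    v
  }, numeric(16)))
  rownames(vals) <- paste0("P", seq_len(nrow(vals)))
  if (!is.null(n_props) && n_props > nrow(vals)) {
    extra <- matrix(seq_len((n_props - nrow(vals)) * 16), ncol = 16,
                    dimnames = list(paste0("P", (nrow(vals) + 1):n_props),
                                    DINUCS))
    vals <- rbind(vals, extra)
  }
  property_table(vals, standardized = standardized)
}

# table of n random properties (then standardized properly)
random_property_table <- function(n_props = 10, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_props * 16), n_props, 16,
                 dimnames = list(paste0("P", seq_len(n_props)), DINUCS))
  standardize_properties(property_table(vals))
}

random_window <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# brute-force lagged covariance from first principles: explicit loop over
# dinucleotide substrings and table lookups
loop_cov <- function(window, m1, m2, g, tab) {
  L <- nchar(window)
  di <- substring(window, 1:(L - 1), 2:L)
  p1 <- unclass(tab)[m1, di]
  p2 <- unclass(tab)[m2, di]
  n <- L - 1
  s <- 0
  for (i in 1:(n - g)) {
    s <- s + (p1[i] - mean(p1)) * (p2[i + g] - mean(p2))
  }
  unname(s / (n - g))
}

# classical Matthews correlation from the TP/FP/TN/FN contingency table
matthews_mcc <- function(n_pos, n_neg, fn, fp) {
  tp <- n_pos - fn; tn <- n_neg - fp
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

# AUC as the pairwise rank statistic: P(pos score > neg score) + 0.5 ties
rank_auc <- function(y, scores) {
  sp <- scores[y == "pos"]
  sn <- scores[y == "neg"]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
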