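#' Convert DNA to RNA
#'
#' Normalizes case to upper and replaces every T with U, so that downstream
#' code works on the RNA alphabet {A, C, G, U}.  IUPAC ambiguity symbols
#' (N, R, Y, ...) are preserved; windows overlapping them are later excluded
#' during benchmark construction.
#'
#' @param x character vector of nucleotide sequences (DNA or RNA, any case).
#' @return character vector of the same length over the RNA alphabet (plus
#'   any preserved ambiguity symbols).  The operation is idempotent and
#'   length-preserving.
#' @examples
#' dna_to_rna("ACGT")  # "ACGU"
#' dna_to_rna("ttt")   # "UUU"
#' @export
dna_to_rna <- function(x) {
  if (!is.character(x)) stop("`x` must be a character vector of sequences")
  if (length(x) == 0L) stop("empty record: no sequences supplied")
  if (any(!nzchar(x))) stop("empty record: zero-length sequence at index ",
                            paste(which(!nzchar(x)), collapse = ", "))
  out <- chartr("T", "U", toupper(x))
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    attr(out, "ambiguous") <- which(bad)
  }
  out
}

#' Positions of cytosines in a sequence
#'
#' @param seq single RNA sequence string.
#' @return ascending integer vector of 1-based positions where the residue
#'   is C (possibly empty).
#' @examples
#' scan_c_sites("ACGU")  # 2
#' @export
scan_c_sites <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  which(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
}

#' Extract a centered window around a cytosine
#'
#' Returns the (2*xi + 1)-nt window centered on `position`.  Where the
#' window extends past either end of the sequence, the missing positions
#' are filled with the nearest existing residue (the terminal base of the
#' sequence), so the result always has length 2*xi + 1.
#'
#' @param seq single RNA sequence string.
#' @param position 1-based position of the candidate C (must be a C).
#' @param xi flank size in nucleotides (window width is 2*xi + 1).
#' @return window string of length 2*xi + 1 with C at index xi + 1.
#' @examples
#' extract_window("ACG", 2, xi = 1)  # "ACG"
#' extract_window("CA", 1, xi = 1)   # "CCA" (upstream filled with first base)
#' @export
extract_window <- function(seq, position, xi = 20L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  xi <- as.integer(xi)
  position <- as.integer(position)
  if (xi < 1L) stop("`xi` must be >= 1")
  L <- nchar(seq)
  if (position < 1L || position > L)
    stop("position ", position, " outside sequence of length ", L)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (res[position] != "C")
    stop("misannotation: residue at position ", position, " is '",
         res[position], "', not C")
  idx <- (position - xi):(position + xi)
  idx[idx < 1L] <- 1L
  idx[idx > L] <- L
  paste(res[idx], collapse = "")
}

new_m5c_benchmark <- function(df, xi) {
  stopifnot(is.data.frame(df),
            all(c("window", "label", "seq_id", "position") %in% names(df)))
  df$label <- factor(as.character(df$label), levels = c("pos", "neg"))
  rownames(df) <- NULL
  structure(df, xi = as.integer(xi), class = c("m5c_benchmark", "data.frame"))
}

#' Assemble a benchmark dataset of labeled windows
#'
#' Extracts a (2*xi + 1)-nt window for every annotated cytosine, splits the
#' windows into a positive and a negative subset by their label, and removes
#' exact duplicate window strings within each subset (first occurrence, in
#' input order, is kept; a window duplicated across the two subsets is
#' retained in both).  Windows containing any non-ACGU symbol are excluded
#' and counted in the `n_ambiguous` attribute.
#'
#' @param seqs named character vector of RNA sequences (names are sequence
#'   ids); run [dna_to_rna()] first if sequences may contain T.
#' @param annotations data frame with columns `seq_id`, `position` (1-based
#'   position of a C) and `label` (`"pos"` or `"neg"`).
#' @param xi flank size; windows have length 2*xi + 1 (default 20 -> 41 nt).
#' @return an object of class `m5c_benchmark`: a data frame with columns
#'   `window`, `label`, `seq_id`, `position`, positives first, with
#'   attributes `xi`, `n_deduplicated` and `n_ambiguous`.
#' @seealso [extract_window()], [sample_negative_sites()]
#' @export
build_benchmark <- function(seqs, annotations, xi = 20L) {
  stopifnot(is.character(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("`seqs` must be a named character vector")
  ann <- as.data.frame(annotations)
  need <- c("seq_id", "position", "label")
  if (!all(need %in% names(ann)))
    stop("annotations must have columns: ", paste(need, collapse = ", "))
  if (nrow(ann) == 0L) stop("no annotations supplied")
  unknown <- setdiff(unique(ann$seq_id), names(seqs))
  if (length(unknown))
    stop("annotations reference unknown sequence id(s): ",
         paste(unknown, collapse = ", "))
  if (!all(ann$label %in% c("pos", "neg")))
    stop("labels must be 'pos' or 'neg'")

  win <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    win[i] <- extract_window(seqs[[ann$seq_id[i]]], ann$position[i], xi)
  }
  df <- data.frame(window = win, label = as.character(ann$label),
                   seq_id = as.character(ann$seq_id),
                   position = as.integer(ann$position),
                   stringsAsFactors = FALSE)

  ambig <- grepl("[^ACGU]", df$window)
  n_ambig <- sum(ambig)
  df <- df[!ambig, , drop = FALSE]
  if (nrow(df) == 0L) stop("all windows excluded (ambiguous symbols)")

  keep_first <- function(d) d[!duplicated(d$window), , drop = FALSE]
  pos <- keep_first(df[df$label == "pos", , drop = FALSE])
  neg <- keep_first(df[df$label == "neg", , drop = FALSE])
  n_dedup <- (nrow(df) - nrow(pos) - nrow(neg))
  out <- new_m5c_benchmark(rbind(pos, neg), xi)
  attr(out, "n_deduplicated") <- n_dedup
  attr(out, "n_ambiguous") <- n_ambig
  out
}

#' Sample negative (unmodified) cytosine sites
#'
#' Every C position not annotated as positive is a candidate negative;
#' this draws a seeded subsample at a given negative:positive ratio, the
#' convention used to assemble imbalanced benchmarks (default 3 negatives
#' per positive).
#'
#' @param seqs named character vector of RNA sequences.
#' @param positives data frame with columns `seq_id`, `position` marking
#'   known modified sites.
#' @param ratio negatives drawn per positive (all candidates if fewer).
#' @param seed integer seed for the subsample.
#' @return data frame of negative annotations (`seq_id`, `position`,
#'   `label = "neg"`).
#' @export
sample_negative_sites <- function(seqs, positives, ratio = 3, seed = 1L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  pos_key <- paste(positives$seq_id, positives$position)
  cand <- do.call(rbind, lapply(names(seqs), function(id) {
    p <- scan_c_sites(seqs[[id]])
    if (length(p) == 0L) return(NULL)
    data.frame(seq_id = id, position = p, stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) stop("no cytosines found in `seqs`")
  cand <- cand[!(paste(cand$seq_id, cand$position) %in% pos_key), , drop = FALSE]
  n <- min(nrow(cand), round(ratio * nrow(positives)))
  set.seed(as.integer(seed))
  take <- sort(sample.int(nrow(cand), n))
  out <- cand[take, , drop = FALSE]
  out$label <- "neg"
  rownames(out) <- NULL
  out
}

#' @export
print.m5c_benchmark <- function(x, ...) {
  xi <- attr(x, "xi")
  cat("m5C benchmark dataset\n")
  cat("  windows : ", nrow(x), " of length ", 2L * xi + 1L,
      " nt (xi = ", xi, ")\n", sep = "")
  cat("  positive: ", sum(x$label == "pos"),
      "   negative: ", sum(x$label == "neg"), "\n", sep = "")
  invisible(x)
}
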