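#' Read sequences from FASTA
#'
#' Reads a (possibly multi-line) FASTA file and converts the sequences to
#' the RNA alphabet via [dna_to_rna()].
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences; ids are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  x <- as.character(ss)
  names(x) <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L)
  dna_to_rna(x)
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a site-annotation table
#'
#' Tab-separated file with a header row and columns `seq_id`, `position`
#' (1-based) and `label` (`pos`/`neg`); lines starting with `#` are
#' ignored.  If `seqs` is supplied, each annotation is validated against
#' it (position in range and pointing at a C).
#'
#' @param path TSV file.
#' @param seqs optional named character vector of sequences to validate
#'   against.
#' @return data frame with columns `seq_id`, `position`, `label`.
#' @export
read_annotations <- function(path, seqs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("seq_id", "position", "label")
  if (!all(need %in% names(ann)))
    stop("annotation file must have header columns: ",
         paste(need, collapse = ", "))
  pos_num <- suppressWarnings(as.integer(ann$position))
  bad <- which(is.na(pos_num) | pos_num < 1L | !(ann$label %in% c("pos", "neg")))
  if (length(bad))
    stop("malformed annotation row(s): ", paste(bad, collapse = ", "))
  ann$position <- pos_num
  if (!is.null(seqs)) {
    for (i in seq_len(nrow(ann))) {
      s <- seqs[[ann$seq_id[i]]]
      if (is.null(s) || is.na(s))
        stop("row ", i, ": unknown sequence id '", ann$seq_id[i], "'")
      if (ann$position[i] > nchar(s))
        stop("row ", i, ": position ", ann$position[i],
             " beyond sequence length ", nchar(s))
      if (substr(s, ann$position[i], ann$position[i]) != "C")
        stop("row ", i, ": residue at position ", ann$position[i],
             " is not C")
    }
  }
  ann[need]
}

#' Write a site-annotation table
#' @param ann data frame with columns `seq_id`, `position`, `label`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann[c("seq_id", "position", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a benchmark dataset to disk
#'
#' TSV format has columns `window`, `label`, `seq_id`, `position`; FASTA
#' format encodes label and provenance in the header as
#' `>w<i>|label=pos|src=<seq_id>:<position>`.
#'
#' @param bm an `m5c_benchmark`.
#' @param path output file.
#' @param format `"tsv"` (default) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bm, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(bm, "m5c_benchmark"))
  if (format == "tsv") {
    df <- as.data.frame(bm)[c("window", "label", "seq_id", "position")]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    hdr <- sprintf("w%d|label=%s|src=%s:%d", seq_len(nrow(bm)),
                   as.character(bm$label), bm$seq_id, bm$position)
    x <- bm$window
    names(x) <- hdr
    write_fasta(x, path)
  }
  invisible(path)
}

#' Read a benchmark dataset written by [write_benchmark()]
#'
#' @param path benchmark file (TSV or label-annotated FASTA).
#' @param format `"tsv"` or `"fasta"`.
#' @return an `m5c_benchmark`; `xi` is recovered from the window length.
#' @export
read_benchmark <- function(path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("window", "label", "seq_id", "position")
    if (!all(need %in% names(df)))
      stop("benchmark file must have columns: ", paste(need, collapse = ", "))
    df <- df[need]
  } else {
    ss <- Biostrings::readBStringSet(path)
    hdr <- names(ss)
    lab <- sub(".*\\|label=([a-z]+)\\|.*", "\\1", hdr)
    src <- sub(".*\\|src=", "", hdr)
    if (any(lab == hdr) || any(src == hdr))
      stop("FASTA headers lack |label=...|src=... fields")
    df <- data.frame(window = as.character(ss), label = lab,
                     seq_id = sub(":[0-9]+$", "", src),
                     position = as.integer(sub(".*:", "", src)),
                     stringsAsFactors = FALSE)
  }
  if (!all(df$label %in% c("pos", "neg")))
    stop("labels must be 'pos' or 'neg'")
  w <- unique(nchar(df$window))
  if (length(w) != 1L || w %% 2L != 1L)
    stop("benchmark windows must share one odd length; found: ",
         paste(w, collapse = ", "))
  xi <- (w - 1L) %/% 2L
  if (any(substr(df$window, xi + 1L, xi + 1L) != "C"))
    stop("benchmark contains windows without C at the center")
  new_m5c_benchmark(df[order(df$label != "pos"), , drop = FALSE], xi)
}
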