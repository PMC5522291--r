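DINUCLEOTIDES <- as.vector(outer(c("A", "C", "G", "U"),
                                 c("A", "C", "G", "U"), paste0))

#' Construct a dinucleotide property table
#'
#' @param values numeric matrix, one row per property, 16 columns named
#'   `AA`, `AC`, ..., `UU`; row names are the property names.
#' @param standardized logical flag recording whether each row has already
#'   been centered and scaled over the 16 dinucleotides.
#' @return an object of class `m5c_properties`.
#' @seealso [load_property_table()], [standardize_properties()]
#' @export
property_table <- function(values, standardized = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) != 16L)
    stop("property table must have 16 dinucleotide columns, found ",
         ncol(values))
  if (is.null(colnames(values)) || !setequal(colnames(values), DINUCLEOTIDES))
    stop("columns must be the 16 dinucleotides AA, AC, ..., UU")
  values <- values[, DINUCLEOTIDES, drop = FALSE]
  if (is.null(rownames(values)))
    stop("property rows must be named")
  if (anyDuplicated(rownames(values)))
    stop("duplicate property name: ",
         rownames(values)[duplicated(rownames(values))][1])
  if (!is.numeric(values) || anyNA(values))
    stop("property values must be numeric and complete")
  structure(values, standardized = isTRUE(standardized),
            class = c("m5c_properties", class(values)))
}

#' Load a dinucleotide property table
#'
#' Reads a TSV with a `property` name column and 16 dinucleotide columns.
#' With no argument, loads the table shipped with the package (helical
#' step parameters plus nearest-neighbor thermodynamics; see the file
#' header in `extdata/rna_dinucleotide_properties.tsv`).  The returned
#' table is unstandardized.
#'
#' @param path TSV file; `NULL` for the shipped default.
#' @return an `m5c_properties` table (10 properties x 16 dinucleotides for
#'   the default).
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rna_dinucleotide_properties.tsv",
                        package = "rnam5c", mustWork = TRUE)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"property" %in% names(df))
    stop("property table needs a 'property' column")
  vals <- as.matrix(df[setdiff(names(df), "property")])
  if (!is.numeric(vals)) stop("non-numeric cell in property table")
  rownames(vals) <- df$property
  property_table(vals, standardized = FALSE)
}

#' Save a property table to TSV
#' @param tab an `m5c_properties` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_property_table <- function(tab, path) {
  stopifnot(inherits(tab, "m5c_properties"))
  df <- data.frame(property = rownames(tab), unclass(tab)[, DINUCLEOTIDES],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize a property table
#'
#' Centers and scales each property to zero mean and unit population
#' standard deviation over its 16 dinucleotide values (divisor 16, not 15).
#' Idempotent; a property that is constant across dinucleotides is an
#' error (zero variance).
#'
#' @param tab an `m5c_properties` table.
#' @return the standardized table, with the `standardized` flag set.
#' @export
standardize_properties <- function(tab) {
  stopifnot(inherits(tab, "m5c_properties"))
  v <- unclass(tab)
  mu <- rowMeans(v)
  sdp <- sqrt(rowMeans((v - mu)^2))
  if (any(sdp == 0))
    stop("zero variance: property '", rownames(v)[which(sdp == 0)[1]],
         "' is constant across dinucleotides")
  property_table((v - mu) / sdp, standardized = TRUE)
}

is_standardized <- function(tab) isTRUE(attr(tab, "standardized"))

#' Checksum of a property table
#'
#' MD5 digest of the canonical text serialization (row/column order fixed,
#' values printed to 15 significant digits).  Stored in trained models so
#' that an encoder/model pairing with a different table is detectable.
#'
#' @param tab an `m5c_properties` table.
#' @return length-1 character MD5 string.
#' @export
property_checksum <- function(tab) {
  stopifnot(inherits(tab, "m5c_properties"))
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  writeLines(c(paste(rownames(tab), collapse = "\t"),
               paste(signif(as.vector(unclass(tab)), 15), collapse = "\t")),
             tf)
  unname(tools::md5sum(tf))
}

#' @export
print.m5c_properties <- function(x, ...) {
  cat("dinucleotide property table: ", nrow(x), " properties x 16 dinucleotides",
      if (is_standardized(x)) " (standardized)" else "", "\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}
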