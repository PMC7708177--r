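# Plain TSV writers/readers for the tables the workflow exchanges.
# Counts: miRNA rows x sample columns, first column "mirna".

#' Write / read a miRNA count (or TPM) matrix as TSV
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file.
#' @return `write_counts_tsv` returns `path` invisibly;
#'   `read_counts_tsv` returns a numeric matrix.
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(mirna = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a triad design table as TSV
#'
#' Columns: `group`, `role` (maternal/paternal/hybrid), `triad`, `sample`.
#' @param design Data frame.
#' @param path File path.
#' @return The path (write) or the data frame (read).
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read sequences as FASTA (wrapped at 60 columns)
#'
#' Thin wrappers over Biostrings; sequences are handled as DNA after
#' U->T normalization.
#'
#' @param seqs Named character vector.
#' @param path File path.
#' @return The path (write) or a named character vector (read).
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  # keep only the ID part of the header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write / read feature intervals as GFF3
#'
#' GFF3 is 1-based inclusive; the `type` metadata column is preserved.
#' @param features `GRanges` with a `type` column.
#' @param path File path.
#' @return The path (write) or a `GRanges` (read).
#' @export
write_features_gff3 <- function(features, path) {
  rtracklayer::export(features, path, format = "gff3")
  invisible(path)
}

#' @rdname write_features_gff3
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!"type" %in% names(S4Vectors::mcols(gr)))
    stop("GFF3 lacks a type column")
  gr$type <- as.character(gr$type)
  gr
}

#' Write / read a qPCR Ct table as TSV
#'
#' Columns: `sample`, `replicate`, `ct_target`, `ct_reference`.
#' @param ct_table Data frame.
#' @param path File path.
#' @return The path (write) or the data frame (read).
#' @export
write_ct_tsv <- function(ct_table, path) {
  utils::write.table(ct_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
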