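#' Length histogram of an sRNA read set
#'
#' Counts reads per length over the small-RNA window 18-30 nt; reads
#' outside the window are collected in an `"other"` bucket.
#'
#' @param lengths Integer vector of read lengths, or a data frame with a
#'   `length` column (e.g. `simulate_srna_reads()$reads`).
#' @param range Inclusive length window (default `c(18, 30)`).
#' @return Named integer vector: one entry per length in the window plus
#'   `"other"`.
#' @export
length_distribution <- function(lengths, range = c(18, 30)) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (length(lengths) == 0) stop("empty read set")
  lv <- seq(range[1], range[2])
  inside <- lengths >= range[1] & lengths <= range[2]
  hist <- table(factor(lengths[inside], levels = lv))
  out <- c(as.integer(hist), sum(!inside))
  names(out) <- c(as.character(lv), "other")
  out
}

# Precedence when a read overlaps several feature types: structural RNAs
# before genic context, genic before nothing.
.class_precedence <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                       "repeat", "exon", "intron")

#' Annotate reads by genomic feature class
#'
#' Assigns every read exactly one of the eleven annotation classes (see
#' [simulate_srna_reads()]) from its genomic placement. When a read
#' overlaps several feature types the precedence
#' miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > exon > intron decides;
#' exon/intron assignments are split into sense/antisense by strand
#' agreement between read and feature; reads overlapping nothing are
#' unannotated.
#'
#' @param reads Data frame with columns `chrom`, `start` (0-based), `end`
#'   (half-open), `strand`.
#' @param features `GRanges` (1-based) with a `type` metadata column over
#'   the eight feature types.
#' @return List: `class` (character vector, one class per read),
#'   `summary` (data frame: `class`, `count`, `percent`, all eleven
#'   classes, percentages summing to 100).
#' @export
annotate_read_classes <- function(reads, features) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (any(reads$end <= reads$start))
    stop("malformed read interval (end <= start in half-open coordinates)")
  if (!"type" %in% names(S4Vectors::mcols(features)))
    stop("features must carry a 'type' column")
  gr_reads <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand)
  hits <- GenomicRanges::findOverlaps(gr_reads, features,
                                      ignore.strand = TRUE)
  cls <- rep("unannotated", nrow(reads))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    ftype <- features$type[S4Vectors::subjectHits(hits)]
    fstrand <- as.character(GenomicRanges::strand(
      features[S4Vectors::subjectHits(hits)]))
    prec <- match(ftype, .class_precedence)
    best <- tapply(seq_along(q), q, function(ii) ii[which.min(prec[ii])])
    idx <- unlist(best)
    ri <- q[idx]
    assigned <- ftype[idx]
    genic <- assigned %in% c("exon", "intron")
    same <- reads$strand[ri] == fstrand[idx] | fstrand[idx] == "*"
    assigned[genic] <- paste0(assigned[genic],
                              ifelse(same[genic], "_sense", "_antisense"))
    cls[ri] <- assigned
  }
  counts <- table(factor(cls, levels = .read_classes))
  summary <- data.frame(class = names(counts),
                        count = as.integer(counts),
                        percent = 100 * as.integer(counts) / nrow(reads),
                        stringsAsFactors = FALSE)
  list(class = cls, summary = summary)
}

#' Count reads matching known mature miRNAs
#'
#' Matches unique sRNA sequences of 18-25 nt exactly (full mature length,
#' after U->T normalization and upper-casing) against a mature-miRNA
#' reference. A read matching several mature miRNAs (identical mature
#' sequences under different IDs) counts toward each, flagged multi-hit.
#'
#' @param reads Character vector of read sequences (with multiplicity).
#' @param mature Named character vector (or `DNAStringSet`/`RNAStringSet`)
#'   of mature miRNA sequences, miRBase-style IDs as names.
#' @param length_range Inclusive read-length filter (default `c(18, 25)`).
#' @return Data frame: `mirna`, `reads` (count), `multi_hit` (logical:
#'   the mature sequence is shared with another ID). miRNAs with zero
#'   reads are included with count 0.
#' @export
match_known_mirnas <- function(reads, mature, length_range = c(18, 25)) {
  if (length(mature) == 0) stop("empty mature-miRNA reference")
  nm <- names(mature)
  if (is.null(nm)) stop("mature reference must be named")
  mature <- chartr("Uu", "Tt", toupper(as.character(mature)))
  names(mature) <- nm
  reads <- chartr("Uu", "Tt", toupper(as.character(reads)))
  keep <- nchar(reads) >= length_range[1] & nchar(reads) <= length_range[2]
  reads <- reads[keep]
  read_tab <- table(reads)
  shared <- duplicated(mature) | duplicated(mature, fromLast = TRUE)
  n <- vapply(mature, function(s) {
    i <- match(s, names(read_tab))
    if (is.na(i)) 0L else as.integer(read_tab[i])
  }, integer(1))
  data.frame(mirna = names(mature), reads = unname(n),
             multi_hit = unname(shared) & n > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
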