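# Read classes reported by the profiler; genic classes split by strand
# agreement between read and feature.
.read_classes <- c("exon_antisense", "exon_sense", "intron_antisense",
                   "intron_sense", "miRNA", "rRNA", "repeat", "snRNA",
                   "snoRNA", "tRNA", "unannotated")

# Feature type and read/feature strand relation for each read class.
.class_feature <- function(class) {
  switch(class,
    exon_sense = list(type = "exon", antisense = FALSE),
    exon_antisense = list(type = "exon", antisense = TRUE),
    intron_sense = list(type = "intron", antisense = FALSE),
    intron_antisense = list(type = "intron", antisense = TRUE),
    unannotated = list(type = NA_character_, antisense = FALSE),
    list(type = class, antisense = FALSE))
}

.random_seq <- function(n, len) {
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate an annotated small-RNA read set with planted truth
#'
#' Lays out one synthetic chromosome with non-overlapping stranded feature
#' blocks (miRNA, rRNA, tRNA, snRNA, snoRNA, repeat, exon, intron) plus
#' unannotated gaps, then places reads: each read draws an annotation
#' class from `class_profile` and a length from `length_profile` (18-30 nt,
#' typically peaked at 21 and 24 nt) and is positioned uniformly inside an
#' interval of its class, on the feature strand (or the opposite strand
#' for the `*_antisense` classes; unannotated reads fall in gaps).
#'
#' @param length_profile Named numeric vector, proportions per read length
#'   (names are lengths in nt); must sum to 1.
#' @param class_profile Named numeric vector over (a subset of) the classes
#'   exon_antisense, exon_sense, intron_antisense, intron_sense, miRNA,
#'   rRNA, repeat, snRNA, snoRNA, tRNA, unannotated; must sum to 1.
#' @param n_reads Number of reads (> 0).
#' @param seed Integer RNG seed.
#' @return List: `reads` (data frame: `id`, `seq`, `chrom`, `start`
#'   (0-based), `end` (half-open), `strand`, `length`, `class_truth`),
#'   `features` (`GRanges` with a `type` column), `truth`
#'   (`class_counts`, `length_counts`, both named integer vectors).
#' @export
simulate_srna_reads <- function(length_profile, class_profile, n_reads,
                                seed = 1L) {
  if (length(length_profile) == 0 || length(class_profile) == 0)
    stop("profiles must be non-empty")
  if (abs(sum(length_profile) - 1) > 1e-9)
    stop("length_profile must sum to 1")
  if (abs(sum(class_profile) - 1) > 1e-9)
    stop("class_profile must sum to 1")
  if (n_reads < 1) stop("n_reads must be positive")
  bad <- setdiff(names(class_profile), .read_classes)
  if (length(bad)) stop("unknown read class(es): ", paste(bad, collapse = ", "))
  set.seed(seed)

  # one 2-kb block per feature type, separated by 1-kb unannotated gaps
  types <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
             "exon", "intron")
  block <- 2000L; gap <- 1000L
  starts <- gap + (seq_along(types) - 1L) * (block + gap)  # 0-based
  features <- GenomicRanges::GRanges(
    seqnames = "chrSim",
    ranges = IRanges::IRanges(start = starts + 1L, width = block),
    strand = "+")
  features$type <- types
  gap_starts <- c(0L, starts + block)  # 0-based gap starts

  cls <- sample(names(class_profile), n_reads, replace = TRUE,
                prob = class_profile)
  lens <- as.integer(sample(names(length_profile), n_reads, replace = TRUE,
                            prob = length_profile))
  start0 <- integer(n_reads); strand <- character(n_reads)
  for (i in seq_len(n_reads)) {
    info <- .class_feature(cls[i])
    if (is.na(info$type)) {
      g <- sample(length(gap_starts), 1)
      start0[i] <- gap_starts[g] + sample.int(gap - lens[i], 1) - 1L
      strand[i] <- "+"
    } else {
      b <- starts[match(info$type, types)]
      start0[i] <- b + sample.int(block - lens[i], 1) - 1L
      strand[i] <- if (info$antisense) "-" else "+"
    }
  }
  reads <- data.frame(
    id = sprintf("read%06d", seq_len(n_reads)),
    seq = .random_seq(n_reads, lens),
    chrom = "chrSim", start = start0, end = start0 + lens,
    strand = strand, length = lens, class_truth = cls,
    stringsAsFactors = FALSE)
  truth_class <- table(factor(cls, levels = .read_classes))
  truth_len <- table(factor(lens, levels = sort(unique(lens))))
  list(reads = reads, features = features,
       truth = list(class_counts = c(truth_class),
                    length_counts = c(truth_len)))
}
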