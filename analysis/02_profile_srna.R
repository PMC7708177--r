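#!/usr/bin/env Rscript
# Stage 2: profile the small-RNA read set — length distribution, feature
# class annotation, and known-miRNA matching — and check against the
# generator's truth counts.

suppressMessages(library(heteromir))
ind <- "results/simdata"; out <- "results/profile"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reads <- utils::read.delim(file.path(ind, "srna_placements.tsv"),
                           stringsAsFactors = FALSE)
features <- read_features_gff3(file.path(ind, "features.gff3"))

hist <- length_distribution(reads)
utils::write.table(data.frame(length = names(hist),
                              count = as.integer(hist)),
                   file.path(out, "length_histogram.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
peaks <- names(sort(hist[names(hist) != "other"], decreasing = TRUE))[1:2]
cat("length peaks:", paste(sort(peaks), collapse = " and "), "nt\n")

ann <- annotate_read_classes(reads, features)
utils::write.table(ann$summary, file.path(out, "class_annotation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
truth <- utils::read.delim(file.path(ind, "srna_class_truth.tsv"))
merged <- merge(ann$summary, truth, by = "class",
                suffixes = c("_called", "_truth"))
cat(sprintf("class annotation: %d/%d classes recovered exactly\n",
            sum(merged$count_called == merged$count_truth), nrow(merged)))

mature <- read_fasta(file.path(ind, "mature_mirnas.fa"))
srna_seqs <- read_fasta(file.path(ind, "srna_reads.fa"))
hits <- match_known_mirnas(unname(srna_seqs), mature)
utils::write.table(hits, file.path(out, "known_mirna_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("known-miRNA matching: %d reference miRNAs, %d with hits\n",
            nrow(hits), sum(hits$reads > 0)))
cat("done: tables under", out, "\n")
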