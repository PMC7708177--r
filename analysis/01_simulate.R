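#!/usr/bin/env Rscript
# Stage 1: generate the full synthetic study with planted ground truth.
# Emulates the design of the real experiment: four hybrid/parent triads
# (three replicates each), a small-RNA read set with the 21/24-nt length
# peaks, a degradome library with planted cleavage sites, and qPCR Ct
# tables. Everything downstream (02-06) runs from these files alone.

suppressMessages(library(heteromir))
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(20260922)

## four triads, one per hybrid combination; moderate replicate noise
triads <- c("hybridA", "hybridB", "hybridC", "hybridD")
sims <- lapply(seq_along(triads), function(i) simulate_triads(
  triad_sim_config(400, n_replicates = 3, dispersion = 0.05,
                   parent_mean_range = c(100, 800),
                   seed = 1000 + i),
  triad_id = triads[i]))
counts <- do.call(cbind, lapply(sims, `[[`, "counts"))
design <- do.call(rbind, lapply(sims, `[[`, "design"))
truth <- do.call(rbind, lapply(seq_along(sims), function(i)
  cbind(triad = triads[i], sims[[i]]$truth)))
write_counts_tsv(counts, file.path(out, "counts.tsv"))
write_design_tsv(design, file.path(out, "design.tsv"))
utils::write.table(truth, file.path(out, "triad_truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("triads: %d miRNAs x %d samples (%d triads)\n",
            nrow(counts), ncol(counts), length(triads)))

## sRNA reads: lengths peaked at 21 and 24 nt, Table-1-like class mix
len_prof <- c("18" = 0.04, "19" = 0.05, "20" = 0.08, "21" = 0.30,
              "22" = 0.10, "23" = 0.08, "24" = 0.25, "25" = 0.04,
              "26" = 0.03, "27" = 0.01, "28" = 0.01, "29" = 0.005,
              "30" = 0.005)
cls_prof <- c(exon_antisense = 0.01, exon_sense = 0.09,
              intron_antisense = 0.02, intron_sense = 0.03,
              miRNA = 0.02, rRNA = 0.09, "repeat" = 0.004,
              snRNA = 0.003, snoRNA = 0.002, tRNA = 0.03,
              unannotated = 0.701)
stopifnot(abs(sum(len_prof) - 1) < 1e-9, abs(sum(cls_prof) - 1) < 1e-9)
srna <- simulate_srna_reads(len_prof, cls_prof, n_reads = 20000,
                            seed = 2024)
# spike in copies of two known mature miRNAs so reference matching has
# planted positives (random background reads essentially never match)
mirnas <- c(mirA = "TGACAGAAGAGAGTGAGCAC",
            mirB = "TTGGACTGAAGGGAGCTCCC",
            mirC = "TGAAGCTGCCAGCATGATCTA")
spike <- c(rep(mirnas[["mirA"]], 150), rep(mirnas[["mirB"]], 80))
write_fasta(c(stats::setNames(srna$reads$seq, srna$reads$id),
              stats::setNames(spike, sprintf("spike%03d", seq_along(spike)))),
            file.path(out, "srna_reads.fa"))
utils::write.table(srna$reads, file.path(out, "srna_placements.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_features_gff3(srna$features, file.path(out, "features.gff3"))
utils::write.table(
  data.frame(class = names(srna$truth$class_counts),
             count = as.integer(srna$truth$class_counts)),
  file.path(out, "srna_class_truth.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("sRNA reads: %d placed over %d feature blocks\n",
            nrow(srna$reads), length(srna$features)))

## degradome: three planted miRNA target sites on synthetic transcripts
tx <- list(); sites <- NULL
for (i in seq_along(mirnas)) {
  pl <- plant_target_transcript(mirnas[[i]], tx_length = 600,
                                site_start = 150 + 40 * i, seed = 300 + i)
  tid <- paste0("tx", i)
  tx[[tid]] <- pl$seq
  sites <- rbind(sites, data.frame(
    mirna_id = names(mirnas)[i], mirna_seq = mirnas[[i]],
    transcript_id = tid, position = pl$cleavage_position,
    peak_reads = 30, stringsAsFactors = FALSE))
}
tx <- unlist(tx)
deg <- simulate_degradome_library(tx, sites, background_rate = 0.02,
                                  seed = 777)
write_fasta(tx, file.path(out, "transcripts.fa"))
write_fasta(mirnas, file.path(out, "mature_mirnas.fa"))
write_fasta(stats::setNames(deg$reads$seq, deg$reads$id),
            file.path(out, "degradome_reads.fa"))
utils::write.table(sites, file.path(out, "degradome_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("degradome: %d reads, %d planted sites\n",
            nrow(deg$reads), nrow(sites)))

## qPCR: Ct tables for two miRNAs with known relative expression
for (target in c("mirA", "mirB")) {
  folds <- if (target == "mirA") c(P1 = 1, P2 = 0.6, F1 = 0.3)
           else                  c(P1 = 1, P2 = 1.8, F1 = 3.2)
  ct <- simulate_qpcr_cts(folds, calibrator = "P1", noise_sd = 0.1,
                          n_reps = 3,
                          seed = 9000 + match(target, c("mirA", "mirB")))
  write_ct_tsv(ct, file.path(out, paste0("qpcr_", target, ".tsv")))
}
cat("qPCR Ct tables written\n")
cat("done: inputs under", out, "\n")
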