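#!/usr/bin/env Rscript
# Stage 6: term enrichment of the degradome target genes against a
# synthetic annotation map, and qPCR verification statistics: relative
# expression by 2^-ddCt with Fisher's LSD letters across genotypes.

suppressMessages(library(heteromir))
ind <- "results/simdata"; out <- "results/enrich_qpcr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(606)

## enrichment: targets = transcripts with called sites; the synthetic
## annotation enriches a "photosynthesis-like" term among them
sites <- utils::read.delim("results/degradome/cleavage_sites.tsv",
                           stringsAsFactors = FALSE)
targets <- unique(sites$transcript[sites$category <= 2])
background <- c(paste0("tx", 1:3), sprintf("gene%03d", 1:97))
annotation <- rbind(
  data.frame(gene = c(targets, sample(background, 5)),
             term = "T:0001", label = "photosynthesis-like process"),
  data.frame(gene = sample(background, 40), term = "T:0002",
             label = "broad housekeeping process"))
enr <- hypergeometric_enrichment(targets, background, annotation)
utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("enrichment: %d terms tested, %d significant (top: %s, p=%.3g)\n",
            nrow(enr), sum(enr$significant), enr$term[1], enr$p_value[1]))

## qPCR: relative expression and LSD letters per assayed miRNA
for (target in c("mirA", "mirB")) {
  ct <- read_ct_tsv(file.path(ind, paste0("qpcr_", target, ".tsv")))
  rel <- delta_delta_ct(ct, calibrator = "P1")
  # letters from the per-replicate dCt values (lower dCt = higher expression)
  dct <- split(ct$ct_target - ct$ct_reference, ct$sample)
  letters <- lsd_groups(dct)
  rel$letters <- letters$letters[match(rel$sample, letters$group)]
  utils::write.table(rel, file.path(out, paste0("relative_", target, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: folds %s; letters %s\n", target,
              paste(sprintf("%s=%.2f", rel$sample, rel$fold_change),
                    collapse = " "),
              paste(sprintf("%s:%s", rel$sample, rel$letters),
                    collapse = " ")))
}
cat("done: tables under", out, "\n")
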