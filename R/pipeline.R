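#' End-to-end heterosis analysis of one or more triads
#'
#' Orchestrates the expression arm of the workflow: TPM normalization,
#' hybrid-vs-parent differential tests, scaled unions, D/A classification,
#' induced/repressed tallies, cross-hybrid Venn partition and family
#' pattern tables. Writes per-stage TSVs, a run log and a machine-readable
#' JSON summary under `out_dir`; every number in the summary is
#' recomputable from the stage TSVs.
#'
#' @param counts Numeric count matrix (miRNA x sample) covering all
#'   triads.
#' @param design Design data frame (`group`, `role`, `triad`, `sample`).
#' @param out_dir Output directory (created; existing files are
#'   overwritten).
#' @param alpha,lfc_threshold,pseudocount DE thresholds (defaults 0.01, 1,
#'   1; see [differential_test()]).
#' @param var_equal Use Student instead of Welch t-test (default FALSE).
#' @param epsilon D/A undefined-denominator tolerance (see
#'   [compute_da()]).
#' @return (Invisibly) the summary list; side effect: files under
#'   `out_dir` (`de/<triad>_*.tsv`, `classify/<triad>.tsv`,
#'   `classify/venn_regions.tsv`, `summary.json`, `run.log`).
#' @export
run_heterosis_analysis <- function(counts, design, out_dir,
                                   alpha = 0.01, lfc_threshold = 1,
                                   pseudocount = 1, var_equal = FALSE,
                                   epsilon = 1e-9) {
  stopifnot(all(c("group", "role", "triad", "sample") %in% names(design)))
  miss <- setdiff(design$sample, colnames(counts))
  if (length(miss))
    stop("stage counts: samples missing from matrix: ",
         paste(miss, collapse = ", "))
  for (d in c("", "de", "classify"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("params: alpha=%g lfc=%g pseudocount=%g ttest=%s", alpha,
       lfc_threshold, pseudocount, if (var_equal) "student" else "welch")
  logf("counts: %d miRNAs x %d samples", nrow(counts), ncol(counts))

  tpm <- tpm_normalize(counts[, design$sample, drop = FALSE])
  triads <- unique(design$triad)
  per_triad <- list()
  scaled_sets <- list()
  classifications <- NULL
  for (tr in triads) {
    res <- analyse_triad(tpm, design, triad_id = tr, alpha = alpha,
                         lfc_threshold = lfc_threshold,
                         pseudocount = pseudocount, var_equal = var_equal)
    utils::write.table(res$de_maternal,
                       file.path(out_dir, "de", paste0(tr, "_vs_maternal.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$de_paternal,
                       file.path(out_dir, "de", paste0(tr, "_vs_paternal.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$classification,
                       file.path(out_dir, "classify", paste0(tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("triad %s: DE %d vs maternal, %d vs paternal, union %d; %d induced, %d repressed",
         tr, res$scaled$n_maternal, res$scaled$n_paternal,
         res$scaled$n_union, res$tally$n_induced, res$tally$n_repressed)
    per_triad[[tr]] <- list(
      n_de_vs_maternal = res$scaled$n_maternal,
      n_de_vs_paternal = res$scaled$n_paternal,
      n_common = res$scaled$n_common,
      n_scaled = res$scaled$n_union,
      n_induced = res$tally$n_induced,
      n_repressed = res$tally$n_repressed,
      n_neutral = res$tally$n_neutral,
      n_undefined = res$tally$n_undefined,
      percent_repressed = res$tally$percent_repressed,
      category_counts = as.list(table(factor(res$classification$category,
        levels = c("--", "-", "+-", "+", "++", "undefined")))))
    scaled_sets[[tr]] <- res$scaled$union
    classifications <- rbind(classifications, res$classification)
  }

  summary <- list(triads = per_triad)
  if (length(triads) >= 2) {
    venn <- cross_hybrid_overlap(scaled_sets)
    utils::write.table(venn$regions,
                       file.path(out_dir, "classify", "venn_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$venn <- list(core = venn$core,
                         unique_counts = as.list(venn$unique_counts),
                         n_union = venn$n_union)
    fams <- family_pattern_table(classifications)
    for (f in names(fams)) {
      fmt <- fams[[f]]$formatted
      utils::write.table(cbind(mirna = rownames(fmt), fmt),
                         file.path(out_dir, "classify",
                                   paste0("family_", f, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary$n_families <- length(fams)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("summary written: %s", file.path(out_dir, "summary.json"))
  invisible(summary)
}
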