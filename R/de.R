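#' TPM normalization of a miRNA count matrix
#'
#' Scales every column (sample) to transcripts per million:
#' `tpm_ij = count_ij * 1e6 / sum_i(count_ij)`. The denominator is the
#' total miRNA-assigned reads of the sample.
#'
#' @param counts Numeric matrix (miRNA x sample) of non-negative counts
#'   with column names.
#' @return Matrix of the same shape; every column sums to 1e6.
#' @examples
#' tpm_normalize(matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1")))
#' @export
tpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("all-zero count column(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, tot, "/") * 1e6
}

# Two-sample t-test p-value with the degenerate-variance conventions used
# by the DE filter: both groups constant and equal -> p = 1; both constant
# but different -> p = 0 (the difference is certain at zero within-group
# variance).
.t_pvalue <- function(x, y, var_equal = FALSE) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Per-miRNA differential expression between two replicate groups
#'
#' For each miRNA, a two-sided two-sample t-test on the replicate TPM
#' values (Welch by default) and a log2 fold change of group means with a
#' pseudocount:
#' `log2FC = log2(mean_a + c) - log2(mean_b + c)`.
#' A miRNA is significant when `p < alpha` and `|log2FC| > lfc_threshold`.
#'
#' Group a is conventionally the hybrid and group b a parent, so a
#' positive log2FC means higher expression in the hybrid.
#'
#' @param tpm TPM matrix (miRNA x sample) with column names.
#' @param group_a,group_b Character vectors of sample (column) names, >= 2
#'   replicates each.
#' @param pseudocount Added to both group means before log2 (default 1 TPM).
#' @param alpha P-value threshold (default 0.01, no multiple-testing
#'   correction; set `adjust = "BH"` to filter on BH-adjusted values).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param var_equal Use the pooled-variance (Student) t-test instead of
#'   Welch (default FALSE).
#' @param adjust P-value adjustment method for the significance filter
#'   (default "none"); the reported `p_value` is always unadjusted.
#' @param contrast Label stored in the output.
#' @return Data frame: `mirna`, `contrast`, `mean_a`, `mean_b`, `log2fc`,
#'   `p_value`, `significant`.
#' @export
differential_test <- function(tpm, group_a, group_b, pseudocount = 1,
                              alpha = 0.01, lfc_threshold = 1,
                              var_equal = FALSE, adjust = "none",
                              contrast = "a_vs_b") {
  tpm <- as.matrix(tpm)
  miss <- setdiff(c(group_a, group_b), colnames(tpm))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("at least 2 replicates required per group")
  a <- tpm[, group_a, drop = FALSE]
  b <- tpm[, group_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  log2fc <- log2(mean_a + pseudocount) - log2(mean_b + pseudocount)
  p <- vapply(seq_len(nrow(tpm)), function(i)
    .t_pvalue(a[i, ], b[i, ], var_equal = var_equal), numeric(1))
  p_filter <- if (identical(adjust, "none")) p else stats::p.adjust(p, adjust)
  data.frame(
    mirna = rownames(tpm),
    contrast = contrast,
    mean_a = mean_a,
    mean_b = mean_b,
    log2fc = log2fc,
    p_value = p,
    significant = p_filter < alpha & abs(log2fc) > lfc_threshold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Scaled candidate set: union of the two hybrid-vs-parent DE sets
#'
#' The miRNAs differentially expressed between a hybrid and its maternal
#' parent and/or its paternal parent form the hybrid's "scaled" set, the
#' input to D/A classification.
#'
#' @param de_vs_maternal,de_vs_paternal Character vectors of significant
#'   miRNA IDs from the two contrasts of one hybrid.
#' @return List: `union` (sorted IDs), `n_union`, `n_maternal`,
#'   `n_paternal`, `n_common`.
#' @examples
#' scaled_union(letters[1:4], letters[3:6])$n_union  # 6
#' @export
scaled_union <- function(de_vs_maternal, de_vs_paternal) {
  a <- unique(de_vs_maternal)
  b <- unique(de_vs_paternal)
  u <- sort(union(a, b))
  list(union = u, n_union = length(u), n_maternal = length(a),
       n_paternal = length(b), n_common = length(intersect(a, b)))
}

#' Full DE-and-classify analysis of one triad
#'
#' Runs both hybrid-vs-parent contrasts, forms the scaled union, and
#' classifies each scaled miRNA by D/A computed from replicate-mean TPM.
#'
#' @param tpm TPM matrix (miRNA x sample).
#' @param design Design data frame with columns `group`, `role`
#'   (`maternal`/`paternal`/`hybrid`), `triad`, `sample` (see
#'   [simulate_triads()]).
#' @param triad_id Triad to analyse (default: the only triad in `design`).
#' @param ... Passed to [differential_test()].
#' @return List: `de_maternal`, `de_paternal` (data frames), `scaled`
#'   (output of [scaled_union()]), `classification` (data frame from
#'   [classify_triad()] restricted to the scaled set), `tally`
#'   (output of [tally_direction()]).
#' @export
analyse_triad <- function(tpm, design, triad_id = NULL, ...) {
  stopifnot(all(c("group", "role", "triad", "sample") %in% names(design)))
  if (is.null(triad_id)) {
    triad_id <- unique(design$triad)
    if (length(triad_id) != 1)
      stop("design contains several triads; give triad_id")
  }
  d <- design[design$triad == triad_id, , drop = FALSE]
  samp <- function(role) d$sample[d$role == role]
  de_m <- differential_test(tpm, samp("hybrid"), samp("maternal"),
                            contrast = "hybrid_vs_maternal", ...)
  de_p <- differential_test(tpm, samp("hybrid"), samp("paternal"),
                            contrast = "hybrid_vs_paternal", ...)
  scaled <- scaled_union(de_m$mirna[de_m$significant],
                         de_p$mirna[de_p$significant])
  means <- data.frame(
    mirna = rownames(tpm),
    f1 = rowMeans(tpm[, samp("hybrid"), drop = FALSE]),
    p1 = rowMeans(tpm[, samp("maternal"), drop = FALSE]),
    p2 = rowMeans(tpm[, samp("paternal"), drop = FALSE]),
    stringsAsFactors = FALSE
  )
  cls <- classify_triad(means[means$mirna %in% scaled$union, , drop = FALSE],
                        triad_id = triad_id)
  list(de_maternal = de_m, de_paternal = de_p, scaled = scaled,
       classification = cls, tally = tally_direction(cls))
}
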