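#' Hypergeometric term enrichment of a target-gene set
#'
#' For every annotation term, tests over-representation of the term among
#' the target genes relative to the background with the upper-tail
#' hypergeometric probability `P(X >= k)` where `k` targets of `n` carry
#' the term, out of `K` annotated genes in a background of `N`. No
#' multiple-testing correction is applied by default (terms pass at raw
#' `p < alpha`); set `adjust = "BH"` to filter on adjusted values.
#'
#' @param target_genes Character vector of gene IDs (must be a subset of
#'   `background`).
#' @param background Character vector of background gene IDs.
#' @param annotation Data frame with columns `gene`, `term` and optionally
#'   `label` (term description).
#' @param alpha Significance cutoff (default 0.05).
#' @param adjust P-value adjustment method for the significance flag
#'   (default "none").
#' @return Data frame sorted by p-value: `term`, `label`, `k`, `K`, `n`,
#'   `N`, `p_value`, `significant`.
#' @export
hypergeometric_enrichment <- function(target_genes, background, annotation,
                                      alpha = 0.05, adjust = "none") {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  target_genes <- unique(target_genes)
  background <- unique(background)
  extra <- setdiff(target_genes, background)
  if (length(extra))
    stop("target genes missing from background: ",
         paste(extra, collapse = ", "))
  if (length(target_genes) == 0)
    return(data.frame(term = character(), label = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  ann <- unique(annotation[annotation$gene %in% background,
                           c("gene", "term")])
  labels <- if ("label" %in% names(annotation)) {
    u <- unique(annotation[, c("term", "label")])
    stats::setNames(u$label, u$term)
  } else NULL
  N <- length(background)
  n <- length(target_genes)
  terms <- unique(ann$term)
  res <- lapply(terms, function(tm) {
    genes_tm <- ann$gene[ann$term == tm]
    K <- length(genes_tm)
    k <- length(intersect(genes_tm, target_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm,
               label = if (is.null(labels)) tm else unname(labels[tm]),
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  p_filter <- if (identical(adjust, "none")) res$p_value else
    stats::p.adjust(res$p_value, adjust)
  res$significant <- p_filter < alpha
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
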