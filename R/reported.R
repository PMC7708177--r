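#' Published D/A values for scaled miRNAs in four maize hybrids
#'
#' Reference table of dominance/additivity values and inheritance-mode
#' labels reported for scaled miRNAs of four maize hybrid combinations
#' developed under the Reid x Tang-SPT heterotic pattern (Zhengdan 958,
#' Anyu 5, Zheng 58 x Huangzaosi, Ye 478 x Huangzaosi; V6-stage sixth
#' leaf). The `common` block lists the 13 miRNAs scaled in all four
#' hybrids; the family blocks (miR156, miR395, miR408/miR528, miR399)
#' list family members with their populated hybrid cells only.
#'
#' @return Data frame: `table` (block), `mirna`, `hybrid`, `da`, `label`.
#' @export
reported_da_calls <- function() {
  path <- system.file("extdata", "zma_hybrid_da_reported.tsv",
                      package = "heteromir", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "numeric", "character"))
}

#' Published per-hybrid differential-expression counts
#'
#' Counts of miRNAs significantly differentially expressed (P < 0.01,
#' |log2FC| > 1) between each maize hybrid and its maternal and paternal
#' inbred, with the overlap of the two contrasts, plus the published
#' induced (D/A > 0) and repressed (D/A < 0) tallies of the scaled union.
#'
#' @return Data frame: `hybrid`, `maternal`, `paternal`, `n_vs_maternal`,
#'   `n_vs_paternal`, `n_common`, `n_induced`, `n_repressed`.
#' @export
reported_de_counts <- function() {
  data.frame(
    hybrid = c("Zhengdan958", "Anyu5", "Ye478xHuangzaosi",
               "Zheng58xHuangzaosi"),
    maternal = c("Zheng58", "Ye478", "Ye478", "Zheng58"),
    paternal = c("Chang7-2", "Chang7-2", "Huangzaosi", "Huangzaosi"),
    n_vs_maternal = c(26L, 33L, 21L, 31L),
    n_vs_paternal = c(25L, 21L, 29L, 25L),
    n_common = c(9L, 4L, 11L, 9L),
    n_induced = c(17L, 23L, 18L, 21L),
    n_repressed = c(25L, 27L, 21L, 26L),
    stringsAsFactors = FALSE)
}
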