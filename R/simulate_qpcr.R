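#' Simulate qPCR Ct tables consistent with chosen fold changes
#'
#' Inverse model of the 2^-ddCt method with amplification efficiency 2:
#' each sample's target Ct is offset from the reference-gene Ct by
#' `base_delta_ct - log2(fold)` so that [delta_delta_ct()] applied to the
#' output recovers `true_fold_changes` (relative to the calibrator)
#' exactly when `noise_sd = 0`. Gaussian noise of `noise_sd` Ct units is
#' added independently to every well.
#'
#' @param true_fold_changes Named positive numeric vector: relative
#'   expression per sample; values are interpreted relative to the
#'   calibrator's entry.
#' @param calibrator Sample name used as calibrator (default: first).
#' @param reference_ct Reference-gene Ct level (default 20).
#' @param base_delta_ct Target-minus-reference Ct of the calibrator
#'   (default 2).
#' @param noise_sd Per-well Gaussian Ct noise (default 0).
#' @param n_reps Replicates per sample (default 3).
#' @param seed Integer RNG seed.
#' @return Data frame: `sample`, `replicate`, `ct_target`, `ct_reference`.
#' @examples
#' ct <- simulate_qpcr_cts(c(P1 = 1, F1 = 0.5))
#' delta_delta_ct(ct, calibrator = "P1")
#' @export
simulate_qpcr_cts <- function(true_fold_changes,
                              calibrator = names(true_fold_changes)[1],
                              reference_ct = 20, base_delta_ct = 2,
                              noise_sd = 0, n_reps = 3, seed = 1L) {
  if (is.null(names(true_fold_changes)))
    stop("true_fold_changes must be named by sample")
  if (any(true_fold_changes <= 0))
    stop("fold changes must be positive")
  if (!calibrator %in% names(true_fold_changes))
    stop("calibrator ", calibrator, " not among samples")
  set.seed(seed)
  rel <- true_fold_changes / true_fold_changes[[calibrator]]
  rows <- expand.grid(replicate = seq_len(n_reps),
                      sample = names(true_fold_changes),
                      stringsAsFactors = FALSE)[, c("sample", "replicate")]
  dct <- base_delta_ct - log2(rel[rows$sample])
  data.frame(
    sample = rows$sample,
    replicate = rows$replicate,
    ct_target = reference_ct + dct +
      stats::rnorm(nrow(rows), 0, noise_sd),
    ct_reference = reference_ct + stats::rnorm(nrow(rows), 0, noise_sd),
    stringsAsFactors = FALSE)
}
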