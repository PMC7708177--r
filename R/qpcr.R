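#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Per replicate, `dCt = Ct(target) - Ct(reference gene)`; dCt values are
#' averaged per sample, then `ddCt = mean dCt(sample) - mean
#' dCt(calibrator)` and the fold change is `2^-ddCt` (amplification
#' efficiency 2). The calibrator sample has ddCt 0 and fold change 1 by
#' construction.
#'
#' @param ct_table Data frame: `sample`, `replicate`, `ct_target`,
#'   `ct_reference`.
#' @param calibrator Sample name used as calibrator.
#' @return Data frame: `sample`, `n_reps`, `mean_dct`, `ddct`,
#'   `fold_change`.
#' @examples
#' ct <- simulate_qpcr_cts(c(P1 = 1, F1 = 4))
#' delta_delta_ct(ct, "P1")
#' @export
delta_delta_ct <- function(ct_table, calibrator) {
  need <- c("sample", "replicate", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct_table)))
  bad <- which(!is.finite(ct_table$ct_reference) |
               !is.finite(ct_table$ct_target))
  if (length(bad))
    stop("missing Ct value in row(s): ", paste(bad, collapse = ", "))
  if (!calibrator %in% ct_table$sample)
    stop("calibrator sample ", calibrator, " not in the table")
  dct <- ct_table$ct_target - ct_table$ct_reference
  mean_dct <- tapply(dct, ct_table$sample, mean)
  ddct <- mean_dct - mean_dct[[calibrator]]
  out <- data.frame(
    sample = names(mean_dct),
    n_reps = as.integer(table(ct_table$sample)[names(mean_dct)]),
    mean_dct = as.numeric(mean_dct),
    ddct = as.numeric(ddct),
    fold_change = 2^(-as.numeric(ddct)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[match(unique(ct_table$sample), out$sample), , drop = FALSE]
}

#' Fisher's LSD grouping letters after one-way ANOVA
#'
#' Fits a one-way ANOVA across groups, derives the least significant
#' difference for each pair,
#' `LSD_ij = t(1 - alpha/2, df_error) * sqrt(MSE * (1/n_i + 1/n_j))`,
#' and assigns compact letters: groups are ordered by descending mean and
#' each maximal run of mutually non-significant groups receives one
#' letter, so two groups share a letter iff no significant difference
#' separates them.
#'
#' @param values Named list of numeric replicate vectors (>= 2 groups,
#'   >= 2 replicates each), or a data frame with columns `group`, `value`.
#' @param alpha Significance level (default 0.05).
#' @return Data frame ordered by descending mean: `group`, `mean`, `n`,
#'   `letters`.
#' @examples
#' lsd_groups(list(a = c(10, 10.2, 9.9), b = c(20, 19.8, 20.1)))
#' @export
lsd_groups <- function(values, alpha = 0.05) {
  if (is.data.frame(values)) {
    stopifnot(all(c("group", "value") %in% names(values)))
    values <- split(values$value, values$group)
  }
  if (length(values) < 2) stop("need at least two groups")
  if (any(lengths(values) < 2)) stop("need >= 2 replicates per group")
  dat <- data.frame(
    group = factor(rep(names(values), lengths(values)),
                   levels = names(values)),
    value = unlist(values, use.names = FALSE))
  fit <- stats::aov(value ~ group, data = dat)
  df_err <- stats::df.residual(fit)
  if (df_err < 1) stop("zero error degrees of freedom")
  mse <- stats::deviance(fit) / df_err
  tcrit <- stats::qt(1 - alpha / 2, df_err)
  means <- vapply(values, mean, numeric(1))
  ns <- lengths(values)
  ord <- order(means, decreasing = TRUE)
  k <- length(values)
  sig <- function(i, j)  # indices into ord
    abs(means[ord[i]] - means[ord[j]]) >
      tcrit * sqrt(mse * (1 / ns[ord[i]] + 1 / ns[ord[j]]))
  # maximal runs of mutually non-significant groups (descending means)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(vapply((i):(j), function(a) sig(a, j + 1),
                                logical(1))))
      j <- j + 1
    runs[[length(runs) + 1]] <- i:j
  }
  # drop runs contained in another run
  keep <- vapply(seq_along(runs), function(a)
    !any(vapply(seq_along(runs), function(b)
      b != a && all(runs[[a]] %in% runs[[b]]), logical(1))), logical(1))
  runs <- runs[keep]
  letter_of <- vapply(seq_len(k), function(i)
    paste(letters[which(vapply(runs, function(r) i %in% r, logical(1)))],
          collapse = ""), character(1))
  data.frame(group = names(values)[ord], mean = means[ord], n = ns[ord],
             letters = letter_of, row.names = NULL,
             stringsAsFactors = FALSE)
}
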