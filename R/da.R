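#' Dominance/additivity (D/A) statistic for a hybrid/parent triad
#'
#' The D/A value scales the dominance deviation of an F1 hybrid by the
#' additive half-range of its parents: `(F1 - MP) / (HP - MP)`, where
#' `MP = (P1 + P2) / 2` is the mid-parent mean and `HP = max(P1, P2)` the
#' high-parent mean. Expression means are on the TPM scale. A D/A of 0 is
#' perfectly additive (F1 at mid-parent), 1 is high-parent dominance, and
#' values beyond +/-2 indicate expression outside the parental range
#' (over-/under-dominance).
#'
#' When the parents are (effectively) equal the additive half-range
#' vanishes and the statistic is undefined; such triads return `NA`.
#'
#' @param f1,p1,p2 Numeric vectors of mean hybrid, maternal and paternal
#'   expression (same length, finite, non-negative).
#' @param epsilon Relative tolerance below which `HP - MP` is treated as
#'   zero: the value is undefined when `HP - MP < epsilon * max(1, HP)`.
#' @return Numeric vector of D/A values, `NA` where undefined.
#' @examples
#' compute_da(30, 10, 20)   # MP = 15, HP = 20 -> 3
#' compute_da(15, 10, 20)   # mid-parent -> 0
#' compute_da(5, 10, 10)    # equal parents -> NA (undefined)
#' @export
compute_da <- function(f1, p1, p2, epsilon = 1e-9) {
  if (!all(is.finite(f1), is.finite(p1), is.finite(p2)))
    stop("expression means must be finite")
  if (any(f1 < 0) || any(p1 < 0) || any(p2 < 0))
    stop("expression means must be non-negative")
  mp <- (p1 + p2) / 2
  hp <- pmax(p1, p2)
  half_range <- hp - mp
  da <- ifelse(half_range < epsilon * pmax(1, hp), NA_real_,
               (f1 - mp) / half_range)
  da
}

#' Five-way inheritance-mode classification of a D/A value
#'
#' Assigns each D/A value to one of the five expression-inheritance modes
#' used for scaled miRNAs:
#' \describe{
#'   \item{`++`}{extremely high-parental, D/A > 2}
#'   \item{`+`}{high-parental, 0.5 < D/A <= 2}
#'   \item{`+-`}{additive, -0.5 <= D/A <= 0.5}
#'   \item{`-`}{low-parental, -2 <= D/A < -0.5}
#'   \item{`--`}{extremely low-parental, D/A < -2}
#' }
#' The published interval scheme is open at the cut points; boundary values
#' (+/-0.5, +/-2) are assigned here to the less extreme class so the map is
#' total and deterministic. `NA` (undefined denominator) returns
#' `"undefined"`.
#'
#' @param da Numeric vector of D/A values (may contain `NA`).
#' @return Character vector of category symbols.
#' @examples
#' classify_da(c(8.36, 0.51, 0.41, -0.6, -5.36, NA))
#' @export
classify_da <- function(da) {
  if (!is.numeric(da)) stop("da must be numeric")
  out <- rep("undefined", length(da))
  ok <- !is.na(da)
  x <- da[ok]
  out[ok] <- ifelse(x > 2, "++",
             ifelse(x > 0.5, "+",
             ifelse(x >= -0.5, "+-",
             ifelse(x >= -2, "-", "--"))))
  out
}

#' Ordered factor of inheritance-mode categories
#'
#' Utility used by summaries; rank order is `-- < - < +- < + < ++`.
#' @param category Character vector of category symbols.
#' @return Ordered factor.
#' @export
da_category_factor <- function(category) {
  factor(category, levels = c("--", "-", "+-", "+", "++"), ordered = TRUE)
}

#' Induced/repressed direction of a D/A value
#'
#' A scaled miRNA is induced when D/A > 0 and repressed when D/A < 0
#' (strict inequalities). D/A exactly 0 is "neutral"; an undefined D/A is
#' "undefined". Neutral and undefined entries are excluded from
#' induced/repressed tallies.
#'
#' @param da Numeric vector of D/A values.
#' @return Character vector in `{induced, repressed, neutral, undefined}`.
#' @export
da_direction <- function(da) {
  out <- rep("undefined", length(da))
  ok <- !is.na(da)
  out[ok] <- ifelse(da[ok] > 0, "induced",
             ifelse(da[ok] < 0, "repressed", "neutral"))
  out
}

#' Classify all scaled miRNAs of one triad
#'
#' Convenience wrapper: computes D/A, category and direction from a table
#' of per-miRNA triad means.
#'
#' @param triad Data frame with columns `mirna`, `f1`, `p1`, `p2`
#'   (mean TPM of hybrid, maternal and paternal groups).
#' @param triad_id Label recorded in the output (default "triad1").
#' @param epsilon Passed to [compute_da()].
#' @return Data frame with columns `mirna`, `triad`, `da`, `category`,
#'   `direction`.
#' @export
classify_triad <- function(triad, triad_id = "triad1", epsilon = 1e-9) {
  stopifnot(all(c("mirna", "f1", "p1", "p2") %in% names(triad)))
  da <- compute_da(triad$f1, triad$p1, triad$p2, epsilon = epsilon)
  data.frame(
    mirna = triad$mirna,
    triad = triad_id,
    da = da,
    category = classify_da(da),
    direction = da_direction(da),
    stringsAsFactors = FALSE
  )
}

# round-half-up to integer; base round() is round-half-even and would give
# 25/42 -> 59.52 -> 60 either way but 54.5-type cases need half-up
round_half_up <- function(x) floor(x + 0.5)

#' Tally induced vs repressed scaled miRNAs of one triad
#'
#' Counts miRNAs with D/A > 0 (induced) and D/A < 0 (repressed); entries
#' with D/A exactly 0 or undefined are excluded from both and reported
#' separately. The repressed percentage is
#' `100 * repressed / (induced + repressed)`, rounded half-up to an
#' integer.
#'
#' @param da Numeric vector of D/A values for one triad (NA = undefined),
#'   or a data frame as returned by [classify_triad()] (its `da` column is
#'   used).
#' @return List with `n_induced`, `n_repressed`, `n_neutral`,
#'   `n_undefined`, `percent_repressed` (NA when no induced or repressed
#'   miRNAs).
#' @examples
#' tally_direction(c(rep(1, 17), rep(-1, 25)))$percent_repressed  # 60
#' @export
tally_direction <- function(da) {
  if (is.data.frame(da)) da <- da$da
  dir <- da_direction(da)
  n_ind <- sum(dir == "induced")
  n_rep <- sum(dir == "repressed")
  pct <- if (n_ind + n_rep == 0) NA_real_ else
    round_half_up(100 * n_rep / (n_ind + n_rep))
  list(n_induced = n_ind, n_repressed = n_rep,
       n_neutral = sum(dir == "neutral"),
       n_undefined = sum(dir == "undefined"),
       percent_repressed = pct)
}
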