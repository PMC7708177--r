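#' Venn partition of scaled miRNA sets across hybrids
#'
#' Given the scaled miRNA ID sets of k triads, counts every one of the
#' 2^k - 1 Venn regions (exclusive membership patterns). Region counts sum
#' to the size of the union of all sets.
#'
#' @param sets Named list of character vectors (>= 2 sets).
#' @return List with `regions` (data frame: one logical column per set,
#'   `count`), `core` (count of IDs present in every set), `unique_counts`
#'   (named vector: IDs exclusive to each set), `n_union`.
#' @examples
#' cross_hybrid_overlap(list(a = c("x", "y"), b = c("y", "z")))
#' @export
cross_hybrid_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || is.null(names(sets)))
    stop("sets must be a named list of at least two ID sets")
  sets <- lapply(sets, unique)
  ids <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  pat_key <- apply(patterns, 1, paste, collapse = "|")
  obs_key <- if (length(ids)) apply(member, 1, paste, collapse = "|") else character()
  counts <- vapply(pat_key, function(p) sum(obs_key == p), integer(1))
  regions <- cbind(patterns, count = unname(counts))
  rownames(regions) <- NULL
  core <- regions$count[rowSums(regions[names(sets)]) == k]
  uniq <- vapply(seq_len(k), function(i) {
    regions$count[regions[[i]] & rowSums(regions[names(sets)]) == 1]
  }, integer(1))
  names(uniq) <- names(sets)
  list(regions = regions, core = core, unique_counts = uniq,
       n_union = length(ids))
}

#' miRNA family from a miRBase-style ID
#'
#' Extracts the family name (e.g. `"miR156"` from `"zma-miR156a-5p"`).
#' Returns `NA` for IDs with no recognizable `miR<number>` component.
#'
#' @param id Character vector of miRNA IDs.
#' @return Character vector of family names.
#' @export
mirna_family <- function(id) {
  m <- regmatches(id, regexpr("miR[0-9]+", id))
  out <- rep(NA_character_, length(id))
  out[regexpr("miR[0-9]+", id) > 0] <- m
  out
}

#' Family-level D/A pattern table across triads
#'
#' Builds, for each miRNA family, a member x triad matrix of (D/A,
#' category) pairs; cells where a member is not in that triad's scaled set
#' are marked absent (printed as `"\\"`). Members scaled in no triad are
#' dropped.
#'
#' @param classifications Data frame with columns `mirna`, `triad`, `da`,
#'   `category` (rows = scaled miRNAs, possibly several triads; see
#'   [classify_triad()]).
#' @param family_of Optional named character vector mapping miRNA ID to
#'   family; defaults to [mirna_family()] of the ID.
#' @param families Optional character vector restricting output families.
#' @return Named list (one element per family) of lists with `da`
#'   (numeric matrix, NA = absent), `category` (character matrix, NA =
#'   absent) and `formatted` (character data frame with `"\\"` for absent
#'   cells, D/A printed to 2 decimals).
#' @export
family_pattern_table <- function(classifications, family_of = NULL,
                                 families = NULL) {
  cl <- classifications
  stopifnot(all(c("mirna", "triad", "da", "category") %in% names(cl)))
  fam <- if (is.null(family_of)) mirna_family(cl$mirna) else
    unname(family_of[cl$mirna])
  cl$family <- fam
  cl <- cl[!is.na(cl$family), , drop = FALSE]
  if (!is.null(families)) cl <- cl[cl$family %in% families, , drop = FALSE]
  triads <- unique(classifications$triad)
  out <- lapply(split(cl, cl$family), function(d) {
    members <- unique(d$mirna)
    da_m <- matrix(NA_real_, length(members), length(triads),
                   dimnames = list(members, triads))
    cat_m <- matrix(NA_character_, length(members), length(triads),
                    dimnames = list(members, triads))
    idx <- cbind(match(d$mirna, members), match(d$triad, triads))
    da_m[idx] <- d$da
    cat_m[idx] <- d$category
    fmt <- matrix("\\", length(members), length(triads),
                  dimnames = list(members, triads))
    has <- !is.na(da_m)
    fmt[has] <- sprintf("%.2f (%s)", da_m[has], cat_m[has])
    list(da = da_m, category = cat_m,
         formatted = as.data.frame(fmt, stringsAsFactors = FALSE))
  })
  out
}
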