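# as.character() drops names (e.g. from a DNAStringSet-derived vector);
# keep them, taking DNAStringSet names where present
.named_chr <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  if (is.null(names(x))) names(x) <- nm
  x
}

#' Map degradome read 5' ends onto transcripts
#'
#' Each read's prefix (default 20 nt) is matched exactly against the
#' sense strand of every transcript; a match increments the 5'-end count
#' at the matched start position. Reads hitting several transcripts (or
#' several positions) increment each hit; hits are also tallied
#' separately. Reads shorter than `min_length` after prefix trimming are
#' dropped.
#'
#' @param reads Character vector of degradome read sequences (or a data
#'   frame with a `seq` column).
#' @param transcripts Named character vector (or `DNAStringSet`).
#' @param prefix_length Prefix used for matching (default 20 nt).
#' @param min_length Minimum usable read length (default 15 nt).
#' @return List: `profiles` (named list of integer vectors, one count per
#'   transcript position), `n_mapped`, `n_unmapped`, `n_multi` (reads
#'   with > 1 hit), `n_short`.
#' @export
map_degradome_reads <- function(reads, transcripts, prefix_length = 20,
                                min_length = 15) {
  if (is.data.frame(reads)) reads <- reads$seq
  tx <- toupper(.named_chr(transcripts))
  if (length(tx) == 0) stop("empty transcript set")
  if (is.null(names(tx))) stop("transcripts must be named")
  profiles <- lapply(tx, function(s) integer(nchar(s)))
  reads <- toupper(as.character(reads))
  n_short <- sum(nchar(reads) < min_length)
  reads <- reads[nchar(reads) >= min_length]
  prefixes <- substr(reads, 1, prefix_length)
  tab <- table(prefixes)
  tx_set <- Biostrings::DNAStringSet(tx)
  n_mapped <- 0L; n_unmapped <- 0L; n_multi <- 0L
  for (p in names(tab)) {
    mult <- as.integer(tab[[p]])
    hits <- Biostrings::vmatchPattern(p, tx_set)
    starts <- lapply(hits, IRanges::start)
    n_hits <- sum(lengths(starts))
    if (n_hits == 0) { n_unmapped <- n_unmapped + mult; next }
    n_mapped <- n_mapped + mult
    if (n_hits > 1) n_multi <- n_multi + mult
    for (tid in names(starts)) {
      for (s in starts[[tid]])
        profiles[[tid]][s] <- profiles[[tid]][s] + mult
    }
  }
  list(profiles = profiles, n_mapped = n_mapped, n_unmapped = n_unmapped,
       n_multi = n_multi, n_short = n_short)
}

# Per-pair penalty: Watson-Crick 0, G:U wobble 0.5, otherwise 1.
# mb = miRNA base, tb = target (mRNA) base, both DNA alphabet.
.pair_penalty <- function(mb, tb) {
  wc <- (mb == "A" & tb == "T") | (mb == "T" & tb == "A") |
        (mb == "G" & tb == "C") | (mb == "C" & tb == "G")
  wobble <- (mb == "G" & tb == "T") | (mb == "T" & tb == "G")
  ifelse(wc, 0, ifelse(wobble, 0.5, 1))
}

#' Plant-miRNA duplex penalty score
#'
#' Scores the ungapped antiparallel duplex between a miRNA and a
#' same-length target window: miRNA position i pairs with window position
#' `L - i + 1`. Per-position penalties: Watson-Crick pair 0, G:U wobble
#' 0.5, mismatch 1; penalties are doubled in the core region (miRNA
#' positions 2-13). Lower is better; a perfect reverse complement scores
#' 0.
#'
#' @param mirna miRNA sequence 5'->3' (U or T accepted).
#' @param target_site Transcript window 5'->3', same length as the miRNA.
#' @return Numeric penalty score.
#' @examples
#' score_duplex("ACGU", "ACGT")  # not complementary
#' @export
score_duplex <- function(mirna, target_site) {
  m <- chartr("Uu", "Tt", toupper(mirna))
  t <- chartr("Uu", "Tt", toupper(target_site))
  L <- nchar(m)
  if (nchar(t) != L) stop("miRNA and target window lengths differ")
  mb <- strsplit(m, "")[[1]]
  tb <- rev(strsplit(t, "")[[1]])  # antiparallel: miRNA i vs window L-i+1
  pen <- .pair_penalty(mb, tb)
  core <- seq_len(L) >= 2 & seq_len(L) <= 13
  sum(pen * ifelse(core, 2, 1))
}

# Vectorized duplex scores of every window of `tx_chars` against the
# miRNA; returns one score per window start.
.score_windows <- function(mirna_chars, tx_chars) {
  L <- length(mirna_chars)
  n_win <- length(tx_chars) - L + 1
  if (n_win < 1) return(numeric(0))
  scores <- numeric(n_win)
  core_mult <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  for (i in seq_len(L)) {
    # miRNA position i pairs with window offset L - i (0-based)
    tb <- tx_chars[seq_len(n_win) + (L - i)]
    scores <- scores + core_mult[i] * .pair_penalty(mirna_chars[i], tb)
  }
  scores
}

# CleaveLand-style abundance category of a candidate position within a
# degradome profile. A single raw read is always category 4; otherwise
# 0 = unique transcript maximum, 1 = tied maximum, 2 = above the median
# of nonzero positions, 3 = at or below that median.
.site_category <- function(profile, position) {
  reads <- profile[position]
  if (reads == 1) return(4L)
  mx <- max(profile)
  if (reads == mx) {
    return(if (sum(profile == mx) == 1) 0L else 1L)
  }
  med <- stats::median(profile[profile > 0])
  if (reads > med) 2L else 3L
}

#' Call miRNA cleavage sites from degradome profiles
#'
#' Slides every miRNA over every transcript window (ungapped, exhaustive).
#' For windows whose duplex penalty is at most `max_score`, the candidate
#' cleavage position is the transcript base paired to miRNA position 10
#' (canonical AGO slicing between the bases paired to miRNA positions
#' 10-11). A site is reported when the degradome profile carries at least
#' `min_reads` 5'-ends there, with an abundance category: 0 = the count
#' is the unique transcript maximum, 1 = a tied maximum, 2 = above the
#' median of nonzero positions, 3 = at or below that median (count > 1),
#' 4 = a single read.
#'
#' @param profiles Named list of per-position 5'-end counts (see
#'   [map_degradome_reads()]).
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param max_score Maximum duplex penalty (default 7).
#' @param min_reads Minimum 5'-end count at the site (default 1).
#' @return Data frame: `mirna`, `transcript`, `position` (1-based),
#'   `reads_at_site`, `duplex_score`, `category`, sorted by score then
#'   position.
#' @export
call_cleavage_sites <- function(profiles, mirnas, transcripts,
                                max_score = 7, min_reads = 1) {
  tx <- toupper(chartr("Uu", "Tt", .named_chr(transcripts)))
  mi <- toupper(chartr("Uu", "Tt", .named_chr(mirnas)))
  if (is.null(names(tx)) || is.null(names(mi)))
    stop("mirnas and transcripts must be named")
  common <- intersect(names(tx), names(profiles))
  out <- list()
  for (tid in common) {
    tx_chars <- strsplit(tx[[tid]], "")[[1]]
    prof <- profiles[[tid]]
    if (length(prof) != length(tx_chars))
      stop("profile length mismatch for ", tid)
    if (!any(prof >= min_reads)) next
    for (mid in names(mi)) {
      mirna_chars <- strsplit(mi[[mid]], "")[[1]]
      L <- length(mirna_chars)
      scores <- .score_windows(mirna_chars, tx_chars)
      ok <- which(scores <= max_score)
      for (w in ok) {
        pos <- w + L - 10  # base paired to miRNA position 10
        if (pos < 1 || pos > length(prof)) next
        reads <- prof[pos]
        if (reads < min_reads) next
        out[[length(out) + 1]] <- data.frame(
          mirna = mid, transcript = tid, position = pos,
          reads_at_site = reads, duplex_score = scores[w],
          category = .site_category(prof, pos),
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna = character(), transcript = character(),
               position = integer(), reads_at_site = integer(),
               duplex_score = numeric(), category = integer(),
               stringsAsFactors = FALSE)
  sites[order(sites$duplex_score, sites$transcript, sites$position), ,
        drop = FALSE]
}

#' T-plot data for one called cleavage site
#'
#' The T-plot shows degradome 5'-end counts along the full transcript
#' with the candidate cleavage position marked.
#'
#' @param profile Integer vector of per-position 5'-end counts.
#' @param position 1-based cleavage position to mark.
#' @return Data frame: `position`, `count`, `is_site`.
#' @export
tplot_data <- function(profile, position) {
  if (position < 1 || position > length(profile))
    stop("site position outside the transcript")
  data.frame(position = seq_along(profile), count = profile,
             is_site = seq_along(profile) == position)
}
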