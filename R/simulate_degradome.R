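#' Simulate a degradome (PARE) read library with planted cleavage sites
#'
#' Degradome sequencing captures the 5' ends of uncapped sense-strand
#' cleavage fragments. For each planted site, `peak_reads` reads start
#' exactly at the cleavage position (the transcript base paired to miRNA
#' position 10); background reads start at positions drawn uniformly
#' (Poisson `background_rate` per position, sense strand only). Read
#' sequences are transcript substrings of `read_length` nt (truncated at
#' the transcript end; reads shorter than 15 nt are dropped).
#'
#' Each planted site is validated: the target window opposite the miRNA
#' must score at most `max_score` under [score_duplex()].
#'
#' @param transcripts Named character vector (or `DNAStringSet`) of
#'   transcript sequences.
#' @param planted_sites Data frame with columns `mirna_id`, `mirna_seq`,
#'   `transcript_id`, `position` (1-based cleavage position),
#'   `peak_reads`. May have zero rows.
#' @param background_rate Expected background reads per transcript
#'   position (default 0).
#' @param read_length Read prefix length emitted (default 20 nt).
#' @param max_score Maximum allowed duplex penalty for a planted site
#'   (default 7).
#' @param seed Integer RNG seed.
#' @return List: `reads` (data frame: `id`, `seq`, `transcript_truth`,
#'   `position_truth`, `origin` in `{site, background}`), `truth` (the
#'   validated `planted_sites`).
#' @export
simulate_degradome_library <- function(transcripts, planted_sites,
                                       background_rate = 0,
                                       read_length = 20, max_score = 7,
                                       seed = 1L) {
  tx <- .named_chr(transcripts)
  if (is.null(names(tx)) || any(names(tx) == ""))
    stop("transcripts must be named")
  set.seed(seed)
  if (nrow(planted_sites)) {
    need <- c("mirna_id", "mirna_seq", "transcript_id", "position",
              "peak_reads")
    stopifnot(all(need %in% names(planted_sites)))
    for (i in seq_len(nrow(planted_sites))) {
      s <- planted_sites[i, ]
      if (!s$transcript_id %in% names(tx))
        stop("unknown transcript ", s$transcript_id)
      tlen <- nchar(tx[[s$transcript_id]])
      L <- nchar(s$mirna_seq)
      win_start <- s$position - L + 10
      if (s$position < 1 || s$position > tlen || win_start < 1 ||
          win_start + L - 1 > tlen)
        stop("cleavage position ", s$position,
             " out of range for transcript ", s$transcript_id)
      window <- substr(tx[[s$transcript_id]], win_start, win_start + L - 1)
      sc <- score_duplex(s$mirna_seq, window)
      if (sc > max_score)
        stop("planted duplex for ", s$mirna_id, " on ", s$transcript_id,
             " scores ", sc, " > max_score ", max_score)
    }
  }
  emit <- function(tid, pos, origin) {
    seqlen <- min(read_length, nchar(tx[[tid]]) - pos + 1)
    if (seqlen < 15) return(NULL)
    data.frame(seq = substr(tx[[tid]], pos, pos + seqlen - 1),
               transcript_truth = tid, position_truth = pos,
               origin = origin, stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(planted_sites))) {
    s <- planted_sites[i, ]
    r <- emit(s$transcript_id, s$position, "site")
    if (!is.null(r)) out[[length(out) + 1]] <- r[rep(1, s$peak_reads), ]
  }
  if (background_rate > 0) {
    for (tid in names(tx)) {
      n_bg <- stats::rpois(nchar(tx[[tid]]), background_rate)
      for (pos in which(n_bg > 0)) {
        r <- emit(tid, pos, "background")
        if (!is.null(r)) out[[length(out) + 1]] <- r[rep(1, n_bg[pos]), ]
      }
    }
  }
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(seq = character(), transcript_truth = character(),
               position_truth = integer(), origin = character(),
               stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  reads <- cbind(id = sprintf("deg%06d", seq_len(nrow(reads))), reads,
                 stringsAsFactors = FALSE)
  list(reads = reads, truth = planted_sites)
}

#' Random transcripts with an embedded perfect miRNA target site
#'
#' Helper for building degradome fixtures: generates a random transcript
#' and splices in the reverse complement of a miRNA so that the planted
#' cleavage position (paired to miRNA position 10) is known.
#'
#' @param mirna_seq miRNA sequence 5'->3' (U or T).
#' @param tx_length Transcript length (default 500).
#' @param site_start 1-based start of the target window (default 200).
#' @param seed Integer RNG seed.
#' @return List: `seq` (transcript), `cleavage_position` (1-based).
#' @export
plant_target_transcript <- function(mirna_seq, tx_length = 500,
                                    site_start = 200, seed = 1L) {
  set.seed(seed)
  m <- chartr("Uu", "Tt", toupper(mirna_seq))
  L <- nchar(m)
  if (site_start < 1 || site_start + L - 1 > tx_length)
    stop("target window does not fit in the transcript")
  base <- paste(sample(c("A", "C", "G", "T"), tx_length, replace = TRUE),
                collapse = "")
  site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
  seq <- paste0(substr(base, 1, site_start - 1), site,
                substr(base, site_start + L, tx_length))
  list(seq = seq, cleavage_position = site_start + L - 10)
}
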