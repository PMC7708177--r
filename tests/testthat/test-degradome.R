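test_that("duplex penalties follow the position-weighted rules", {
  mir <- "TGACAGAAGAGAGTGAGCAC"
  rc <- reverse_complement_chr(mir)
  expect_equal(score_duplex(mir, rc), 0)
  # mismatch at miRNA position 5 (core, doubled): window position L-5+1=16
  w <- rc
  substr(w, 16, 16) <- "C"  # pairs miRNA A5; neither WC nor wobble
  expect_equal(score_duplex(mir, w), 2)
  # G:U wobble at miRNA position 20 (outside the 2-13 core): 0.5
  mir_g <- "TGACAGAAGAGAGTGAGCAG"
  w2 <- reverse_complement_chr(mir_g)
  substr(w2, 1, 1) <- "T"   # pairs miRNA G20 as G:U
  expect_equal(score_duplex(mir_g, w2), 0.5)
  # U/T spelling equivalence and length guard
  expect_equal(score_duplex(chartr("T", "U", mir), rc), 0)
  expect_error(score_duplex(mir, substr(rc, 1, 10)), "length")
})

test_that("perfect reverse complements score zero for random miRNAs", {
  set.seed(33)
  for (i in 1:25) {
    m <- random_dna(sample(18:24, 1))
    expect_equal(score_duplex(m, reverse_complement_chr(m)), 0)
  }
})

test_that("map_degradome_reads counts 5' ends and conserves reads", {
  tx <- c(t1 = random_dna(300, seed = 41), t2 = random_dna(300, seed = 42))
  r100 <- substr(tx[["t1"]], 100, 119)
  res <- map_degradome_reads(c(r100), tx)
  expect_equal(res$profiles$t1[100], 1L)
  expect_equal(sum(res$profiles$t1), 1L)
  expect_equal(sum(res$profiles$t2), 0L)
  # unmapped and short reads tallied, not placed
  res2 <- map_degradome_reads(c(r100, paste(rep("A", 20), collapse = ""),
                                "ACGT"), tx)
  expect_equal(res2$n_unmapped, 1L)
  expect_equal(res2$n_short, 1L)
  expect_equal(res2$n_mapped, 1L)
  # conservation: profile mass equals mapped reads (multi-hit counted per hit)
  lib_reads <- c(rep(r100, 7), substr(tx[["t2"]], 55, 74))
  res3 <- map_degradome_reads(lib_reads, tx)
  expect_equal(sum(res3$profiles$t1) + sum(res3$profiles$t2),
               res3$n_mapped)
  expect_error(map_degradome_reads("ACGTACGTACGTACGTACGT",
                                   character()), "empty")
})

test_that("cleavage caller recovers a planted site at category 0", {
  mir <- "TGACAGAAGAGAGTGAGCAC"
  pl <- plant_target_transcript(mir, 500, 200, seed = 51)
  tx <- c(t1 = pl$seq)
  lib <- simulate_degradome_library(tx, data.frame(
    mirna_id = "m1", mirna_seq = mir, transcript_id = "t1",
    position = pl$cleavage_position, peak_reads = 50), seed = 52)
  prof <- map_degradome_reads(lib$reads, tx)
  expect_equal(prof$profiles$t1[pl$cleavage_position], 50L)
  expect_equal(sum(prof$profiles$t1), 50L)
  sites <- call_cleavage_sites(prof$profiles, c(m1 = mir), tx)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, pl$cleavage_position)
  expect_equal(sites$duplex_score, 0)
  expect_equal(sites$category, 0L)
  expect_equal(sites$reads_at_site, 50L)
})

test_that("abundance categories rank the site against the profile", {
  mir <- "TGACAGAAGAGAGTGAGCAC"
  pl <- plant_target_transcript(mir, 400, 100, seed = 61)
  tx <- c(t1 = pl$seq)
  pos <- pl$cleavage_position
  base <- integer(400)
  # tied maximum: candidate and one other position share the max
  p1 <- base; p1[pos] <- 10; p1[300] <- 10
  s1 <- call_cleavage_sites(list(t1 = p1), c(m1 = mir), tx)
  expect_equal(s1$category[s1$position == pos], 1L)
  # below max, above median of nonzero positions
  p2 <- base; p2[pos] <- 8; p2[300] <- 20; p2[310] <- 2; p2[320] <- 2
  s2 <- call_cleavage_sites(list(t1 = p2), c(m1 = mir), tx)
  expect_equal(s2$category[s2$position == pos], 2L)
  # at or below the median, more than one read
  p3 <- base; p3[pos] <- 2; p3[300] <- 20; p3[310] <- 12; p3[320] <- 2
  s3 <- call_cleavage_sites(list(t1 = p3), c(m1 = mir), tx)
  expect_equal(s3$category[s3$position == pos], 3L)
  # single read is category 4 even when it is the only signal
  p4 <- base; p4[pos] <- 1
  s4 <- call_cleavage_sites(list(t1 = p4), c(m1 = mir), tx)
  expect_equal(s4$category[s4$position == pos], 4L)
  # min_reads filters the candidate out
  s5 <- call_cleavage_sites(list(t1 = p4), c(m1 = mir), tx, min_reads = 2)
  expect_equal(nrow(s5), 0L)
})

test_that("tplot_data marks the called position along the transcript", {
  prof <- c(0L, 3L, 0L, 10L, 1L)
  tp <- tplot_data(prof, 4)
  expect_equal(tp$count, prof)
  expect_equal(which(tp$is_site), 4L)
  expect_error(tplot_data(prof, 9), "outside")
})
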