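test_that("compute_da evaluates the (F1-MP)/(HP-MP) formula", {
  expect_equal(compute_da(30, 10, 20), 3)     # MP=15, HP=20
  expect_equal(compute_da(20, 10, 20), 1)     # F1 at high parent
  expect_equal(compute_da(15, 10, 20), 0)     # F1 at mid-parent
  expect_true(is.na(compute_da(5, 10, 10)))   # equal parents: undefined
  expect_error(compute_da(-1, 10, 20), "non-negative")
  expect_error(compute_da(NaN, 10, 20), "finite")
})

test_that("compute_da is scale invariant and parent symmetric", {
  set.seed(11)
  for (i in 1:50) {
    p1 <- runif(1, 1, 100); p2 <- p1 * runif(1, 1.2, 4)
    f1 <- runif(1, 0, 300); k <- runif(1, 0.01, 100)
    expect_equal(compute_da(k * f1, k * p1, k * p2),
                 compute_da(f1, p1, p2))
    expect_equal(compute_da(f1, p2, p1), compute_da(f1, p1, p2))
  }
})

test_that("classify_da applies the five-class interval scheme", {
  expect_equal(classify_da(c(8.36, 2.69, 1.67, 0.51, 0.41, 0.1, -0.39,
                             -0.6, -1.06, -2.14, -5.36)),
               c("++", "++", "+", "+", "+-", "+-", "+-", "-", "-",
                 "--", "--"))
  # boundaries go to the less extreme class
  expect_equal(classify_da(c(-2, -0.5, 0.5, 2)), c("-", "+-", "+-", "+"))
  expect_equal(classify_da(NA_real_), "undefined")
})

test_that("classify_da is total and monotone in da", {
  da <- sort(runif(500, -8, 8))
  cat <- classify_da(da)
  expect_false(any(cat == "undefined"))
  rank <- as.integer(da_category_factor(cat))
  expect_true(all(diff(rank) >= 0))
})

test_that("direction tallies count strict signs and round half-up", {
  t1 <- tally_direction(c(rep(0.8, 17), rep(-0.8, 25)))
  expect_equal(t1$n_induced, 17)
  expect_equal(t1$n_repressed, 25)
  expect_equal(t1$percent_repressed, 60)
  # zero and undefined excluded from both tallies
  t2 <- tally_direction(c(1, -1, 0, NA))
  expect_equal(t2$n_induced, 1)
  expect_equal(t2$n_repressed, 1)
  expect_equal(t2$n_neutral, 1)
  expect_equal(t2$n_undefined, 1)
  expect_equal(t2$percent_repressed, 50)
  expect_equal(tally_direction(rep(2, 5))$percent_repressed, 0)
  expect_true(is.na(tally_direction(numeric(0))$percent_repressed))
})

test_that("cross_hybrid_overlap partitions the union exactly", {
  # identical sets: everything in the core
  same <- cross_hybrid_overlap(list(a = letters[1:5], b = letters[1:5],
                                    c = letters[1:5], d = letters[1:5]))
  expect_equal(same$core, 5L)
  expect_equal(sum(same$regions$count), 5L)
  expect_equal(unname(same$unique_counts), rep(0L, 4))
  # pairwise disjoint sets: unique counts equal set sizes
  disj <- cross_hybrid_overlap(list(a = letters[1:2], b = letters[3:5],
                                    c = letters[6:9], d = letters[10]))
  expect_equal(disj$core, 0L)
  expect_equal(unname(disj$unique_counts), c(2L, 3L, 4L, 1L))
  expect_equal(sum(disj$regions$count), disj$n_union)
  # random sets: region counts always partition the union
  set.seed(7)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) sample(letters, sample(3:15, 1)))
    names(sets) <- c("x", "y", "z")
    ov <- cross_hybrid_overlap(sets)
    expect_equal(sum(ov$regions$count), length(unique(unlist(sets))))
  }
})

test_that("family tables place cells exactly where members are scaled", {
  cls <- data.frame(
    mirna = c("zma-miR156j-3p", "zma-miR156j-3p", "zma-miR156j-3p",
              "zma-miR399d-5p"),
    triad = c("h2", "h3", "h4", "h1"),
    da = c(-3.19, -1.61, -5.11, 1.08),
    category = c("--", "-", "--", "+"),
    stringsAsFactors = FALSE)
  fams <- family_pattern_table(cls)
  expect_setequal(names(fams), c("miR156", "miR399"))
  m <- fams$miR156
  expect_true(is.na(m$da["zma-miR156j-3p", "h1"]))
  expect_equal(m$da["zma-miR156j-3p", "h2"], -3.19)
  expect_equal(m$category["zma-miR156j-3p", "h4"], "--")
  expect_equal(m$formatted["zma-miR156j-3p", "h1"], "\\")
  # absent cell iff the member is not scaled in that triad
  expect_equal(unname(is.na(m$da["zma-miR156j-3p", c("h2", "h3", "h4", "h1")])),
               c(FALSE, FALSE, FALSE, TRUE))
})

test_that("mirna_family extracts the family from miRBase-style IDs", {
  expect_equal(mirna_family(c("zma-miR156a-5p", "zma-miR1432-5p",
                              "zma-miR408a", "novel-x")),
               c("miR156", "miR1432", "miR408", NA))
})
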