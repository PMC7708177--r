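test_that("hypergeometric p matches exhaustive enumeration for N <= 12", {
  cases <- list(c(N = 10, K = 5, n = 4, k = 4),
                c(N = 10, K = 5, n = 4, k = 2),
                c(N = 12, K = 3, n = 6, k = 1),
                c(N = 12, K = 7, n = 5, k = 3),
                c(N = 8,  K = 8, n = 3, k = 3))  # term covers everything
  for (cs in cases) {
    genes <- paste0("g", seq_len(cs["N"]))
    ann <- data.frame(gene = genes[seq_len(cs["K"])], term = "T",
                      stringsAsFactors = FALSE)
    # target set with exactly k annotated genes
    target <- c(genes[seq_len(cs["k"])],
                genes[cs["K"] + seq_len(cs["n"] - cs["k"])])
    res <- hypergeometric_enrichment(target, genes, ann)
    expect_equal(res$p_value,
                 hyper_enum_oracle(cs["N"], cs["K"], cs["n"], cs["k"]),
                 tolerance = 1e-12,
                 label = paste(names(cs), cs, collapse = " "))
  }
})

test_that("enrichment handles edge cases and validates the background", {
  genes <- paste0("g", 1:10)
  ann <- data.frame(gene = genes, term = "all")
  res <- hypergeometric_enrichment(genes[1:4], genes, ann)
  expect_equal(res$p_value, 1)        # term annotates every gene
  expect_false(res$significant)
  empty <- hypergeometric_enrichment(character(), genes, ann)
  expect_equal(nrow(empty), 0L)
  expect_error(hypergeometric_enrichment(c("g1", "zz"), genes, ann), "zz")
})

test_that("delta_delta_ct follows the Livak convention", {
  ct <- data.frame(sample = rep(c("cal", "s1"), each = 2),
                   replicate = c(1, 2, 1, 2),
                   ct_target = c(22, 22, 20, 20),
                   ct_reference = c(20, 20, 20, 20))
  rel <- delta_delta_ct(ct, "cal")
  expect_equal(rel$fold_change[rel$sample == "cal"], 1)
  expect_equal(rel$ddct[rel$sample == "s1"], -2)
  expect_equal(rel$fold_change[rel$sample == "s1"], 4)
  # invariance to a global Ct shift (both target and reference)
  ct2 <- ct; ct2$ct_target <- ct2$ct_target + 5
  ct2$ct_reference <- ct2$ct_reference + 5
  expect_equal(delta_delta_ct(ct2, "cal")$fold_change, rel$fold_change)
  bad <- ct; bad$ct_reference[3] <- NA
  expect_error(delta_delta_ct(bad, "cal"), "row")
  expect_error(delta_delta_ct(ct, "nope"), "calibrator")
})

test_that("lsd_groups reproduces a hand-computed LSD grouping", {
  # 3 groups, means 10 / 10.1 / 20, within-group sd 0.1, n = 3
  vals <- list(a = c(10.0, 10.1, 9.9), b = c(10.2, 10.1, 10.0),
               c = c(20.0, 20.1, 19.9))
  # hand computation: MSE = pooled within-group variance, df_err = 6
  mse <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 1)) / 6
  lsd <- qt(0.975, 6) * sqrt(mse * (2 / 3))
  expect_lt(abs(mean(vals$a) - mean(vals$b)), lsd)   # a,b share a letter
  expect_gt(abs(mean(vals$c) - mean(vals$a)), lsd)   # c differs
  res <- lsd_groups(vals)
  expect_equal(res$group, c("c", "b", "a"))  # descending means
  expect_equal(res$letters[res$group == "c"], "a")
  expect_equal(res$letters[res$group == "a"],
               res$letters[res$group == "b"])
  expect_false(res$letters[res$group == "c"] %in%
               res$letters[res$group %in% c("a", "b")])
})

test_that("identical groups share one letter; letters cover non-significance", {
  same <- lsd_groups(list(a = c(5, 5, 5), b = c(5, 5, 5), c = c(5, 5, 5)))
  expect_true(all(same$letters == "a"))
  # property: any two groups sharing a letter are not significantly
  # different under the pairwise LSD test
  set.seed(44)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    vals <- lapply(seq_len(k), function(i)
      rnorm(3, mean = sample(c(0, 1, 5), 1), sd = 0.5))
    names(vals) <- letters[seq_len(k)]
    res <- lsd_groups(vals)
    dat <- data.frame(g = factor(rep(names(vals), lengths(vals))),
                      v = unlist(vals))
    fit <- aov(v ~ g, dat)
    mse <- deviance(fit) / df.residual(fit)
    tc <- qt(0.975, df.residual(fit))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      gi <- res$group[i]; gj <- res$group[j]
      share <- any(strsplit(res$letters[i], "")[[1]] %in%
                   strsplit(res$letters[j], "")[[1]])
      sig <- abs(mean(vals[[gi]]) - mean(vals[[gj]])) >
        tc * sqrt(mse * (1 / 3 + 1 / 3))
      if (share) expect_false(sig)
      if (!sig) expect_true(share)
    }
  }
  expect_error(lsd_groups(list(a = 1:3)), "two groups")
  expect_error(lsd_groups(list(a = 1, b = 2)), "replicates")
})
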