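# Independent oracles used to cross-check package computations.

# Textbook Welch two-sample t-test, coded from the formulas
# (Welch-Satterthwaite df), independent of stats::t.test.
welch_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# n-subsets of a background of size N whose first K genes are annotated.
# Feasible for N <= 12.
hyper_enum_oracle <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

random_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# genotype-mean TPM per miRNA from a triad simulation, for D/A recovery
triad_mean_tpm <- function(sim) {
  tpm <- tpm_normalize(sim$counts)
  d <- sim$design
  m <- function(role)
    rowMeans(tpm[sim$truth$mirna, d$sample[d$role == role], drop = FALSE])
  data.frame(mirna = sim$truth$mirna, f1 = m("hybrid"), p1 = m("maternal"),
             p2 = m("paternal"), stringsAsFactors = FALSE)
}

# distance of a D/A value from the nearest class boundary
boundary_distance <- function(da) {
  apply(abs(outer(da, c(-2, -0.5, 0.5, 2), "-")), 1, min)
}
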