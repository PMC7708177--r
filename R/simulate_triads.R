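#' Configuration for the triad count simulator
#'
#' Validates and assembles the parameters of [simulate_triads()].
#'
#' @param n_mirnas Number of miRNAs to simulate.
#' @param n_replicates Replicates per genotype (>= 2; default 3, the
#'   study design for small RNA libraries).
#' @param class_mix Named proportions over the five inheritance classes
#'   `++`, `+`, `+-`, `-`, `--`; must sum to 1 (default uniform).
#' @param parent_mean_range Pair (low, high) of positive TPM-scale means
#'   for the maternal parent; `low < high`.
#' @param parent_divergence Multiplicative factor (> 1) separating the two
#'   parental means; each miRNA's paternal mean is the maternal mean times
#'   or divided by this factor (random side). Must exceed 1 so the D/A
#'   denominator is defined for every planted miRNA.
#' @param dispersion Overdispersion alpha of the count model
#'   (var = (1 + alpha) * mu); 0 gives the deterministic noise-free limit.
#' @param library_size Total reads per sample used to scale TPM means to
#'   expected counts.
#' @param seed Integer RNG seed.
#' @return A list of class `triad_sim_config`.
#' @export
triad_sim_config <- function(n_mirnas,
                             n_replicates = 3,
                             class_mix = c("++" = 0.2, "+" = 0.2,
                                           "+-" = 0.2, "-" = 0.2,
                                           "--" = 0.2),
                             parent_mean_range = c(50, 500),
                             parent_divergence = 2,
                             dispersion = 0.05,
                             library_size = 2e6,
                             seed = 1L) {
  if (!is.numeric(n_mirnas) || n_mirnas < 1)
    stop("n_mirnas must be a positive integer")
  if (n_replicates < 2)
    stop("n_replicates must be >= 2 (a downstream t-test needs replicates)")
  classes <- c("++", "+", "+-", "-", "--")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% classes))
    stop("class_mix must be named with the five classes ",
         paste(classes, collapse = " "))
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1 (got ", sum(class_mix), ")")
  if (any(class_mix < 0)) stop("class_mix proportions must be non-negative")
  if (length(parent_mean_range) != 2 || any(parent_mean_range <= 0) ||
      parent_mean_range[1] >= parent_mean_range[2])
    stop("parent_mean_range must be positive with low < high")
  if (parent_divergence <= 1)
    stop("parent_divergence must be > 1 (equal parents make D/A undefined)")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (library_size < 1) stop("library_size must be a positive integer")
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_replicates = as.integer(n_replicates),
                 class_mix = class_mix[classes[classes %in% names(class_mix)]],
                 parent_mean_range = parent_mean_range,
                 parent_divergence = parent_divergence,
                 dispersion = dispersion,
                 library_size = library_size,
                 seed = as.integer(seed)),
            class = "triad_sim_config")
}

# Draw a planted D/A inside a class interval, truncated at +/-6 and, for
# the "--" class, additionally above 98% of the value at which the F1 mean
# would hit zero (F1 = MP + da * (HP - MP) must stay positive).
.sample_da <- function(class, mp, hp) {
  lo_floor <- -mp / (hp - mp) * 0.98
  switch(class,
    "++" = stats::runif(1, 2, 6),
    "+"  = stats::runif(1, 0.5, 2),
    "+-" = stats::runif(1, -0.5, 0.5),
    "-"  = stats::runif(1, max(-2, lo_floor), -0.5),
    "--" = stats::runif(1, max(-6, lo_floor), -2),
    stop("unknown class ", class))
}

# NB1 count draw: var = (1 + alpha) * mu, i.e. rnbinom size = mu / alpha,
# vectorized over mu. dispersion 0 returns the exact expectation (possibly
# fractional) so the noise-free limit is exact.
.draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) return(mu)
  out <- numeric(length(mu))
  pos <- mu > 0
  out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                             size = mu[pos] / dispersion)
  out
}

#' Simulate miRNA counts for a maternal/paternal/F1 triad with planted truth
#'
#' Plants, for each miRNA, parental TPM-scale means, an inheritance class
#' drawn from `class_mix`, and a D/A value uniform within that class's
#' interval (truncated at +/-6); the hybrid mean is then
#' `MP + D/A * (HP - MP)` exactly. Counts are drawn per replicate from a
#' negative binomial with variance `(1 + dispersion) * mu`
#' (`dispersion = 0` gives exact expected counts). One extra `background`
#' row per matrix absorbs the remainder of the 1e6 TPM budget of each
#' genotype so that TPM renormalization returns the planted means exactly.
#'
#' @param config A [triad_sim_config()].
#' @param triad_id Triad label used in the design table (default
#'   `"triad1"`); genotype groups are named `<triad_id>_P1/_P2/_F1`.
#' @return List of class `triad_sim`: `counts` (matrix, one column per
#'   replicate per genotype plus a `background` row), `design` (data
#'   frame: `group`, `role`, `triad`, `sample`), `truth` (data frame:
#'   `mirna`, `p1_mean`, `p2_mean`, `f1_mean`, `da`, `class`).
#' @examples
#' sim <- simulate_triads(triad_sim_config(20, dispersion = 0, seed = 7))
#' head(sim$truth)
#' @export
simulate_triads <- function(config, triad_id = "triad1") {
  if (!inherits(config, "triad_sim_config"))
    stop("config must be built with triad_sim_config()")
  set.seed(config$seed)
  n <- config$n_mirnas
  p1 <- stats::runif(n, config$parent_mean_range[1],
                     config$parent_mean_range[2])
  side <- sample(c(-1, 1), n, replace = TRUE)
  p2 <- p1 * config$parent_divergence^side
  mp <- (p1 + p2) / 2
  hp <- pmax(p1, p2)
  cls <- sample(names(config$class_mix), n, replace = TRUE,
                prob = config$class_mix)
  da <- vapply(seq_len(n), function(i) .sample_da(cls[i], mp[i], hp[i]),
               numeric(1))
  f1 <- mp + da * (hp - mp)
  mirnas <- sprintf("mir%04d", seq_len(n))
  truth <- data.frame(mirna = mirnas, p1_mean = p1, p2_mean = p2,
                      f1_mean = f1, da = da, class = cls,
                      stringsAsFactors = FALSE)

  genotype_means <- list(P1 = p1, P2 = p2, F1 = f1)
  budget <- vapply(genotype_means, sum, numeric(1))
  if (any(budget >= 0.95e6))
    stop("planted TPM means exceed the per-sample budget; ",
         "lower parent_mean_range or n_mirnas")
  roles <- c(P1 = "maternal", P2 = "paternal", F1 = "hybrid")
  cols <- list(); design <- NULL
  for (g in names(genotype_means)) {
    mu_tpm <- c(genotype_means[[g]], 1e6 - budget[[g]])  # background filler
    mu_counts <- mu_tpm / 1e6 * config$library_size
    for (r in seq_len(config$n_replicates)) {
      samp <- sprintf("%s_%s_rep%d", triad_id, g, r)
      cols[[samp]] <- .draw_counts(mu_counts, config$dispersion)
      design <- rbind(design, data.frame(
        group = sprintf("%s_%s", triad_id, g), role = unname(roles[g]),
        triad = triad_id, sample = samp, stringsAsFactors = FALSE))
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- c(mirnas, "background")
  structure(list(counts = counts, design = design, truth = truth),
            class = "triad_sim")
}
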