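---
title: "Methods: miRNA inheritance classification in hybrid/parent triads"
author: "heteromir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA inheritance classification in hybrid/parent triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteromir)
```

## The question and the statistic

Heterosis is the superior performance of an F1 hybrid over its inbred
parents. At the expression level it shows up as *non-additive*
inheritance: a transcript whose hybrid abundance departs from the
mid-parent value. For a miRNA with mean expression `F1` in the hybrid and
`P1`, `P2` in the parents (all on the TPM scale), define the mid-parent
`MP = (P1 + P2)/2` and the high parent `HP = max(P1, P2)`. The
dominance/additivity ratio

$$ D/A = \frac{F1 - MP}{HP - MP} $$

scales the dominance deviation by the additive half-range, so `0` is
perfectly additive, `1` is exact high-parent dominance, `-1` exact
low-parent dominance, and values beyond the parental range (|D/A| > 1)
indicate over- or under-dominance. Five inheritance modes are assigned by
interval:

| category | meaning | interval |
|---|---|---|
| `++` | extremely high-parental | D/A > 2 |
| `+`  | high-parental | 0.5 < D/A <= 2 |
| `+-` | additive | -0.5 <= D/A <= 0.5 |
| `-`  | low-parental | -2 <= D/A < -0.5 |
| `--` | extremely low-parental | D/A < -2 |

The published interval scheme is open at the cut points and therefore
leaves D/A values of exactly +/-0.5 or +/-2 unassigned; `classify_da()`
assigns boundaries to the *less extreme* class so the map is total and
deterministic. No reference value in the shipped tables lies on a
boundary, so this choice does not affect concordance with them. A miRNA
with D/A > 0 is called *induced* in the hybrid, D/A < 0 *repressed*;
exactly 0 is "neutral" and excluded from both tallies (the published
definitions use strict inequalities). Repressed percentages are rounded
half-up to an integer, which reproduces the published 60/54/54/55 values
from 25/42, 27/50, 21/39 and 26/47.

When `P1 = P2` the half-range vanishes and D/A is undefined;
`compute_da()` returns `NA` when `HP - MP < 1e-9 * max(1, HP)`, a
relative tolerance chosen to avoid catastrophic division when parents are
effectively equal on the TPM scale.

D/A is computed from replicate-mean TPM per genotype, not averaged over
per-replicate ratios — the classification is "by expression abundance".

## Which miRNAs get classified: the scaled set

Only miRNAs differentially expressed between the hybrid and at least one
parent are classified ("scaled" miRNAs). `differential_test()` applies a
two-sided two-sample t-test to the replicate TPM values of each miRNA
and filters at raw `P < 0.01` and `|log2FC| > 1`, where the fold change
compares group means with a pseudocount:
`log2FC = log2(mean_hybrid + c) - log2(mean_parent + c)`, `c = 1` TPM by
default. Choices worth stating:

* **Welch by default.** The procedure specifies only "a t-test"; the
  unequal-variance form is the safer default and `var_equal = TRUE`
  selects the pooled-variance Student form.
* **No multiple-testing correction by default.** The published filter is
  on the raw P-value; `adjust = "BH"` is available for users who want
  FDR control.
* **Pseudocount 1 TPM** handles zero means; at `c = 0` the log2FC is
  exactly scale invariant, and the t-test p-value is scale invariant for
  any `c` (the statistic is scale free).
* **Degenerate variances.** Two groups with zero variance and equal
  means give `p = 1` by convention; zero variance with different means
  gives `p = 0` (at zero within-group variance the difference is
  certain). This keeps the filter total on constant rows.
* **TPM denominator** is the total miRNA-assigned count of the sample.

The two per-parent DE sets are combined by `scaled_union()`; the union,
not the intersection, is classified — a miRNA deviating from even one
parent is informative about inheritance.

## The synthetic study

`simulate_triads()` generates the full planted-truth study the tests and
acceptance checks run on. Per miRNA: a maternal mean is drawn uniformly
from `parent_mean_range` (default 50-500 TPM; the recovery analyses use
100-800 TPM so that every parent clears 100 TPM), the paternal mean is
the maternal mean times or divided by `parent_divergence` (default 2;
equal parents are excluded because their D/A is undefined), a class is
drawn from `class_mix` (default uniform over the five modes), and a D/A
value is drawn uniformly inside that class's interval truncated at
+/-6. The F1 mean is then set to `MP + D/A * (HP - MP)` *exactly*, so the
truth table satisfies the classifier's own identity. For the `--` class
the lower truncation is additionally raised to 98% of the D/A at which
the F1 mean would reach zero (with divergence 2 that limit is -3);
extremely low-parental truth therefore lives in roughly (-2.9, -2),
closer to the -2 boundary than the +/-6 truncation suggests.

**Noise model.** Counts are negative binomial with
`var = (1 + dispersion) * mu` (`rnbinom` with `size = mu/dispersion`),
i.e. mild extra-Poisson noise whose coefficient of variation falls as
`sqrt((1 + dispersion)/mu)`. The default `dispersion = 0.05` emulates
tightly reproducible small-RNA libraries in which abundant miRNAs vary a
few percent between replicates. This is deliberately lighter-tailed than
the mean-squared overdispersion (`var = mu + phi * mu^2`) that count
models such as edgeR/DESeq2 estimate for biological replicates of field
material, where the biological CV floor is typically ~20% or more.
Consequences are stated honestly: under this generator, D/A class
recovery for miRNAs at least 0.25 from every class boundary exceeds 95%
and the DE filter reaches power ~1 on 4x changes at 100+ TPM with three
replicates; under a BCV ~ 0.2 noise floor those figures would drop
substantially (the D/A sampling error alone approaches +/-0.4). Passing
the synthetic recovery checks therefore demonstrates correctness of the
computations, not that three replicates suffice for noisy field data.

**Exact noise-free limit.** At `dispersion = 0` the generator emits the
exact expected counts without rounding (fractional counts are accepted
throughout). Rounding to integers would already introduce ~1e-3 relative
error at 100 TPM and break the exact round trip; with exact expectations,
`simulate_triads -> tpm_normalize -> compute_da` returns every planted
D/A to < 1e-9 and every planted class exactly.

**TPM budget row.** TPM renormalization divides by the per-sample total,
so a genotype whose planted means sum differently from the others would
have all its TPM values rescaled and the planted D/A distorted. Each
simulated matrix therefore carries one extra `background` row absorbing
the remainder of the 1e6 TPM budget of each genotype, which makes TPM of
the planted rows equal the planted means exactly. The background row is
not part of the truth table and is classified like any other row
downstream (it rarely passes the DE filter).

Companion generators follow the same planted-truth pattern:
`simulate_srna_reads()` lays out one synthetic chromosome with a 2-kb
block per feature type and places reads by drawn class and length (the
defaults used in the analysis scripts peak at 21 and 24 nt, the canonical
plant sRNA modes); `simulate_degradome_library()` emits reads whose 5'
ends sit exactly at planted cleavage positions plus uniform Poisson
background on the sense strand; `simulate_qpcr_cts()` is the exact
inverse of the 2^-ddCt computation with optional Gaussian Ct noise. All
generators are seed-deterministic.

## Read profiling

`annotate_read_classes()` assigns each read exactly one class. Overlap
precedence is miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > exon >
intron > unannotated: structural RNA annotations win over genic context,
which the flat published categories do not specify but a reproducible
pipeline must fix. Exon and intron assignments split into sense/antisense
by strand agreement. Internally coordinates are 0-based half-open; GFF3
is read/written 1-based inclusive, BED-style inputs 0-based half-open.

`match_known_mirnas()` counts reads of 18-25 nt that match a mature
reference sequence *exactly over the full mature length* after U->T
normalization. No mismatches are allowed — the reference procedure states
no mismatch tolerance, and exact matching keeps fixtures bit-reproducible.
Reads matching several identical mature sequences count toward each ID,
flagged as multi-hits.

## Degradome cleavage-site calling

The caller re-implements the standard plant degradome logic (the
reference analysis used CleaveLand 3.0, whose scoring parameters are not
printed; all three knobs here are arguments):

1. `map_degradome_reads()` matches each read's 20-nt prefix exactly
   against the sense strand of every transcript and increments the 5'-end
   count at the match start. Multi-hits increment each hit and are
   tallied separately, so profile mass equals mapped reads.
2. `score_duplex()` scores the ungapped antiparallel duplex: miRNA
   position *i* pairs with window position *L - i + 1*; Watson-Crick 0,
   G:U wobble 0.5, mismatch 1, penalties doubled at miRNA positions 2-13
   (the seed-through-cleavage core). Gapped/bulged duplexes are out of
   scope and such targets will be missed — a stated limitation.
3. `call_cleavage_sites()` slides each miRNA over every window
   (exhaustive; fine at desk scale), keeps windows scoring <= 7 by
   default, and tests the transcript base paired to miRNA position 10 —
   canonical AGO slicing occurs between the bases paired to positions
   10 and 11.

Abundance categories rank the candidate against its transcript's profile:
0 = unique maximum, 1 = tied maximum, 2 = above the median of nonzero
positions, 3 = at or below that median (count > 1), 4 = a single read. A
single raw read is always category 4, *even when it is the transcript's
unique maximum*: on sparse background a lone chance read would otherwise
be promoted to category 0, and the false-positive guarantee of the
planted-site checks (no spurious category-0 calls at background rate
0.01/nt over 20 libraries) depends on this rule, which follows CleaveLand
convention.

## Enrichment and qPCR verification

`hypergeometric_enrichment()` computes the upper-tail probability
`P(X >= k)` per term from a user-supplied gene-to-term map (no live
ontology download; term hierarchy propagation is out of scope) and flags
terms at raw `p < 0.05` by default. The test is validated against
exhaustive subset enumeration for backgrounds up to 12 genes.

`delta_delta_ct()` follows the Livak convention: per-replicate
`dCt = Ct_target - Ct_reference`, averaged per sample, then differenced
against the calibrator and exponentiated (`2^-ddCt`, efficiency 2).
Averaging dCt before differencing (rather than averaging per-replicate
folds) matters: the two orders differ under noise, and only the former
makes the calibrator's fold exactly 1. The computation is invariant to
any global Ct shift.

`lsd_groups()` fits a one-way ANOVA, computes pairwise least significant
differences `t(1-alpha/2, df_err) * sqrt(MSE (1/n_i + 1/n_j))`, and
assigns compact letters by descending mean: each maximal run of mutually
non-significant groups gets one letter. With equal group sizes
non-significance is interval-consistent in the ordered means, so two
groups share a letter exactly when they are not significantly different.

## Problem sizes and numerical choices

The shipped checks use deliberately desk-scale designs chosen to make the
statistical assertions sharp rather than slow: 1000 miRNAs x 3 replicates
for class recovery and DE size/power (binomial 3-SD bands at n = 1000),
20 degradome libraries of two 500-nt transcripts for the false-positive
sweep, and enumeration backgrounds of at most 12 genes for the
hypergeometric oracle. All random stages take explicit integer seeds and
are bit-reproducible; the analysis drivers under `analysis/` fix their
seeds at the top of each script.

Known limitations, summarized: the noise model understates biological
replicate variance (see above); duplexes are ungapped; no novel-miRNA
hairpin prediction, adapter trimming, or read alignment is included
(placements come from the generator or the user); the enrichment
background must be supplied by the user, as the reference procedure does
not state its own.
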