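---
title: "Region-level differential methylation for targeted bisulfite capture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level differential methylation for targeted bisulfite capture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdmr)
```

## Scope and model

methdmr analyses targeted bisulfite capture methylation data at the
level of predefined genomic regions (capture-manifest targets), the
setting of comparative methylome studies of pituitary adenomas that
contrast nonfunctioning tumours (NFPAs) with GH-secreting tumours
(GH-omas), alongside normal pituitary tissue. The analysis unit is a
region's *beta value*

$$\beta_{ij} = \frac{m_{ij}}{t_{ij}},$$

the ratio of methylated to total aligned reads for region $i$ in sample
$j$, after collapsing cytosine-level counts into the region
(`collapse_to_regions()`, 0-based half-open intervals). A cell with
$t_{ij} = 0$ is *undefined*, never 0. Before testing, only regions
covered in **every** sample of both tumour groups are retained
(`filter_covered_regions()`); "covered" means total reads at or above
`min_total`, default 1, because the source protocol states the
all-sample rule but no depth threshold.

The differential caller (`call_dmrs()`) computes per region the group
mean betas $\bar\beta^{NFPA}_i$, $\bar\beta^{GH}_i$, the log2 fold
enrichment

$$\mathrm{LFC}_i = \log_2
  \frac{\bar\beta^{NFPA}_i + \epsilon}{\bar\beta^{GH}_i + \epsilon},
  \qquad \epsilon = 10^{-6},$$

a two-sided two-sample t-test across samples, and Bonferroni-adjusted
p-values $p^{adj}_i = \min(1, m\,p_i)$ with $m$ the number of tested
(post-filter) regions. A region is a DMR iff $p^{adj}_i \le 0.05$ and
$|\mathrm{LFC}_i| > 0.5$ (strict); DMRs with $|\mathrm{LFC}| > 2$ are
H-DMRs, the remaining DMRs L-DMRs, so H and L partition the significant
set.

### Design choices in the caller

* **Welch by default.** The protocol says only "t-test". The Welch
  variant reproduces the reference cohort's printed age p-value (0.36)
  and is the safer default for unequal group variances; the pooled
  Student variant is available via `dmr_config(test_variant =
  "student")`.
* **Significance at `p_adj <= alpha`.** The source text uses "less
  than" in one place and "$\le$" in another; the difference is
  immaterial at float precision and the inclusive form is implemented.
* **H/L as a partition.** A literal reading of "LFC between 2 and -2"
  for L-DMRs would include sub-threshold regions; the published counts
  (111 + 67 = 178) only add up if H and L partition the significant
  set, which is the reading implemented.
* **Raw betas are tested.** Whether the original test ran on betas or a
  variance-stabilised transform (M-values) is unstated; betas are used
  as written. The caller is deliberately unmoderated (no shrinkage
  variance estimators, no merging of adjacent regions) to stay faithful
  to the described procedure.
* **$\epsilon$ symmetric at $10^{-6}$** keeps the LFC defined for zero
  means; label-swap antisymmetry of the LFC then holds only up to
  $O(\epsilon/\bar\beta)$, which the tests acknowledge.

## Annotation

CpG-centric context (`build_context_map()`, `annotate_cpg_context()`)
uses the standard array-manifest convention, which the source names but
never defines: shores are the 2 kb flanks of an island, shelves the
next 2 kb, everything farther open sea; N marks the lower-coordinate
flank and S the higher-coordinate flank, independent of strand. The map
is a true partition of each chromosome: where flanks of adjacent
islands would collide, each base goes to the nearer island's context,
ties to the lower-coordinate island. A region spanning several contexts
receives a single label by priority island > shore > shelf > open sea,
then larger overlap, then N before S — regions can be kilobases long,
and one label per region is required downstream.

Genic annotation (`annotate_genic()`) is a simplified ANNOVAR-style
precedence scheme over gene models with exons and an optional CDS span:
CDS-exonic > UTR5/UTR3 > noncoding-exonic > intronic > upstream /
downstream (1 kb strand-aware windows) > intergenic, with nearest gene
and non-negative distance (0 iff overlapping). `classify_coding()`
calls a region CODING only on CDS-exonic overlap, reproducing the
coding/noncoding dichotomy without transcript-isoform arbitration. No
splicing category and no isoform handling are attempted. Both
annotators are verified against per-base / per-category brute-force
oracles on randomized genomes.

## Group-level contrasts

`compare_global()` and `compare_by_context()` pool every defined
per-region per-sample beta within each group — the distribution-level
view used for "global methylation" boxplots; per-region group means are
the pooling unit only for the DMR-restricted strata
(`compare_dmr_strata()`), matching the reading that the published
coding/noncoding medians (0.83/0.25) describe DMR regions. Two-sided
Mann-Whitney tests are used: exact when $n_a n_b \le 400$ with no ties,
otherwise the tie- and continuity-corrected normal approximation. For
tied samples this approximation can deviate from the exact permutation
distribution by up to ~0.15 at $n \approx 5$; the test suite asserts
exact agreement with full enumeration for tie-free small samples and
closeness under ties. Published medians (0.68/0.48 etc.) are
data-bound descriptive values, not reproduction targets.

## The synthetic-data generator

The generator emulates the *structure* of a targeted capture
experiment, not its sequences:

* **Region geometry.** Lengths are log-normal truncated to [2, 8131] bp
  with the truncated mean calibrated to 245 bp — the three moments the
  protocol states. The desk-scale default is 5,000 regions (437,792 is
  supported but flagged); two 5 Mb chromosomes host 150 islands of 500
  bp spaced at least 8 kb so shores and shelves never collide, and 100
  gene models (30% noncoding).
* **Counts.** Totals are negative binomial (mean 100, size 10);
  methylated counts are beta-binomial around the region's group mean
  with a single concentration $\theta = 20$ per run — the standard
  overdispersion model for bisulfite counts; the source gives no noise
  model. $\theta = 20$ makes the per-sample beta SD at $\mu = 0.5$
  about 0.11, a plausible inter-tumour spread.
* **Baselines.** Context-dependent means (island 0.04, shores 0.45,
  shelves 0.58, open sea 0.55) reproduce the *ordering* of the
  published per-context medians — islands low, open sea high. The
  per-context variances are unstated in the source, so only the
  ordering, not the printed values, is calibrated. Region-level logit
  jitter (SD 0.3) avoids identical regions.
* **Group effect.** NFPA means are shifted on the logit scale
  (`group_shift`, default 0.8 = logit(0.68) − logit(0.48), the gap of
  the published global medians), which keeps means inside (0,1) at any
  shift. Normal-pituitary samples are generated at baseline and
  excluded from differential testing, mirroring the tumour-vs-tumour
  contrast.
* **Planted DMRs.** A `dmr_fraction` of regions (default 5%) gets a
  target NFPA/GH mean ratio of $2^{\pm\mathrm{planted\_lfc}}$ (default
  ±2; 90% hyper), clamped into (0.005, 0.995) — equivalently a
  logit-scale move of exactly the size achieving that ratio. The truth
  table records the *achieved* post-clamp LFC, so recovery tests never
  assume an unattainable effect.

A green recovery test therefore establishes that the caller finds
two-group mean differences of the stated size under beta-binomial noise
at coverage 100 — not that it would reproduce the published DMR list,
which depends on the real inter-tumour covariance structure, capture
efficiency and genome annotation that the generator does not model
(no read-level simulation, no bisulfite-conversion errors, no
alignment).

The cohort generator emits per-patient clinical records with the
published table's schema, including censored Ki-67 entries ("<1") and
missing values; `mode = "table1"` returns the packaged 21-patient
reference table verbatim. With `effects = TRUE` (default) NFPAs are
drawn larger and more invasive, as in surgical series; `effects =
FALSE` gives a null cohort for calibration checks.

## Cohort statistics

`cohort_summary()` reproduces the reference table's machinery: standard
median and $n-1$ SD per group, Welch t for continuous variables, Yates
chi-square $\chi^2 = n(\,|ad-bc| - n/2)^2 / (r_1 r_2 c_1 c_2)$ for 2×2
tables with the correction floored at zero. Censored "<1" entries are
**excluded** from medians/SDs by default — the policy that uniquely
reproduces the printed Ki-67 median 2 / SD 1.81 — with
`substitute` (half the bound) as an option. Missing invasion entries
count as non-invasive so the fractions match the printed 2/11 and
4/10. p53 is summarised but not tested (no printed comparison exists).

Known irreproducibilities, verified by recomputation from the
per-patient values and deliberately left out of the assertions: the GH
diameter median (prints 12, recomputes 13.5), the diameter SDs (5.60,
11.13) and the GH/NFPA surgery SDs (0.31, 0.70 vs recomputed 0.30,
0.67), which match neither the $n-1$ nor the $n$ convention — the
missing cells likely held unprinted values; and the sex p-value (0.78),
which none of Yates, uncorrected chi-square or Fisher reproduces on
4M/7F vs 4M/6F (the floored Yates statistic is 0, p = 1).

## Numerical and degenerate-input conventions

* Zero-variance t-tests: both groups constant and equal gives $t = 0,
  p = 1$; constant but different gives $p = 0$ with a warning.
* Undefined betas propagate as NA and are excluded sample-wise from
  group means; they cannot reach the caller (the coverage filter
  removes them), which refuses NA inputs.
* All generators draw through an isolated RNG stream derived from
  `config$seed` (caller RNG state restored), so fixed seed means
  bit-identical outputs, including written files.
* Ties in the DMR table ordering resolve by adjusted p, then |LFC|
  descending, then region id — deterministic output order.

## What the acceptance checks compute

The test suite's acceptance block (i) plants |LFC| = 2 effects on 5% of
2,000 regions (10 vs 10 samples, coverage 100) and requires sensitivity
at least 0.9 with every recovered direction correct, plus familywise
error control over 20 null seeds; (ii) checks the annotators against
per-base/per-category brute-force scans on 20 randomized 100-kb
genomes, the Mann-Whitney p against exhaustive permutation enumeration
for all tie-free sample sizes up to 6, and the collapse against an
$O(nm)$ membership scan; (iii) verifies the threshold-logic properties
(H/L partition, label-swap antisymmetry, Bonferroni monotonicity); and
(iv) recomputes the reference cohort statistics from the packaged
table. `scripts/acceptance.R` replays the whole pipeline and the cohort
summary from scratch under a caller-supplied seed.

## Worked example

```{r example, eval = FALSE}
library(methdmr)
sim <- sim_config(n_regions = 2000, seed = 1)
res <- run_pipeline(out_dir = "run1", sim = sim)
res$manifest$funnel
res$comparisons$global
cohort_summary(cohort_table1())
```

## Limitations

The simulator's independence across regions understates the spatial
correlation of real methylomes; the t-test on betas ignores the
mean-variance relationship a beta-binomial regression would model; the
genic annotator is single-isoform; and the published headline numbers
(178 DMRs, 111 H / 67 L, the per-context medians, 92.7% noncoding)
require the original ~30-sample capture dataset and its annotation
database, so they are covered here by property-based checks rather than
numeric reproduction.
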