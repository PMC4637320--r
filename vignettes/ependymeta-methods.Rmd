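---
title: "Methods: multi-cohort ependymoma expression meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort ependymoma expression meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ependymeta` combines several normalized expression cohorts of spinal
(SEPN) versus intracranial ependymoma into a single analysis. This
vignette is the package's account of the statistical machinery: the models
and their assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## Input model and preprocessing

Each cohort is a genes × samples matrix of normalized log2 expression with
a two-level label per sample (`spinal` / `intracranial`). The pipeline
deliberately starts *after* platform-level normalization (RMA and
friends): array processing is platform-specific and better served by the
platform's own tooling. Three filters precede the meta-analysis:

* **Missing-value filter.** A gene is dropped when *strictly more than*
  `max_missing_frac` (default 0.30) of its samples are missing; a gene at
  exactly the threshold is kept. Missingness is assumed unrelated to
  expression level (see the generator section).
* **Probe collapse.** When several probes map to one gene, the probe with
  the highest mean over its non-missing samples is kept. Ties — rare but
  possible with duplicated probes — go to the lexicographically smallest
  probe id, so the result is deterministic.
* **Common universe.** Both combination methods require each gene in every
  cohort, so analysis runs on the sorted intersection of the cohorts' gene
  lists. Intersecting *after* per-study filtering is a choice, not a
  necessity; the alternative (intersect first) changes which genes survive
  the missingness filter only when missingness differs strongly between
  cohorts.

Gene identifiers are opaque strings throughout: mapping between platform
identifier spaces (symbol, Entrez, probeset) is upstream of this package.

## Two routes to differential expression

**Route 1 — pooled effect sizes.** Per cohort, Hedges' adjusted g
(spinal − intracranial, so positive means up in spinal) with the
small-sample correction J = 1 − 3/(4·df − 1) and the large-sample variance
v = (n₁+n₀)/(n₁n₀) + g²/(2(n₁+n₀)). Cohorts are pooled with the
DerSimonian–Laird (DL) moment estimator of between-study variance τ²; the
pooled effect over weights 1/(vᵢ+τ²) is tested as z = ES/SE against a
standard normal, two-sided.

**Route 2 — combined p-values.** Per cohort, a moderated t-statistic:
per-gene pooled variances s²_g (df d_g = n₁+n₀−2, computed over non-missing
samples) are shrunk toward a scaled-F prior (d₀, s₀²) fitted by
moment-matching the log-variances — the mean and variance of
log s² − ψ(d_g/2) + log(d_g/2) identify (d₀, s₀²) through the digamma and
trigamma functions, with the trigamma inverted by Newton iteration
(relative tolerance 1e−10). The posterior variance
(d₀s₀² + d_g s²_g)/(d₀+d_g) enters an ordinary two-sample t with d₀+d_g
degrees of freedom. Per-gene p-values are combined across cohorts with
Fisher's sum of logs, −2Σln pᵢ ~ χ²(2k).

Both routes are BH-corrected over the full universe, separately, and the
**consensus** takes genes with FDR < `alpha` (default 0.05) in both. Genes
that fail in any cohort (constant expression, too few non-missing values)
are reported as `NA` rows and excluded from both FDR vectors rather than
silently dropped.

Choices worth flagging:

* All p-values are two-sided; there is no one-sided option. The two routes
  therefore agree on significance, and the effect-size sign carries
  direction.
* A p-value of exactly zero entering Fisher's method is clamped to the
  smallest positive double with a warning; propagating −∞ would poison the
  combined statistic.
* When the observed dispersion of log-variances falls below its expected
  sampling floor (the mean trigamma term), the prior fit returns d₀ = ∞
  and every posterior variance equals s₀² — the total-shrinkage branch.
* `d0 = 0` is accepted as an override and reproduces the ordinary pooled
  t exactly, which the test suite uses as a limit check; the default fit
  is also verified against an independent variance-shrinkage
  implementation (limma) to machine precision.

**Known limitation.** With only k = 3 cohorts the DL z-test is
conservative under the global null: τ² is estimated with large noise
(τ̂² > 0 for roughly a third of null genes, as expected for a χ²₂-distributed
Q exceeding k−1), which inflates the SE and compresses the z-statistics.
The calibration checks in the test suite compute this directly: route-2
p-values are uniform under the null, route-1 p-values lean conservative
(too few small values — the direction that costs power, not validity), and
the consensus under the null stays empty. Users wanting exact route-1
calibration at k = 3 would need a different SE treatment
(e.g. Hartung–Knapp), which is out of scope here because the consensus
with route 2 already guards the error rate.

## Target-gene co-expression meta-analysis

Per cohort, Pearson correlations between the target (by default the
*NF2* analog) and every other gene over pairwise-complete samples; pairs
with fewer than 4 complete observations are dropped because the Fisher-z
variance 1/(n−3) requires n > 3, and constant vectors yield `NA` rather
than an error. Correlations are pooled on the z scale (atanh) with the same
DL estimator, back-transformed with tanh, and selected at
`r_pooled > r_min` (default 0.4) and FDR < 0.05, ranked by descending
pooled correlation with ties broken by gene id. Correlations of exactly ±1
(possible with duplicated rows) are clamped to ±(1 − 1e−12) with a
warning. The standard error is reported on both scales — `se_z` exactly,
and `se_r = se_z · (1 − r²)` by the delta method — because the two are
easily confused in published tables.

The physical-neighborhood report lists genes whose interval intersects
`[target_start − window, target_end + window)` (default window 500 kb,
half-open on the right like all internal coordinates), joined with the
differential-expression direction and the co-expression selection flag.

## Enrichment and positional structure

Over-representation uses the exact hypergeometric upper tail
(`phyper`) with BH correction across the sets actually testable in the
universe; the universe is the meta-analysis gene universe, not the genome,
because genes never measured cannot be drawn into a query. Cytoband sets
are built directly from the annotation (one set per band string).

The positional scan is a deliberate re-specification of positional
gene-enrichment tools whose internals are not public: candidate regions
are *all* genomic intervals delimited by two query genes on one chromosome
containing at least `min_genes` (default 5) universe genes; each is scored
hypergeometrically (k = query genes inside, K = universe genes inside);
BH runs across all candidates; and a greedy pass by ascending p (ties:
wider region first, then leftmost) keeps non-overlapping regions. This
construction is exact and testable — a planted contiguous block is
recovered with its exact gene extremes — but is not claimed identical to
any external tool. Coordinates are 0-based half-open internally; report
tables add 1-based inclusive columns.

The chromosome profile is a Nadaraya–Watson estimate with a Gaussian
kernel over gene midpoints (default bandwidth 2 Mb, evaluated on a 1-kb
rounded grid of 200 points): wide enough to show domain-scale suppression,
narrow enough not to flatten a 4-Mb block. Constant input gives a constant
curve; an infinite bandwidth tends to the global mean.

## PPI permutation prioritization

Seeds (down-regulated consensus genes on the block chromosome, hub
excluded) are scored by their direct links to other seeds. Significance
comes from degree-matched node permutations: nodes are binned by degree
deciles (`degree_bins = 10`), each permutation replaces every seed with a
node drawn without replacement from its bin, and the per-seed p-value is
the +1 pseudo-count estimator (1 + #{perm ≥ obs})/(n_perm + 1), so p is
never 0 and never below 1/(n_perm+1). A bin with fewer than twice its
seed count would make the draw degenerate (mostly re-selecting the seeds
themselves), so such bins are merged into their neighbor with a warning.
This degree-binned resampling is an approximation to exact
degree-preserving permutation — documented as such, with the bin count
configurable. The default 10,000 permutations give a p-value floor of
1/10,001, comfortably below the 0.05 ranking threshold.

Because the within-seed degree is a small count on sparse networks, its
permutation p-values are discrete; the test suite's null calibration
therefore uses a dense random graph (800 nodes, mean degree 150, 300
seeds) where the statistic is effectively continuous and the mean null p
sits near 0.5. On sparse graphs the +1 estimator with ties is
conservative, which again costs power rather than validity.

No multiple-testing correction is applied across seeds — prioritization
ranks by raw p < 0.05, matching how such candidate lists are used — and
the integration step joins the pooled co-expression columns onto
prioritized seeds, keeping seeds absent from the co-expression table with
`NA` columns rather than dropping them.

## The synthetic-cohort generator

`simulate_cohorts()` emulates the structure of a three-cohort ependymoma
compendium. Defaults are the study conditions: intracranial/spinal sizes
71/12, 85/19 and 65/10; 10% of genes differentially expressed at
|g| = 1.5 with an even sign split; a 40-gene contiguous block on the
chromosome-22 analog suppressed at g = −1.2 and containing the hub gene
(`NF2`); a 50-gene hub module at pairwise r = 0.6; an 8-gene PPI clique
among the block genes nearest the hub.

Expression for gene g, sample s of cohort j is

    x = shift_j + scale_j · (μ_g + δ + σ_g e),

with baseline μ_g ~ N(7, 1) (typical log2 microarray intensity), per-gene
noise σ²_g scaled-inverse-χ² with d₀ = 4 and s₀² = 0.25 (a realistic
spread of gene-level variances that also exercises the moderated-t prior
fit), δ = g_true·σ_g added to spinal samples so the *standardized* effect
equals g_true regardless of a gene's noise level, and module genes sharing
a per-sample latent factor, e = √r·f + √(1−r)·ε, which yields pairwise
correlation r in expectation. Per-cohort batch structure is an additive
shift and multiplicative scale ((0, 1), (0.4, 1.1), (−0.3, 0.9));
standardized effects are invariant to both, and that invariance is itself
a test. Cells are masked completely at random at per-cohort rates
(0, 0, 0.05) — only the third cohort's platform carries missing values in
the emulated design. Genes sit 100 kb apart in near-equal chunks across 22
chromosomes, with cytobands of 30 consecutive genes; the PPI is an
Erdős–Rényi graph (2,000 nodes, mean degree 6) with the planted clique.

What the generator does **not** emulate: probe-level artifacts, quantile
normalization residue, informative missingness, correlated background
structure beyond the single planted module, scale-free PPI topology, and
annotation errors. Passing tests on this generator therefore demonstrate
that the statistics recover the structure they model — not that real
cohorts satisfy that model.

## Problem sizes and reproducibility

The test suite and the acceptance script run the generator at 400–2,000
genes and 100–10,000 permutations — sizes chosen so each statistical claim
is measured at the scale where it is meaningful (null calibration at 2,000
genes, permutation calibration at 10,000 permutations) while the whole
suite stays interactive. The pipeline derives per-stage child seeds from
one global seed, so stages are individually reproducible and two runs with
the same configuration write byte-identical tables; every output TSV
carries a provenance header with the package version and the parameters
used.
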