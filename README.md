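# ependymeta

Multi-cohort gene-expression meta-analysis of spinal versus intracranial
ependymoma.

Spinal ependymomas (SEPN) are histologically similar to intracranial
ependymomas but biologically distinct, and individual expression studies of
the contrast are small (often ~10–20 spinal tumors against 65–85
intracranial ones). `ependymeta` is for computational biologists who want to
combine several such cohorts into one analysis: it pools per-cohort effect
sizes across studies, screens for genes co-expressed with a target tumor
suppressor (*NF2* on chromosome 22, the locus most frequently lost in
spinal tumors), locates chromosomal domains of suppressed transcription,
and prioritizes candidate genes by their protein–protein interaction (PPI)
connectivity. A synthetic three-cohort generator with planted ground truth
makes every stage testable end to end.

## Methods at a glance

**Differential expression, route 1 (effect sizes).** Per cohort and gene,
Hedges' adjusted g (spinal − intracranial):

    g = J (x̄₁ − x̄₀) / s_p,   J = 1 − 3 / (4(n₁+n₀−2) − 1)
    v = (n₁+n₀)/(n₁n₀) + g² / (2(n₁+n₀))

pooled across cohorts by DerSimonian–Laird random effects
(τ² = max(0, (Q − (k−1)) / (Σwᵢ − Σwᵢ²/Σwᵢ)), weights 1/(vᵢ+τ²)), tested
with z = ES/SE against N(0,1), and Benjamini–Hochberg corrected.

**Differential expression, route 2 (p-values).** Per cohort, an
empirical-Bayes moderated t-statistic (per-gene variances shrunk toward a
scaled-F prior fitted by moment-matching on log s²), combined across
cohorts with Fisher's sum of logs, X² = −2Σln pᵢ ~ χ²(2k), then BH
corrected. The consensus call requires FDR < 0.05 by **both** routes.

**Target-gene co-expression.** Per-cohort Pearson correlations with the
target are Fisher-z transformed (variance 1/(n−3)), pooled by
DerSimonian–Laird, back-transformed, and selected at r > 0.4 and
FDR < 0.05.

**Positional enrichment.** Hypergeometric over-representation of cytoband
gene sets; a positional scan that scores every query-gene-delimited genomic
interval hypergeometrically and greedily keeps non-overlapping regions; a
Gaussian-kernel (Nadaraya–Watson) expression profile along a chromosome.

**PPI prioritization.** Seeds (down-regulated chromosome-22 genes) are
scored by their number of direct links to other seeds and tested against
degree-binned node permutations with the +1 pseudo-count estimator
p = (1 + #{perm ≥ obs}) / (n_perm + 1); prioritized seeds are joined with
the co-expression evidence.

## Worked example

```r
library(ependymeta)

sim <- simulate_cohorts(simulation_config(n_genes = 1500, rng_seed = 42))
fit <- run_meta_de(sim$studies)
fit
#> <meta_de> 1500 genes, 3 cohorts; consensus (FDR < 0.05): 190 genes (75 up, 115 down)

dplyr::select(head(dplyr::arrange(tidy(fit), q_es), 4),
              gene_id, pooled_es, se, tau2, q_es, q_fisher, direction)
#> # A tibble: 4 x 7
#>   gene_id pooled_es    se  tau2     q_es q_fisher direction
#>   <chr>       <dbl> <dbl> <dbl>    <dbl>    <dbl> <chr>
#> 1 G00146       1.98 0.193     0 1.61e-21 9.17e-21 up
#> 2 G01078      -1.88 0.191     0 6.20e-20 3.93e-19 down
#> 3 G00607       1.86 0.190     0 6.38e-20 3.93e-19 up
#> 4 G00623      -1.84 0.189     0 6.43e-20 3.93e-19 down

mc <- run_meta_cor(sim$studies, "NF2")
head(select_coexpressed(mc), 4)[, c("gene_id", "r_pooled", "se_r", "q")]
```

The generator plants 10% differentially expressed genes at |g| = 1.5, a
40-gene suppressed block on the chromosome-22 analog (containing the hub
gene `NF2`), a 50-gene co-expression module at pairwise r = 0.6, and an
8-gene PPI clique among block genes; `run_meta_de()` recovers the planted
genes (190 consensus calls above, against 150 planted DE genes plus the
40-gene block), with positive `pooled_es` meaning higher expression in
spinal tumors. The `q_es`/`q_fisher` columns are the two routes' FDRs; a
consensus call requires both below 0.05.

The whole chain — simulate, preprocess, both meta-analyses, enrichment and
region scan, permutation prioritization — runs as one call:

```r
res <- run_pipeline(pipeline_config(rng_seed = 1), out_dir = "run1")
```

which writes `meta_de.tsv`, `coexpr.tsv`, `flanking.tsv`, `enrichment.tsv`,
`regions.tsv`, `profile.tsv`, `seed_scores.tsv`, `prioritized.tsv` (each
with a provenance header) plus `manifest.json`. A command-line wrapper
lives at `inst/scripts/run_pipeline.R`.

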