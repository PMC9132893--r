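# panelscan

Landscape analysis of curated gene panels across cancer cohorts, built
around the 28-gene transient-receptor potential (TRP) channel panel
(six families: TRPA, TRPC, TRPM, TRPV, TRPML, TRPP) but applicable to any
panel with protein-coordinate annotations.

TRP channels are membrane calcium-signaling proteins repeatedly implicated
in tumor growth, progression and drug response. Asking what happens to a
panel like this across cancers means running several statistically distinct
analyses over shared inputs: where do somatic mutations fall within the
protein, are copy-number changes frequent, is expression dysregulated
tumor-versus-normal, do alterations track clinical covariates and
survival, which pathways co-express with each gene, and which drug
sensitivities correlate with its expression. panelscan packages those
stages as tested, composable functions plus an end-to-end pipeline, with a
synthetic cohort generator so everything runs and is testable without any
external download.

## The core statistic

For a gene of length $L_g$ residues with transmembrane (TM) intervals
covering $L_{TR}$ residues, and $N$ positioned mutations of which $k$ fall
inside TM intervals, mutations placed uniformly give a binomial null for
the TM count:

$$P(X \ge k) = 1 - \sum_{x=0}^{k-1}\binom{N}{x} p_{ri}^x (1-p_{ri})^{N-x},
\qquad p_{ri} = L_{TR}/L_g,$$

with enrichment ratio $E = k / (N \cdot L_{TR}/L_g)$. A gene is called
TM-enriched when $E > 1.3$ and the (BH-adjusted, by default) p-value is
below 0.05. Around this sit the standard stages: Wilcoxon/Fisher region
contrasts on mutation density, CADD scores and deleterious labels;
GISTIC-thresholded CNV gain/loss frequencies; rank-sum differential
expression with BH adjustment and conjunctive log2FC/significance calls;
maximally selected survival cutpoints with univariate Cox hazard ratios;
preranked GSEA on Spearman co-expression rankings with a set-permutation
null; and IC50 correlation screens with KNN imputation. The methods
vignette (`vignettes/panelscan-methods.Rmd`) documents every model and
design choice.

## Worked example

Simulate the reference cohort (200-gene panel, 20 genes with a 3-fold TM
mutation-rate multiplier, ~50 mutations per gene) and score TM enrichment:

```r
library(panelscan)

co  <- sim_cohort(sim_config(seed = 1))
enr <- tm_region_enrichment(co$mutations, co$panel)
head(enr[order(enr$p_value), c("gene", "n_mutations", "k_tm", "p_ri",
                               "enrichment", "p_value", "p_adjusted", "enriched")], 5)
#>    gene n_mutations k_tm  p_ri enrichment  p_value p_adjusted enriched
#> 1  G001          78   45 0.233       2.48 7.44e-11   1.49e-08     TRUE
#> 8  G008          59   40 0.313       2.16 9.55e-09   9.22e-07     TRUE
#> 12 G012          80   41 0.223       2.30 1.38e-08   9.22e-07     TRUE
#> 6  G006          80   39 0.207       2.35 2.37e-08   1.19e-06     TRUE
#> 2  G002          74   37 0.224       2.23 1.83e-07   7.32e-06     TRUE
sum(enr$enriched)
#> [1] 22
```

Each row is one gene: of `n_mutations` positioned mutations, `k_tm` fell
in TM intervals covering a fraction `p_ri` of the protein; `enrichment`
is the observed-over-expected ratio (G001 has 2.48× the uniform
expectation) and the binomial tail p-values are BH-adjusted before the
`enriched` call. Here 22 genes are called, recovering all 20 planted
enriched genes (`co$manifest$tm_enrichment_genes`) plus two false calls.

Survival of genetically altered versus unaltered patients (planted hazard
multiplier 2, 200 patients per arm):

```r
status <- setNames(rep(c("altered", "unaltered"), each = 200),
                   sprintf("P%03d", 1:400))
cl  <- sim_clinical(status, sim_config(seed = 1))
fit <- hazard_ratio(factor(status, c("unaltered", "altered")),
                    cl$os_time, cl$os_event)
fit[, c("hr", "ci_low", "ci_high", "logrank_chi2", "p_value", "classification")]
#>     hr ci_low ci_high logrank_chi2  p_value classification
#> 1 1.92   1.49    2.48           26 3.38e-07          risky
```

The Cox hazard ratio 1.92 (95% CI 1.49–2.48) recovers the planted
multiplier of 2, and the log-rank p classifies the grouping as a risky
factor (HR > 1, p < 0.05).

The full pipeline over a simulated cohort, from the shell:

```sh
exec/panelscan simulate --outdir sim --seed 1
exec/panelscan run-all  --inputs sim --outdir out --seed 1
```

which writes one TSV per result table (TM enrichment, CNV frequencies,
differential expression, clinical comparisons, survival screen, GSEA,
drug correlations) plus a run manifest and log. The shipped TRP panel is
available as `trp_panel()`; its TM interval table is a synthetic
placement (see the function's documentation) — supply UniProt intervals
via `read_tm_intervals()` for real analyses.

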