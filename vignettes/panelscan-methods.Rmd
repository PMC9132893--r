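---
title: "Methods and design of panelscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of panelscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscan)
```

panelscan characterizes a curated gene panel — the shipped example is the
28 transient-receptor potential (TRP) channel genes in their six classic
families — across cancer cohorts: somatic mutation and copy-number
landscape, transcriptome dysregulation, clinical relevance, pathway
associations, and pharmacogenomic correlates. This vignette explains the
statistical models behind each stage, the tunable parameters and their
defaults, what the synthetic cohort generator does and does not emulate,
and the design choices we made where more than one defensible option
existed.

## The transmembrane-region enrichment statistic

TRP channels share a six-transmembrane-helix architecture, and missense
mutations falling in those membrane-spanning segments are more likely to
perturb channel function. `tm_region_enrichment()` asks, per gene, whether
mutations concentrate in the transmembrane (TM) intervals beyond what
uniform placement would give. With $N$ positioned mutations in a gene of
length $L_g$ residues, of which $k$ fall inside TM intervals covering
$L_{TR}$ residues, the null model is binomial:

$$P(X \ge k) = 1 - \sum_{x=0}^{k-1} \binom{N}{x} p_{ri}^x (1-p_{ri})^{N-x},
\qquad p_{ri} = \frac{L_{TR}}{L_g},$$

computed through the survival-function form of `pbinom` (numerically
stable for extreme tails), together with the enrichment ratio

$$E = \frac{k}{N \cdot L_{TR}/L_g},$$

the observed TM count over its uniform expectation. $E = 1$ exactly when
the observed TM fraction matches the TM fraction of the protein; $E$ is
monotone increasing and the tail p monotone decreasing in $k$.

**Coordinates.** All lengths and positions are protein residues, 1-based
inclusive — the convention of UniProt TM annotations. Mutations without a
protein position (splice-site and similar) are excluded from region
statistics but still count toward mutation frequency and tumor mutation
burden.

**The calling rule.** A gene is flagged as TM-enriched when $E >$
`e_threshold` (default 1.3) and its p-value is below `p_threshold`
(default 0.05). By default the threshold applies to the BH-adjusted
p-value across the scored genes; `p_adjust = "none"` applies it to the raw
p instead, and both columns are always reported. We adopted the adjusted
default after working out the operating characteristics of the raw rule:
the binomial test's discreteness leaves a realized per-gene type-I rate
near 0.035, so on a 200-gene screen with a 10% planted-enrichment
prevalence the raw rule produces an expected false-discovery proportion
around 0.24 — no sensitivity gain can buy that back, whereas the BH rule
holds the empirical FDP near 0.03 at sensitivity ≈ 0.95 under the same
conditions. For a 28-gene panel the two rules rarely disagree; for larger
screens the adjusted rule is the defensible default.

Genes with no TM annotation ($L_{TR} = 0$) or no positioned mutations are
reported `scored = FALSE` rather than silently dropped. The degenerate
saturated case $L_{TR} = L_g$ gives $p_{ri} = 1$, tail probability 1, and
$E = k/N \le 1$: never enriched, as it should be.

Two companions complete the region analysis. `region_value_compare()`
contrasts per-gene mutation densities (mutations per residue, TM vs
other) or per-mutation CADD scores between regions with a two-sided
rank-sum test — exact by complete enumeration of the average-rank
statistic when the combined sample is at most 20 (ties handled exactly),
normal approximation with tie and continuity corrections otherwise.
Pooled-across-genes densities are available via
`mutation_density_by_region(per_gene = FALSE)`; per-gene is the default.
`deleterious_region_association()` tests the 2×2 of region against
deleterious/damaging status (SIFT-deleterious OR PolyPhen-damaging;
mutations with both labels missing are excluded) with Fisher's exact
test.

## Mutation frequency, TMB, and CNV frequencies

Mutation frequency is the proportion of samples of a cancer type with at
least one mutation in the gene; tumor mutation burden (TMB) is the count
of nonsynonymous mutations per patient, zero for patients without
records. CNV input follows the GISTIC thresholded coding (−2 homozygous
deletion … +2 high-level amplification); gain frequency counts values
$\ge 1$ and loss $\le -1$ by default, with a `mode = "high"` option
restricting to $\pm 2$. The inclusive default reflects that the
thresholded calls themselves already separate low- from high-level
events, and nothing in the frequency definition restricts to high-level
ones.

## Differential expression

Per cancer type with more than `min_normals` (default 5) normal samples,
each gene is tested tumor-versus-normal with the two-sided Wilcoxon
rank-sum test on log2(FPKM + 1); p-values are BH-adjusted within the
cancer type (per-cancer reporting is the unit of interest, so the family
is the within-cancer gene set). The fold change is
$\log_2(\overline{\mathrm{FPKM}}_T + 1) - \log_2(\overline{\mathrm{FPKM}}_N + 1)$
by default (`fc_mode = "log-means"`); a mean-of-logs variant is provided
since the source convention is ambiguous. A gene is called up when
log2FC > 1 *and* adjusted p < 0.05 — the thresholds are conjunctive, so a
huge fold change on three noisy samples is not a call. Cohorts with too
few normals are skipped with an explicit status rather than analyzed
badly.

The +1 pseudocount matters: it compresses fold changes for genes whose
FPKM is near zero, which is why the synthetic generator plants its
differential-expression effects on clearly expressed baselines (below).

Tissue-specificity classes follow the human-protein-atlas style rules
with threshold factor 4: *tissue enriched* (top tissue ≥ 4× every other),
*group enriched* (a group of 2–7 tissues, each ≥ 4× the mean of the
rest), *tissue enhanced* (top tissue ≥ 4× the mean of all tissues), else
*low specificity*. The group search scans descending-expression prefixes,
which is provably equivalent to searching all subsets of each size (any
other group of the same size has a smaller minimum and a larger
complement mean); the tests verify this against brute-force subset
enumeration.

## Clinical relevance

`alteration_status()` labels a patient *altered* when they carry a
nonsynonymous mutation in a panel gene or a high-level CNV event
(|value| = 2) in one; the CNV criterion can be relaxed to any event. The
high-level default matches the alteration semantics commonly used when
pairing genomic alteration with clinical covariates. Feature comparisons
between altered and unaltered patients use the chi-square test for
categoricals (Fisher's exact test whenever an expected cell is below 5),
the rank-sum test for continuous covariates, and the rank-sum test on
ordinal codes for stage/grade — a trend-sensitive choice — with BH
adjustment across the tested features.

The survival machinery is deliberately split:

- `logrank_test()` is the standard two-group log-rank statistic
  $(O - E)^2 / V$ summed over event times, implemented directly (it is
  evaluated thousands of times inside the cutpoint scan); the test suite
  cross-checks it against `survival::survdiff`.
- `optimal_cutpoint()` dichotomizes expression at the maximally selected
  rank statistic: every midpoint between consecutive distinct expression
  values leaving at least `minprop` (default 0.1) of patients per group
  is scored by the standardized log-rank statistic, and the argmax wins.
  Because the cutpoint maximizes the statistic, any subsequent p-value on
  the same data is optimistically biased; fits derived this way carry a
  `selection_biased` flag rather than a hidden caveat.
- `hazard_ratio()` fits the univariate Cox proportional-hazards model
  (Efron tie handling, via the survival package) on the dichotomized (or
  supplied) grouping, reporting the Wald 95% CI and the log-rank p, and
  classifying genes as *risky* (HR > 1, p < 0.05) or *protective*
  (HR < 1, p < 0.05). Genes with zero expression in more than half the
  patients are skipped with a reason — a rank-based cutpoint on a
  majority-zero vector is meaningless — and non-converging fits are
  returned flagged, never as a crash.

Overall survival is the primary endpoint; disease-free survival is
supported as a second endpoint. No multiplicity correction is applied to
the per-gene classification (the raw p rule is the reported convention);
a BH column is emitted alongside for users who want it.

## Pathway enrichment

For each anchor gene, all other genes are ranked by Spearman correlation
with the anchor (`rank_by_correlation()`, average-rank ties; zero-variance
genes are flagged and placed last). `preranked_es()` computes the weighted
Kolmogorov–Smirnov running sum on that ranking: hits advance by
$|score|^{weight}$ (normalized to total 1, weight 1 by default), misses
retreat by $1/(N - N_{hit})$, and the enrichment score is the signed
maximum deviation. Weight 0 recovers the classic unweighted KS statistic.
The running-sum profile is returned for plotting.

The null in `gsea_screen()` permutes set membership over list positions —
the appropriate null for a preranked input, where there is no two-class
design to permute. The normalized enrichment score divides the observed
ES by the mean |null ES| of matching sign, the permutation p is two-sided
on |ES| with the +1 correction (so its floor is $1/(n_{perm}+1)$), and BH
runs across sets within each anchor. Permutations are seeded per
(anchor, set) cell, so results are reproducible bit-for-bit and
independent of evaluation order. The ES computation works from hit
positions alone (between hits the walk is linear, so extrema occur
adjacent to hits), which keeps a 999-permutation screen inexpensive.

## Pharmacogenomics

`prepare_ic50()` implements the published preprocessing contract for drug
response matrices: drugs missing in more than 30% of cell lines are
removed (and logged); remaining gaps are imputed by the K nearest drugs
(Euclidean distance over mutually observed columns, scaled by the number
of shared columns; mean of the k = 5 nearest rows observed in the target
column); rows over `rowmax = 0.5` missing fall back to column means;
columns over `colmax = 0.8` missing abort with the cell line named. The
`maxp`/`seed` parameters belong to the same contract: the seeded
recursive-partitioning path only engages above `maxp = 1500` rows, so for
matrices smaller than that the output is deterministic and the seed is
inert — we document this rather than simulate a partitioning that would
never run at this scale.

`correlation_screen()` is one operation serving four analyses by
parameterization: panel-gene expression against drug IC50
(|SCC| > 0.15), against clinically actionable gene expression (0.2),
against gene essentiality profiles (0.2), and against the proliferation
marker MKI67 (0.2). Spearman's rho with average-rank ties is computed
over pairwise-complete shared columns, p-values follow `cor.test` (exact
for small tie-free samples, t approximation otherwise), BH runs over all
defined pairs of one screen invocation (separate invocations are separate
families), and a pair is significant when |SCC| exceeds the recorded
threshold and adjusted p < 0.05. Rank-basedness makes the screen
invariant to any monotone transform of either side, so whether IC50 is
raw or log-scale is immaterial. Constant rows yield undefined rho and are
excluded from the adjustment family. Correlations are pooled across cell
lines by default (no per-tissue stratification), matching the pan-cell-line
convention; stratification can be had by subsetting columns.

## The synthetic cohort generator

Every stage is exercisable offline because `sim_cohort()` generates
cohorts with the statistical structure the analyses assume. Each
generator op draws from its own stream seeded by `seed` plus an
op-specific offset, so outputs are byte-identical across runs and adding
one generator never perturbs another's draws. All planted truths are
recorded in the returned manifest.

The reference conditions (the defaults of `sim_config()`):

- **Panel**: 200 genes, lengths uniform on 500–900 residues, seven TM
  segments of 23 residues each (six helices plus a pore re-entrant
  segment, the compact 6-TM channel architecture) — TM fractions around
  0.18–0.32.
- **Mutations**: region-specific Poisson rates — background
  `50/700` per residue per cohort outside TM intervals, multiplied by 3
  inside the TM intervals of 20 designated genes. Under this
  superposition the expected TM fraction of an enriched gene's mutations
  is $mf/(mf + 1 - f)$ with $f = L_{TR}/L_g$, and enriched genes carry
  proportionally more total mutations, exactly as a region-specific
  mutational process would produce. Variant classes are 70%
  nonsynonymous / 25% silent / 5% other (the last without protein
  position); SIFT/PolyPhen deleterious probabilities and CADD means
  differ by region (0.5 vs 0.25; 20 vs 15) so the deleterious-mutation
  contrasts are recoverable.
- **Expression**: log-normal FPKM, gene means N(3, 1.5²) on the log2
  scale, within-gene spread SD 1. Ten genes at log2 effect +2 and ten at
  −2 in tumors; planted DE genes have baseline means floored at log2
  FPKM 2.5 because the +1 pseudocount makes a shift on a near-zero
  baseline unidentifiable — the planted truth must be detectable in
  principle for recovery rates to mean anything. A 30-gene co-expression
  module shares a latent factor (loading 0.8) so correlation-ranked GSEA
  has a recoverable signal, and a designated proliferation marker tracks
  its own latent factor.
- **Clinical**: exponential survival (memoryless, so hazard-ratio
  recovery has a closed-form target), baseline hazard 1/1000 per day,
  hazard multiplier 2 for altered patients, independent uniform censoring
  on [0, 2000] days. Hypoxia scores shift by +1 SD, TMB doubles, and
  stage/grade tilt by a proportional-odds factor of 2 in altered
  patients. No published effect sizes exist for these contrasts; the
  magnitudes are placeholders chosen to be detectable at n = 100–400 and
  are labelled as such.
- **Alteration label**: the integrated cohort plants its altered label
  directly (50% of patients) rather than deriving it from the simulated
  mutations. This is deliberate: a desk-scale cohort dense enough in
  mutations for the region-enrichment statistics (~50 mutations per gene
  across 100 tumors) makes *every* patient altered under any genetic
  rule. `alteration_status()` remains the analysis-side operation and is
  what the pipeline uses when no status table is supplied.
- **Drug response**: 50 drugs × 500 cell lines on the natural-log IC50
  scale. Drugs come in classes of ten sharing a per-cell-line latent
  factor (loading 0.7) — the mechanism-level clustering of real drug
  panels, and the reason nearest-neighbour imputation can outperform
  column means at all. Ten planted gene-drug pairs at Spearman rho 0.6
  via a Gaussian copula (normal correlation $2\sin(\pi\rho/6)$, so the
  rank correlation lands on the target); 10% MCAR missingness, below the
  30% removal filter unless raised per drug.

What the generator does **not** emulate: mutational signatures and
trinucleotide context, copy-number segmentation and length-dependent CNV
calls, batch effects and normalization artefacts, cancer-type-specific
expression programs, dependent censoring, and non-proportional hazards.
Passing recovery tests therefore demonstrates that the estimators are
correct and calibrated under the stated models — not that real cohorts
satisfy those models.

## Numerical choices and degenerate inputs

- Binomial tails via `pbinom(k - 1, N, p, lower.tail = FALSE)` — no
  explicit summation, stable in the far tail.
- Exact small-sample branches: rank-sum by enumeration up to combined
  n = 20; Spearman p exact (via `cor.test`) for small tie-free samples.
- GSEA ES extrema from hit positions; ties in |ES| across positions are
  resolved toward the earlier list position (measure-zero for continuous
  scores).
- Cutpoint candidates are midpoints between consecutive distinct values;
  ties in the scan statistic resolve to the smallest cutpoint.
- Degenerate inputs error early with named reasons: empty patient
  universe, all-censored survival, constant anchor gene, gene set
  covering the whole list, cell line over the colmax missingness limit.
  Skips (zero-expression filter, small set overlap, too-few normals) are
  reported as statuses in the result tables, not silently dropped rows.

## Problem sizes

The shipped test and acceptance workloads use the reference conditions
above: 200-gene panels, two cancer types of 50 tumor/50 normal samples,
400-patient survival arms over 30 replicates, 999-permutation GSEA with a
~200-test null calibration, and 50×500 drug screens. These sizes put
every estimator comfortably in its asymptotic regime while keeping a full
run in minutes on a single core; they are scaled-down analogues, not
reproductions, of consortium-scale cohorts.

## Known limitations

- The Cox fit is univariate by design; confounder adjustment is out of
  scope.
- The maximally selected cutpoint's selection bias is flagged but not
  corrected (no minP adjustment); treat per-gene survival p-values as
  screening statistics.
- The binomial region test assumes positions are exchangeable within a
  gene given region; clustered hotspots violate this and will inflate
  enrichment for reasons other than membrane topology.
- The KNN imputer recomputes distances per target row (O(rows²·cols));
  fine for panel-scale matrices, not tuned for genome-wide ones.
- The shipped TM interval table for the TRP panel is a synthetic
  placement provided so examples run out of the box; supply real UniProt
  intervals for any substantive analysis.
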