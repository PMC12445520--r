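---
title: "Models and methods: X-chromosome regulation and meiotic drive in testis scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: X-chromosome regulation and meiotic drive in testis scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivescope)
```

## The scientific setting

drivescope analyses testis single-cell RNA-seq from males of two X-chromosome
genotypes — standard (ST) and sex-ratio drive (SR), where the driving X
disables Y-bearing sperm — and asks three families of questions:

1. **Is the X silenced during spermatogenesis?** Meiotic sex chromosome
   inactivation (MSCI) would push a cell's X:autosome expression ratio far
   below 1. Each cell is classified from its X:A CPM ratio with an inclusive
   threshold of 0.33, and the proportion of inactivated cells is compared
   between germline and soma with a Pearson chi-square contingency test.
2. **Is X expression dosage-compensated, stage by stage?** On pseudobulk
   (sample x cell type) units, each X-linked gene contributes
   log2(CPM / median autosomal CPM); a stage median of 0 means parity with
   the autosomes, and -1 means half — the single-X expression expected
   without compensation.
3. **What does drive change?** Pseudobulk differential expression (SR vs ST)
   per cell type, chromosomal enrichment of the significant genes, a
   cell-resampling null for that enrichment, mixed-model tests of cell-type
   abundance, haploid/diploid classification from allele counts, and DNA
   coverage differences as a copy-number proxy correlated with expression
   changes.

All results are tibbles; fitted objects carry `tidy()`/`glance()` methods and
result types have plotting helpers.

## The synthetic-data generator

Real droplet data for this design (eight males, four per genotype) is large
and external, so the package ships a generative model with truth tables;
every statistical routine is validated by parameter recovery against it.

For a cell of type $t$ and genotype $g$, the count at gene $j$ is negative
binomial with mean $L_c\, w_{t,g,j} / \sum_k w_{t,g,k}$ and dispersion
$\phi$ (variance $\mu + \phi\mu^2$), where

$$w_{t,g,j} = \lambda_j \,\pi_{t,j}\, d_{t,g}^{[j \in X]}\, 2^{\beta\,[j \in \mathrm{DE},\, g = \mathrm{SR}]}.$$

* $\lambda_j$ — log-normal per-gene rate (`baseline_logmean/logsd`, defaults
  1 and 1 on the log scale): relative transcription propensities.
* $\pi_{t,j}$ — per-stage gene inclusion: each gene is "on" in stage $t$
  with probability `stage_inclusion[t]`. Off genes contribute rate 0.
* $d_{t,g}$ — the X dosage factor (dimensionless). Defaults encode the
  stage profile the analyses are designed to detect: 1 in somatic cells,
  0.5 in GSC/spermatogonia and primary spermatocytes (uncompensated
  single-X expression), 1 again in secondary spermatocytes and spermatids;
  identical for ST and SR.
* $\beta$ — drive-biased effect size (`de_log2fc`, default 2) on
  `n_de_genes` (default 50) genes upregulated in SR, placed half on the X.
* $L_c$ — expected library size, log-normal (`libsize_logmean` defaults to
  log 6000 UMIs) multiplied by the stage activity factor $a_t$.

Two modelling choices deserve explanation. First, because counts are
conditioned on a realized library size, a stage-wide multiplier on all gene
rates cancels out of the composition $w/\sum w$; the declining transcriptome
of late spermatogenesis therefore acts through the library-size draw
($a_t$, monotone declining over the germline) *and* through $\pi_t$
(fewer genes on). Together the defaults reproduce the qualitative pattern of
early stages expressing several-fold more genes than spermatids. Second,
mitochondrial genes are modelled compositionally: each cell draws a
mitochondrial share from a Beta distribution (default mean 5%) and MT genes
split that share, which gives the QC filter something real to act on.

Sample sizes follow the study design the analyses assume: 4 ST + 4 SR
males; default cell numbers per sample (~1,500 across six cell types) and
~3,000 genes across chr1, chr2, chrX and MT keep desk-scale runs fast while
leaving hundreds of X-linked genes after filtering. Allele-count tables
(`simulate_sites()`) and DNA coverage tables (`simulate_coverage()`, 50 ST
and 27 SR individuals by default) emulate the corresponding inputs for the
ploidy and coverage modules.

What the generator does *not* emulate: ambient RNA, UMI saturation,
batch/chemistry effects, correlated gene modules, doublets by default
(`doublet_rate = 0`; when enabled, doublets are summed cell pairs labelled
in truth), or genuinely continuous developmental trajectories — cell types
are discrete. Passing recovery tests therefore demonstrates correctness of
the estimators under the assumed NB model, not robustness to every artefact
of real droplet data.

## QC definitions

Cells are removed when they detect fewer than 200 features or exceed 20%
mitochondrial expression; genes are kept when expressed (count > 1) in at
least three cells. Two deliberate readings are exposed as options:

* the two cell criteria are combined with **either-fails-removes**
  (`logic = "any"`), the standard QC practice; `logic = "all"` is available;
* "detected" (count >= 1) governs the 200-feature rule while "expressed"
  (count > 1) governs the gene filter and all biology metrics. The two
  definitions are kept distinct and configurable.

Boundary cells — exactly 200 features, exactly 20% mitochondrial — are
retained, since the removal rules are strict inequalities.

## The per-cell classifier and its depth limitation

The per-cell X:A CPM ratio summarises expressed genes only; the summary is
the **median** (robust to the heavy right tail of expression), switchable to
the mean. Mitochondrial genes are excluded from numerator, denominator and
the CPM library size: mitochondrial load is a technical covariate, not
chromosomal dosage.

Counts are discrete, and that matters at the decision boundary: in a shallow
cell whose expressed X genes mostly sit at the minimum qualifying count of
2, the X median is pinned at 2 while the autosomal median may be 6, giving
a ratio of exactly 1/3 — just above the 0.33 threshold. Recovery of a
near-silenced X (dosage 0.05) is therefore evaluated on cells with at least
200 expressed genes on each chromosome class, a stratum that exists only at
deep per-cell coverage; the package's tests simulate ~150k-count cells for
that check. On shallow droplet data the classifier errs on the side of *not*
calling inactivation, which is conservative for detecting MSCI absence.

## Pseudobulk dosage statistic

Counts are summed over all cells of each (sample, cell type) unit, making
the male — not the cell — the biological replicate. Library normalisation is
TMM (30% M-trim, 5% A-trim, reference chosen by upper quartile); plain
total-count scaling is available. Genes enter the dosage statistic for a
cell type only if expressed (count > 1) in at least 5% of that cell type's
cells *and* above log2 CPM 2 in a strict majority of ST males or a strict
majority of SR males. Both "half" rules are strict, so 2-of-4 samples fails.

The gene filters interact with the statistic in a way worth knowing about.
When the X truly sits at half dose, X-linked genes are twice as likely to
fall below the expressed-in-5%-of-cells rule (and, more weakly, the CPM
majority rule) than autosomal genes of the same underlying rate; at shallow
coverage this truncates the lower tail of the X distribution and biases the
recovered median log2(X:A) *upward* — at ~6,000 counts/cell with 3,000
genes the bias reaches +0.3-0.4, shrinking below ~0.05 by ~25,000
counts/cell. The bias is a property of the filtering recipe itself, not of
this implementation, and is conservative for claiming *loss* of
compensation. The package's recovery checks therefore run at coverage where
truncation is negligible; on shallow data, interpret small upward shifts of
the X:A median with this in mind. A second precision note: the median over
the X panel carries the sampling noise of that panel (standard error
roughly 1.25 sd(log2 lambda)/sqrt(n_X), shared across all stages because
the gene rates are fixed), so recovery bands should be read against the
filtered X gene count.

Per unit, each X-linked gene contributes log2(CPM / median autosomal CPM),
the autosomal median being computed within the same unit over the filtered
autosomal genes (the statistic is internal to a unit, so any unit-wide
scaling cancels). X genes with zero CPM after filtering are excluded and
counted, never pseudocounted. Per-gene values are averaged across a
genotype's samples; the one-sample test against 0 is a Wilcoxon signed-rank
over genes (matching per-gene box plots), switchable in principle to
per-sample medians — the replicate unit is recorded in the output. The exact
signed-rank distribution is computed by a convolution over signed ranks for
n <= 25 (it tolerates ties, where the classical exact tables do not), with
a tie-corrected normal approximation beyond. ST-SR comparisons use the
two-sided Mann-Whitney test.

## The differential-expression engine

One engine serves both expression and coverage: a negative-binomial
conditional exact test with moderated dispersions.

* Counts are scaled to the geometric-mean library size ("pseudo-counts").
* A common dispersion maximises the pooled profile likelihood with
  group-specific means; tagwise dispersions maximise each gene's likelihood
  plus a prior weight of 10 gene-equivalents of the average likelihood —
  weighted-likelihood shrinkage toward the common value. Underdispersed
  genes are floored at 0.
* Given group sums $s_1, s_2$ from $n_1, n_2$ units, the two-sided p-value
  conditions on the total: group-sum laws NB$(n_g\mu,\ \phi/n_g)$, binomial
  in the Poisson limit $\phi = 0$; the smaller tail is doubled and capped
  at 1. At $\phi = 0$ this reproduces binomial enumeration to 1e-9, which
  is the package's main analytic oracle.
* log2 fold changes (SR vs ST) use adjusted group means with a 0.5-count
  prior to stabilise zero groups.
* Significance is the joint rule |log2FC| > 1 and BH-FDR < 0.05, FDR
  computed within cell type.

A quasi-likelihood F-test is the other common choice for pseudobulk DE; the
exact test was chosen because its sampling distribution is fully specified
and oracle-checkable, and the same engine is reused for DNA coverage, where
the exact test is standard. Inside the resampling null (below) the engine
runs with the common dispersion only: with 4+4 pseudo-samples the prior
weight of 10 makes tagwise values nearly common anyway, and the null loop
pays that cost hundreds of times.

## Enrichment and the pseudo-replicate null

Chromosomal enrichment of significant genes is a binomial GLM,
`significant ~ chromosome * cell_type`, with nested models compared by
likelihood-ratio chi-square in a fixed order: interaction first, then the
chromosome main effect. Complete separation (e.g. a chromosome with every
gene significant) is detected and reported; a Jeffreys-prior penalised fit
(`firth = TRUE`) keeps estimates finite in that case.

The resampling null asks how much "differential expression" arises from
cell sampling alone: per repeat, two groups of four pseudo-samples of 100
cells are drawn with replacement — both from the ST pool for the null, one
from each pool for the observed comparison — aggregated, filtered with the
pseudobulk rules (the 5%-of-cells rule is evaluated on the pool, the
majority-CPM rule within the repeat), tested, and summarised as the percent
of filtered genes significant on the X and on the autosomes. Distributions
from 1,000 repeats (the default) are compared between designs with a
rank-sum test. Cells are drawn ignoring sample identity, exactly as a
pooled bootstrap; `stratify_by_sample = TRUE` preserves batch structure
instead. The packaged checks run 50-100 repeats per design, which is
sufficient to place the observed X percent against the null's 95th
percentile; the repeat count is a precision knob, not a model parameter.

## Cell-type abundance

Abundance contrasts are binomial mixed models
`outcome ~ genotype + (1 | sample)`, fitted by Laplace-approximated maximum
likelihood on per-sample binomial totals (likelihood-identical to the
cell-level Bernoulli fit) with a Wald z test on the genotype log-odds.
Adaptive Gauss-Hermite quadrature (`nAGQ = 15`) serves as a cross-check;
on the packaged simulations Laplace and quadrature agree to better than
1e-3 in the treatment effect. When the random-intercept variance hits the
boundary at 0 the model is refitted as ordinary logistic regression and
flagged. Contrast composition: germline-vs-cyst uses all four germline
stages; premeiotic (GSC/spermatogonia + primary spermatocytes) vs
postmeiotic (spermatids) **excludes secondary spermatocytes** by default —
they are meiotically active and belong cleanly to neither side; the mapping
is configurable and recorded in the result.

## Ploidy from allele counts

A site is homozygous with >= 2 reads on one allele and none on the other,
heterozygous with >= 2 reads on each, otherwise ungenotyped — a 2/1 split
qualifies for neither call and is deliberately ungenotyped. Cells genotyped
at fewer than 10 sites are unclassified. The haploid rule defaults to a
homozygous fraction of 1 (a single heterozygous site makes a cell diploid);
on real data with sequencing errors a tolerance such as 0.95 is advisable
and exposed as `hom_frac_cutoff`.

## Coverage as a copy-number proxy

Per-gene DNA read counts per individual are tested with the same NB exact
engine. Normalisation defaults to total-count scaling — genome-wide
coverage is far less composition-biased than expression, so TMM's trimming
buys little (it remains available). The expression-coverage association is
a Spearman rank correlation; the reported rho is the tie-corrected
Pearson-on-ranks value. Signed log2 fold changes are correlated by default
("magnitude" association is available via `absolute = TRUE`, since
direction-free copy-number dosage is also a reasonable reading).

## Numerical choices, in one place

* Strict inequalities where the filter definitions state them
  (200 features, 20% mito, count > 1, log2 CPM > 2, strict majorities);
  the inactivation threshold 0.33 is inclusive.
* Exact signed-rank for n <= 25; normal approximation with tie and
  continuity corrections beyond.
* Dispersion optimisation on a log grid (1e-6 to 10, 36 points) refined by
  golden-section search; dispersions below 2e-6 are reported as 0.
* Group sums are rounded to integers after library adjustment for the
  conditional exact test; equal library sizes leave counts untouched.
* The enrichment LRT compares deviances of nested `stats::glm` fits; the
  Firth fit uses Jeffreys-prior IRLS with step tolerance 1e-8.
* One master seed drives named RNG sub-streams per operation, so each
  stage reproduces independently of what ran before it.

## Problem sizes used by the packaged checks

Unit and property tests run on hand-built fixtures and simulations of a
few hundred cells; parameter-recovery checks use 8-sample simulations with
~3,000 genes (dosage), ~120-150 deep cells per sample (MSCI), 20 null
replicates (FDR calibration), 50-100 resampling repeats per design, 200
GLMM simulations of 8 samples x 800 cells, and 300 cells x 50 sites
(ploidy). These sizes were chosen so the whole suite completes on a
single CPU in a few minutes while leaving each check comfortable
statistical margin.

## Known limitations

* **Wald intervals from few-group GLMMs undercover.** With 8 samples the
  ML estimate of the random-intercept variance is biased low and the Wald
  interval ignores its uncertainty; in the packaged 200-simulation
  recovery check the nominal 95% interval covers the true genotype effect
  in roughly 85% of runs. This is a property of the Laplace-ML + Wald
  procedure itself, not of the implementation (15-node quadrature gives
  the same estimates to < 1e-3). Treat the reported Wald p-values as
  anticonservative at this design size; profile or few-df t intervals
  would be the remedy if calibrated intervals are needed.
* **The resampling null is degenerate under homogeneity.** Between
  identical cell pools the joint significance rule essentially never
  fires, so the percent-DE null distribution is a point mass at 0 and the
  rank-sum comparison saturates at p = 1. That is the desired conservative
  behaviour — the machinery never fabricates differences — but it means
  the null comparison p-value carries no resolution below "indistinguishable".
* The generator's independence across genes understates the variance of
  genome-wide summaries on real data, where expression is modular.
* The exact test conditions on rounded adjusted group sums; with wildly
  unequal library sizes the rounding is a (documented, tiny) approximation.
* The per-cell classifier's behaviour at shallow depth is conservative, as
  described above.
* Cell-type labels are taken as given; clustering, annotation, doublet
  removal and trajectory inference are upstream concerns outside this
  package's scope.
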