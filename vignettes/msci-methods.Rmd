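---
title: "Replicate error, X-chromosome expression and tissue-specificity enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate error, X-chromosome expression and tissue-specificity enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msci)
```

## The scientific problem

Meiotic sex chromosome inactivation (MSCI) predicts that X-linked genes are
transcriptionally silenced in the male germline as spermatocytes enter
meiosis. In *Drosophila*, one observable consequence would be a depression
of mean X-linked expression, relative to the autosomes, in whole-testis
transcriptomes from developmental stages in which meiotic cells dominate.
A second, population-genetic consequence is the well-documented deficit of
testis-biased genes on the X. Whether that deficit is specific to
testis-related expression or a generic property of *any* tissue-specific
gene is a separate, testable question — and answering it requires removing
a confound: tissue-specific gene sets assembled from expression atlases by
signal-ratio criteria are themselves enriched with testis-biased genes.

This package implements both analyses as a reusable pipeline: replicate
quality control and variance decomposition for a developing-testis
microarray time course; per-stage X-versus-autosome contrasts; tissue
specificity, sex bias, and gene-age classification from an atlas-style
tissue panel; and contingency-table enrichment statistics with and without
removal of sex-biased genes.

## Data model

Two-channel arrays are reduced to `M = R − G` and `A = (R + G)/2` from
normalized log2 channel intensities (`ma_transform()`); all developmental
analyses operate on A-values. Records with missing A are excluded
*stage-wise* at load time: the statistical analyses are per stage, so a
gene unusable in one stage can still contribute to another. The canonical
interchange format is plain delimited text (TSV by default), which keeps
fixtures diffable; spreadsheet inputs must be converted to this dialect
beforehand, as no spreadsheet reader is part of the package.

Tissue panels carry one mean signal per gene per tissue plus four
present/absent replicate calls per tissue. Probe-level tables are
crosslinked to gene annotation, probes without a unique genomic alignment
are dropped, and multiple unique probes per gene are aggregated: signals by
the mean, calls from the probe with the highest overall mean signal (calls
are per-array booleans, so a mean is undefined; the strongest probe is the
least likely to sit at the detection boundary).

Chromosome arms `X, 2L, 2R, 3L, 3R, 4` enter linkage contrasts (arm 4
counts as an autosome); anything else — Y, heterochromatic scaffolds,
mitochondrial, unmapped — is excluded rather than guessed.

## Replicate quality and the variance decomposition

`pairwise_correlations()` computes Pearson correlations over genes for all
`C(r, 2)` replicate pairs of a stage. On log2 data with additive
within-replicate error the expected pairwise correlation is the intraclass
ratio `σ²_gene / (σ²_gene + σ²_error)`, so low replicate correlations and a
high experimental-error fraction are two views of the same quantity — a
property the test suite exploits. The pooled mean is compared against a
configurable benchmark (default 0.9, a conventional figure for
well-replicated array experiments); the benchmark is a flag, not an
assertion, because it is a rule of thumb rather than a standard.

`variance_components()` is the moment-based sum-of-squares decomposition of
a one-way random-effects design with genes as groups — the only nesting
available within a stage, and the construction that defines "experimental
error" as the within-gene, among-replicate variance:

* `SS_within = Σ_g Σ_r (y_gr − ȳ_g)²`, `MS_within = SS_within / (N − G)`
* `SS_among = Σ_g n_g (ȳ_g − ȳ)²`, `MS_among = SS_among / (G − 1)`
* `var_within = MS_within`;
  `var_among = max(0, (MS_among − MS_within) / n₀)`

with `n₀` the Sokal–Rohlf effective group size
`(N − Σn_g²/N)/(G − 1)`, equal to the replicate count for balanced data.
The among-gene component is clamped at zero (the standard convention; it
also keeps the error fraction within [0, 100] %). No REML/ML fitting is
offered: the moment method *is* the procedure being reproduced, and for a
balanced one-way layout it is also the ANOVA estimator.

`sd_ratio()` reports the companion diagnostic: the SD among per-gene
replicate means divided by the mean per-gene SD across replicates, pooled
and per linkage class. Values near 1 mean biological signal barely exceeds
noise; since one log2 unit is a two-fold signal difference, an MSCI-sized
effect is then near the detection floor. Both the pooled and the per-class
ratios are reported because the diagnostic is meaningful at either
granularity.

## X-versus-autosome contrasts

`x_autosome_test()` averages each gene's replicates and runs a two-sample
t-test of X-linked versus autosomal per-gene means. The Welch
(unequal-variance) form is the default — the class variances have no reason
to be equal — with Student's pooled form available by argument, and
two-sided p-values by default; both switches exist because the original
analyses do not record which variant was used, and matching archived
results may require either. The unit of inference is the chromosome class,
not the individual gene; no per-gene differential-expression machinery is
involved.

## Tissue specificity, sex bias, age

Two specificity definitions are implemented, and only these two:

* **Ratio**: a gene is specific to a focal tissue at fold `t` when the
  minimum over denominator tissues of (focal signal / other signal)
  exceeds `t`; thresholds 2, 5, 10 give nested sets by construction.
  Denominator signals are floored (default 1 signal unit) before division:
  atlas signals are non-negative means, and without a floor a single zero
  denominator would make every expressed gene infinitely specific. A
  non-positive focal signal scores 0.
* **Presence/absence**: present in all four replicate arrays of exactly one
  tissue and absent in every replicate of every other tissue — a much
  stricter call that assigns each gene to at most one tissue.

Whether testis and ovary belong in the denominator panel when scoring
somatic tissues is genuinely open; the default excludes them, which is what
allows a midgut-specific gene (say, 629 units in midgut against 196 in
testis and 34 in ovary) to be simultaneously midgut-specific and
testis-biased. That coexistence is not an edge case — it is the confound
the enrichment layer is designed to remove — but the choice is an argument
(`sex_tissues_in_panel`) and is recorded in the output's config attribute.

`sex_bias()` classifies testis-biased (testis/ovary > threshold, default
2), ovary-biased (ovary/testis > threshold), or unbiased — mutually
exclusive for any threshold ≥ 1. "Not sex-biased" downstream always means
the unbiased class at threshold 2. `filter_by_age()` restricts sets to old
genes (origin predating the Sophophora/Drosophila subgenus split), since
young genes are enriched for X-linked testis expression and would confound
chromosomal contrasts of the call-based sets.

## Enrichment statistics

`contingency_test()` applies the size rule used throughout: Fisher exact
below 5000 total cases, Yates-corrected chi-square at or above. The
two-sided Fisher p follows the probability-mass convention (sum of
hypergeometric probabilities ≤ the observed table's, with a 1e-7 relative
tie slack) — the convention of R's `fisher.test`, against which the
implementation is cross-checked, and implemented directly so that the test
suite can sweep every 2×2 table with N ≤ 60 against an independent
enumeration oracle in seconds. The Yates statistic uses the closed form
`N(|ad−bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d))` with the statistic clamped at
0 when `|ad−bc| ≤ N/2`. Degenerate tables (a zero margin) report p = 1
with a flag. The odds ratio is the sample cross-product ratio, one
definition for both branches.

`normalized_x_frequency()` reports a set's X fraction divided by the
genome's, with the binomial SE of the set fraction (genome fraction
treated as fixed, consistent with "standard error of the mean" bars
normalized against a genome average) giving ±1 SE (~70%) and ±2 SE (~95%)
bands. `chromosomal_enrichment()` combines both per tissue × threshold,
with the background defined as the *rest of the genome* (genome minus the
set). With `exclude_sex_biased = TRUE`, sex-biased genes are removed from
set *and* background before testing. `testis_bias_enrichment()` tests the
excess of testis-biased genes in each specific set; because the archived
descriptions of this table's second margin differ (all non-testis-biased
genes vs only ovary-biased genes), both contrasts are implemented and
neither is privileged. Raw p-values with the conventional star levels are
the primary output — matching the analyses being reproduced, which apply
no multiplicity correction — and a Benjamini–Hochberg column is available
by argument.

## The synthetic-data generator

`simulate_stage_set()` draws per-gene baselines `μ_g ~ N(gene_mean,
var_among)` shared across stages, adds a per-stage shift to X-linked genes,
and adds i.i.d. Gaussian error per replicate. Defaults are the study
conditions: 14,000 genes × 10 replicates × 7 stages; `var_among = 1`
(log2²); per-stage `var_within` set so the error fraction follows the
24–44% profile of the real time course (which makes the expected pairwise
replicate correlation ≈ 0.70); X fraction 0.16 (the approximate share of
X-linked genes in FlyBase release-5-era annotation); X shift 0 in the four
early (feeding-larva) stages and −0.5 log2 in the three late stages, a
detectable-but-sub-twofold downshift of the kind MSCI would produce as
meiotic cells accumulate.

`simulate_tissue_panel()` gives background genes exchangeable log-normal
signals (per-gene size × per-tissue noise); plants per-tissue specific
genes at `specific_fold` × their maximum background signal; suppresses all
non-focal signals of a planted subset below the call threshold (the genes
recoverable under the strict presence/absence definition); makes planted
somatic-specific genes testis-biased with probability `sexbias_coupling`
(testis raised to 3–8× ovary, capped below the focal signal so ratio-based
specificity is preserved); and skews chromosome assignment via odds
multipliers — testis-linked genes toward the autosomes, ovary-specific
toward the X. Presence calls are thresholded signals with four replicate
copies and Bernoulli flip noise; no hybridization physics is modelled
because only the call semantics matter downstream. Identical config + seed
gives bit-identical output.

What the generator does *not* emulate: correlated noise between replicates
(batch structure), heavy-tailed signal distributions, probe saturation,
and any dependence between expression level and chromosome beyond the
planted shifts. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators under the assumed additive
model, not robustness to real-data artifacts.

## Problem sizes and numerical choices in the test suite

The package's tests size simulations to keep assertions sharp: variance
recovery uses 5,000 genes × 10 replicates over 20 seeds (a configured 30%
error fraction is recovered within ±2 points); type-I error of the
X-vs-autosome test uses 1,000 null datasets at 2,400 genes; the power check
injects a −0.5 log2 shift at 400 X / 2,000 autosomal genes over 100 seeds;
band coverage uses 1,000 draws of 100 genes (the exact binomial coverage of
a ±2 SE band at these sizes is 0.945, comfortably inside the asserted
0.95 ± 0.02); the Fisher sweep enumerates all 635,376 tables with N ≤ 60.
The SD-ratio identity check uses 40 replicates, where both small-sample
biases (the replicate-mean inflation `√(1 + 1/r)` and the sample-SD factor
`c₄(r)`) fall below 2%. The contamination-removal test aggregates 5 panels
× 5 somatic tissues and sizes its margins from the binomial null: ≥ 21 of
25 contaminated sets must show significant X depletion before sex-bias
filtering, and ≤ 3 of 25 (the ~2.5% one-sided null rate plus slack) after.

One aggregate check deliberately uses a clean-separation configuration
(call threshold far below all background signals, no call-flip noise): the
planted presence/absence sets are then recovered *exactly*, which is the
designed behaviour of the classifier, not a typical-data claim.

## Known limitations

* The deposited developing-testis table itself is not redistributed with
  the package; reproducing the published per-stage error percentages,
  the 0.72 pooled correlation and the adult SD ratio of 1.1 requires
  converting that table to the canonical TSV dialect (see the README's
  reproduction section). The corresponding acceptance test fails, by
  design, until the table is supplied.
* Stage matrices are assumed balanced after stage-wise exclusion of
  missing A-values; per-cell missingness is supported through the
  unbalanced `n₀` correction but not exercised by the canonical loader.
* The enrichment layer treats genes as exchangeable; no gene-length,
  expression-level or GC covariates are available to condition on.
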