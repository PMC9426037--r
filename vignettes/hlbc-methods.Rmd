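---
title: "Methods: integrative genomic and transcriptomic profiling of HER2-low breast carcinomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative genomic and transcriptomic profiling of HER2-low breast carcinomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlbc)
```

## Scope and data model

`hlbc` implements the analysis workflow used to ask whether HER2-low breast
carcinomas (HLBC; IHC score 1+ or 2+, no *ERBB2* amplification) form a
distinct molecular entity. The workflow takes five kinds of input, all plain
tables: a variant-call table from a targeted DNA panel (523 genes, 1.94 Mb
footprint, 120 microsatellite loci, 59 copy-number genes by default), a
clinical covariate table (ER, PgR, grade, Ki67, HER2 IHC/FISH class, PAM50
label), a copy-number fold-change table, per-locus microsatellite calls, and
a nonnegative gene-by-sample expression matrix from a targeted expression
panel (776 genes by default) with gene-set membership.

Because cohorts of this kind cannot be redistributed, the package ships a
seeded generator (`generate_cohort()`, `generate_control_pool()`,
`simulate_expression()`) that emulates the statistical structure every
downstream stage assumes. All statements below about recovery and
calibration are verified by the test suite on generated data.

## Mutation statistics

**TMB.** Per sample, the count of somatic, non-synonymous variants with
variant allele frequency strictly greater than 0.05, divided by the panel's
sequenced megabases. The non-synonymous set is {missense, nonsense,
frameshift, inframe indel, splice}; this includes small indels, which some
panel-vendor implementations exclude — the set is a documented choice
following common TMB practice, and the threshold is strict (a VAF of exactly
0.05 does not qualify). Samples with no qualifying variants are reported
with TMB 0 rather than dropped.

**MSI.** The per-sample fraction of microsatellite loci called unstable.
No standard cutoff for "MSI-high" exists for fraction-scale panel output;
the package uses an inclusive threshold of 0.20, configurable, chosen so
that clearly unstable profiles (about 40% unstable loci) flag while the
background instability rate (a few percent of loci) does not.

**Group contrasts.** Mean comparisons (TMB, VAF, Ki67) use Welch's
unequal-variance t-test rather than Student's pooled test: the subgroup
sizes are imbalanced (34 / 15 / 50 by default) and there is no reason to
assume equal variances. The Welch statistic is computed in closed form,
which also gives defined behavior for zero-variance groups (equal means give
t = 0, p = 1); `stats::t.test` serves as an independent oracle in the tests.
Families of tests are adjusted by Benjamini–Hochberg throughout, except
variant-spectrum chi-square comparisons, which follow the more conservative
Bonferroni convention with the family size equal to the number of
cohort-pair comparisons.

**Signature refitting.** SNVs with VAF > 0.1 are binned into the 96
trinucleotide substitution contexts, and the frequency-scaled catalog is
decomposed on a column-normalized reference signature matrix by non-negative
least squares (`pracma::lsqnonneg`), with weights renormalized to sum to
one. Curated signature catalogs are not redistributable here, so
`synthetic_signatures()` provides a deterministic synthetic basis (peaked,
largely distinct profiles with unit column sums); any 96-by-S reference with
the same contract can be supplied. Exact mixtures are recovered with zero
residual whenever the catalog lies in the reference cone; with finite
catalogs (500 draws) the recovery error depends on the conditioning of the
reference, which the synthetic basis keeps comparable to curated catalogs.

## Matched-cohort comparison

The control cohort is drawn from a large pool so that its ER and grade
strata match the study cohort: 90% ER-positive, 55% G3 within the
ER-positive stratum, 80% G3 within the ER-negative stratum. Stratum counts
are the largest-remainder rounding of the target size times the stratum
fractions — totals are exact and each stratum deviates from its quota by at
most one sample; only the percentages, not the rounding rule, are externally
given. Sampling is without replacement and deterministic given the seed; the
draw is made once, not resampled.

Per-gene differential-mutation testing uses the two-sided Fisher exact test
with R's point-probability convention (the sum of all tables as or less
probable than the observed one), matching the ecosystem in which such
analyses are typically run; the test suite verifies it against full
hypergeometric enumeration for every table with n ≤ 20. Genes unmutated in
both cohorts have degenerate tables and are excluded from the BH family.
"Spider" summaries count genes below α = 0.05 on both the raw and the
adjusted scale.

## Expression analysis

**Normalization.** Vendor normalization pipelines for targeted expression
panels are proprietary; the package uses a documented housekeeping-only
approximation: each sample's scale factor is the geometric mean of its
housekeeping counts divided by the cohort-wide arithmetic mean of those
geometric means, and values are log2(x + 1) (pseudocount 1). Passing a fixed
reference mean makes normalization of a sample independent of the rest of
the cohort, which is also what makes the scale-invariance property exact.

**Differential expression.** Per gene, ordinary least squares of log2
expression on a two-level group indicator plus covariates (ER status,
grade, ...), with the plain unmoderated t-statistic of the group
coefficient. No variance shrinkage is applied: the source analyses specify
only a covariate-adjusted linear ("ANOVA-type") model, and the unmoderated
test has exact type-I control, which the suite checks by null simulation
(1000 genes, 20 vs 20 samples; the raw-p < 0.05 fraction must lie in
0.05 ± 0.02). Rank-deficient designs (a covariate aliased with the group)
are an error naming the aliased terms, not a silent drop.

**Pathway and cell-type scores.** The pathway score is the first principal
component of the gene-centered set submatrix. Eigenvector sign is fixed
deterministically: the score is oriented to correlate positively with the
set's mean expression; if that correlation is zero or undefined (e.g. a
perfectly anti-correlated pair), the loading sum and then the first
non-negligible score entry break the tie. Cell-type scores are mean log2
marker expression.

**GSS / dGSS.** For a gene set S with member t-statistics,
GSS = sqrt(mean t²) and dGSS = sign(Σ sign(t)·t²) · sqrt(|mean sign(t)·t²|),
the root-mean-square significance and its direction-preserving variant.
These are the published gene-set summary definitions used with targeted
expression panels; |dGSS| ≤ GSS always, with equality exactly when all
member t-statistics share one sign.

## Class discovery

Consensus NMF is run on the top 33% most variable genes (floor rule;
variance ties break lexicographically by symbol) of the normalized matrix.
The factorization itself uses multiplicative updates for the generalized
Kullback–Leibler divergence with seeded uniform initialization — the
default objective of the standard R NMF tooling — implemented as a compiled
kernel (the objective is nonincreasing per sweep, checked in tests).
Defaults: 30 restarts per rank, K from 2 to 6, convergence at a relative KL
change below 1e-6 checked every 10 sweeps, at most 2000 sweeps.

Each restart assigns samples to their argmax metagene; the consensus matrix
records co-clustering frequencies across restarts. Final labels come from
average-linkage hierarchical clustering of 1 − consensus cut at K — the
standard consensus practice, preferred over taking a single best run because
it uses all restarts. Clustering stability per K is the cophenetic
correlation between the consensus dissimilarities and the dendrogram's
cophenetic distances (1 for a perfect 0/1 block consensus).

Rank selection then applies a two-step rule: rank candidates by cophenetic
coefficient, and discard any candidate whose clustering recapitulates the
PAM50 intrinsic subtypes, since the goal is a classification that adds
information beyond intrinsic subtype. "Recapitulates" is operationalized as
an adjusted Rand index above a threshold (default 0.6, configurable — the
source procedure states the exclusion qualitatively and no quantitative
overlap is published). An optional minimum-K constraint is exposed
(`min_k`, default off) for analyses that require at least a given number of
groups; it is off by default because the cophenetic ranking plus overlap
exclusion already determines a unique K on well-separated data. If every
candidate is discarded the selection fails loudly ("no novel clustering")
rather than returning a PAM50 lookalike.

## The synthetic-data model

`simulate_expression()` generates V = W·H plus Gaussian noise truncated at
zero. H has planted block structure: each sample loads about 1 on its own
metagene and `bleed` (default 0.05) on the others; each metagene owns a
block of 64 genes with loadings in [2, 4]; remaining genes are flat
(near-constant) across samples, including 10 high-expressed housekeeping
genes. Defaults: four metagenes with sample fractions 12/28/15/30 out of 85
and noise SD 0.2 — a low-noise regime on the O(3) in-block signal scale.

`generate_cohort()` adds the clinical and mutational layers: exact subgroup
sizes 34/15/50; per-group driver prevalences (PIK3CA 0.31 in all groups,
GATA3 and TP53 depleted in the 2N subgroup, ERBB2 mutations confined to the
2E subgroup); per-group VAF Beta distributions with means
0.175 / 0.244 / 0.256 and concentration 20 (the concentration is a generator
choice — only group means and their confidence intervals are externally
stated); per-group mean TMB 8.46 / 4.70 / 5.18 mut/Mb, realized as Poisson
passenger counts that top up the configured drivers (passengers are drawn
outside the driver genes so configured prevalences stay exact); an ERBB2
copy-number fold-change gradient (means 1.0 / 1.7 / 2.5 — the gradient
direction is externally motivated, the values are generator choices); a 2%
per-locus background microsatellite instability rate with rare (1%)
hypermutated MSI-high profiles (40% unstable loci, TMB ≈ 42.5); and
substitution contexts drawn from mixtures of the synthetic signature basis,
with one mixture component private to the score-1+ group.

What the generator does **not** model: count-level noise of the expression
chemistry (noise is truncated Gaussian, not negative binomial), linkage
between mutations and expression classes (the planted expression clusters
are independent of the mutation layer unless constructed otherwise),
copy-number segmentation, and any survival structure. Passing tests
therefore demonstrate correctness of the statistical machinery and
recoverability of planted structure — not that real HLBC cohorts contain
four expression classes.

## Numerical choices and degenerate inputs

* Strict VAF thresholds (`>` 0.05 for TMB, `>` 0.1 for catalogs), inclusive
  MSI (≥ 0.20) and TMB-high (≥ 10 mut/Mb) thresholds; all configurable.
* Fisher tests use the point-probability two-sided method; BH via
  `stats::p.adjust`; both verified against independent oracles in the suite.
* NMF requires no all-zero rows/columns (error advises filtering); KL is
  computed with a 1e-16 floor inside logs; runs stop early when the KL falls
  below 1e-12 absolute.
* Consensus matrices are asserted symmetric with unit diagonal in [0, 1];
  a zero-spread consensus (all restarts identical) defines cophenetic 1.
* Zero-variance groups in mean tests collapse the CI onto the mean instead
  of erroring; a cluster whose complement has fewer than two samples skips
  mean tests; singleton clusters skip all tests with a warning.
* Fixture writers emit doubles with 17 significant digits so write-then-read
  is the identity; readers validate mandatory columns and report the line
  number of malformed numeric fields.

## Problem sizes used in the test suite

Unit tests run on small constructed fixtures. The simulation-based checks
use: 10,000 samples for mutation-prevalence calibration; pools of 5000 for
matching; 1000 features for null calibration of Fisher and OLS testing;
10,000 random t-vectors for the GSS dominance property; and, for class
discovery, ten generator seeds at n = 85 samples, four planted classes and
30 restarts over K = 2..6 — the same cohort geometry the workflow targets.

## Known limitations

The normalization is a housekeeping-only approximation of vendor pipelines
(no positive-control step). The DGE model is unmoderated OLS, which is
well-calibrated but less powerful than shrinkage estimators at very small n.
The dGSS sign convention follows the published vendor definition; other
sign conventions exist. The actionability rule table shipped under
`inst/extdata/` is a small synthetic illustration of the level-of-evidence
format, not a curated knowledge base, and real analyses should supply their
own table via `read_loe_table(path)`.
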