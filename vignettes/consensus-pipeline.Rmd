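---
title: "Consensus differential expression across genotype contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential expression across genotype contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two panels of genotypes differ in their tolerance of a stress --
here, sorghum lines that keep growing under nitrogen starvation versus
lines that do not -- the genes that *cause* the difference are hidden
among thousands of genes that differ between any two genotypes for
reasons unrelated to the stress. A single pairwise differential
expression (DE) contrast cannot separate the two. The approach
implemented in ndeg is a consensus scheme: compare *every* sensitive
genotype against *every* tolerant genotype (3 x 4 = 12 contrasts for the
canonical seven-genotype panel), count for each gene the number `n` of
contrasts in which it is a DEG, and additionally compare genotypes
*within* each panel. A gene that is a DEG in many cross-panel contrasts
but not among genotypes of the same panel is a candidate tolerance gene;
a gene that differs within a panel is genotype background and is
discarded no matter how often it appears across panels.

```{r, eval = FALSE}
library(ndeg)
sim <- simulate_counts(sim_params(seed = 1))
grid <- enumerate_comparisons(sim$design)
res <- run_comparisons(sim$counts, sim$design, grid)
excl <- within_group_exclusion(res[grid$type == "within_tolerant"],
                               res[grid$type == "within_sensitive"])
cons <- build_consensus(res[grid$type == "cross"], excl, n_min = 6)
glance(cons)
autoplot(cons)
```

## The per-pair test

Each pairwise contrast is an independent small RNA-seq experiment (4 vs
4 replicate libraries) and is analysed with the classical
exact-test machinery for negative-binomial (NB) counts:

1. **TMM normalization** on the two genotypes' columns. Scaling factors
   are the trimmed mean of gene-wise log ratios
   `M = log2((y_k/N_k)/(y_r/N_r))` against a reference sample, doubly
   trimmed (30% each side on M, 5% each side on the average abundance
   A), precision-weighted by the delta-method variance of M, and
   rescaled to geometric mean one. The reference is the sample whose
   library-size-standardized upper-quartile count (over nonzero genes)
   is closest to the mean; `tmm_factors(weighted = FALSE)` provides an
   unweighted variant for sensitivity checks. Genes with zero counts in
   all samples are dropped before factor computation.
2. **Common dispersion** by conditional maximum likelihood. All
   libraries are rescaled to their geometric-mean effective size
   (continuous pseudo-counts); given a gene's group total the NB
   conditional likelihood is free of the gene's mean, so one dispersion
   `phi` (`variance = mu + phi * mu^2`) is estimated by bounded
   one-dimensional search over `[1e-6, 10]`. This is the qCML idea with
   linear count rescaling rather than full quantile adjustment -- a
   deliberate, documented simplification; the estimate agrees with the
   reference qCML implementation to well within its sampling noise in
   the test suite.
3. **Conditional exact test**. Group sums of the equalized counts are
   rounded to integers; conditional on a gene's total, the group-A sum
   follows the distribution obtained by convolving NB replicates within
   each group (negative hypergeometric), which collapses to a binomial
   in the Poisson limit `phi = 0`. The two-sided p-value doubles the
   smaller tail, both tails including the observed outcome, capped at
   one -- so p is always in (0, 1].
4. **Multiplicity**: Benjamini-Hochberg within each comparison (not
   pooled across the twelve). Genes with a pairwise total count below 5
   are reported with p = FDR = 1 and excluded from the BH denominator so
   they do not dilute the FDR.
5. **Fold change**: `log2` of prior-augmented (0.125) mean normalized
   counts, with the *sensitive* genotype always the numerator, so
   positive values mean sensitive-abundant. A DEG is
   `|log2FC| >= 1` (ties significant) **and** `FDR < 0.001`.

### Numerical choices and degenerate inputs

Continuous pseudo-counts enter the likelihood unrounded; the exact test
sees rounded group sums, keeping the test exact on integers while
respecting normalization. The conditional distribution is evaluated in
log space and normalized before tail summation. Swapping the two groups
gives bitwise-identical p-values (the distribution is evaluated in a
canonical group order). A gene with total zero gets p = 1; two all-zero
groups get log2FC = 0 (equal priors). `optimize()` never returns an
interval endpoint, so the dispersion search explicitly prefers the
boundary when the conditional likelihood is monotone towards it
(Poisson-like data).

The doubled-tail exact test is *conservative* on discrete counts: both
tails contain the observed outcome's probability mass, so under the null
the p-value distribution sits slightly above uniform. At the simulated
depths used here the anti-conservative side of the Kolmogorov distance
to uniform is ~0.002 (well inside the 99% band) while the conservative
side reaches ~0.04; the null rejection rate at 0.05 is ~0.043-0.049.
The test suite asserts exactly this: no excess of small p-values, and
the nominal-level band [0.035, 0.065].

## Consensus, exclusion, direction

Membership `n` is the count of cross-panel contrasts in which a gene is
a DEG. The common-DEG list keeps genes with `n >= n_min` (default 6 of
12). Exclusion is applied *after* membership counting: a gene
significant in at least 5 of the 6 within-tolerant pairs or at least 2
of the 3 within-sensitive pairs is discarded as genotype background.
Within-group contrasts reuse the identical test and thresholds; their
sign convention is first-listed genotype over second.

Direction requires strict sign unanimity among a gene's significant
cells: all positive log fold changes give `sensitive_abundant`, all
negative `tolerant_abundant`, and any conflict `mixed`. Sign conflicts
are real -- a gene can be more abundant than one tolerant genotype and
less abundant than another -- so `mixed` genes stay in the common list
but belong to neither abundance class; the three classes partition the
list. Published-style tables are produced by `format_consensus_table()`,
printing significant cells to one decimal and marking non-significant
cells `"ns"` (or `"**"`).

## Enrichment

Over-representation of a DEG list in a flat term-to-gene annotation is
the hypergeometric upper tail `P(X >= m)` for the quadruple (N, M, n, m):
annotated universe, term size, DEGs in the universe, DEGs in the term.
DEGs without annotation are dropped from `n` (that is the definition of
`n` as "DEGs in N"). The `enriched` flag uses the raw p at 0.05 with no
multiplicity correction -- deliberately matching the convention this
analysis follows -- while a BH-adjusted column is emitted alongside for
readers who want it. The flat table is used as given: no GO-DAG ancestor
propagation is performed, so GO results are per-term, not per-subgraph.
Sensitive-abundant and tolerant-abundant lists are enriched separately.

## qPCR validation

`delta_delta_ct()` implements comparative 2^-ddCT quantification:
`dCT = mean CT(gene) - mean CT(control)` per genotype,
`ddCT = dCT(test) - dCT(reference)`, `RQ = 2^-ddCT`. Biological and
technical replicates are averaged together in CT space before
differencing (the pooling is not uniquely prescribed by convention; this
is the simplest choice and is stated, with the standard error propagated
from replicate variances by the delta method). RQ is exactly inverted by
swapping test and reference and is invariant to any global CT shift.
For concordance with RNA-seq, compute RQ with the sensitive genotype as
test and the tolerant genotype as reference so that `log2(RQ)` shares
the `log2(sensitive/tolerant)` orientation of the fold changes;
`compare_to_rnaseq()` then reports per-gene sign agreement and a
Spearman rank correlation.

## What the synthetic data emulates -- and what it does not

`simulate_counts()` mirrors the structure of the motivating study:
seven genotypes (three sensitive: CK60, BTx623, a low-NUE RIL bulk;
four tolerant: San Chi San, China17, KS78, a high-NUE bulk), four
biological replicates each, ~thousands of expressed genes, and NB count
noise. Per gene and sample the mean is `mu = L_s * p_g * 2^delta`:
`L_s` is the library depth (uniform 0.5-1.0 M by default -- a
desk-scale stand-in for tens-of-millions-read libraries; the shape of
the design, not the sequencing depth, is what the consensus procedure
exercises), `p_g` a log2-normal relative abundance (Normal(4, 2) on the
log2 scale, normalized), and `delta` the planted effect.

Three planted classes define the ground truth: tolerance DEGs elevated
in every tolerant genotype (default 100), tolerance DEGs elevated in
every sensitive genotype (100), and background DEGs perturbing exactly
one random genotype with a random sign (200), all at |log2FC| = 2. The
single-genotype construction is the minimal model of "unrelated
genotype differences" that the within-group exclusion filter targets; a
background gene touching one tolerant genotype is a DEG in only 3 of the
12 cross contrasts and so also fails the membership threshold -- the
two defences are redundant by design, which is why background exclusion
is near-total in practice.

Features of real data deliberately *not* modelled: gene-length and GC
bias, per-gene dispersion variation (a single common phi is both
simulated and estimated), correlated genes, unequal replicate quality,
batch effects, and multi-genotype background structure. Passing the
recovery tests therefore demonstrates that the statistical machinery and
the consensus logic are correct under their own assumptions -- not that
the thresholds are optimal for any particular real dataset.

Gene lengths are uniform 500-5000 bp (lengths are needed only for the
RPKM report and no canonical values exist for a synthetic genome). The
qPCR generator writes `CT = 25 - delta + noise` with three replicates
per gene/genotype, so one planted log2 unit is exactly one cycle, and it
refuses a control gene with a planted effect -- a reference gene must be
expression-stable.

## Problem sizes and tunable parameters

Defaults, all overridable: `lfc_threshold = 1` (log2 units),
`fdr_threshold = 0.001`, `n_min = 6` (of 12), `tolerant_exclude_min = 5`
(of 6), `sensitive_exclude_min = 2` (of 3), `enrich_alpha = 0.05` (raw),
`prior_count = 0.125` (normalized counts), `pseudocount = 1` (RPKM
units, log2 report only), TMM trims 0.30/0.05, dispersion search in
`[1e-6, 10]`, low-count filter at a pairwise total of 5.

The test suite exercises the full default scenario (5000 genes, 21
comparisons) once, plus ten 5000-gene null calibrations and an
integration scenario at 1000 genes with 0.1-0.2 M-read libraries; these
sizes were chosen so the whole suite runs in a couple of minutes on one
CPU while keeping every per-contrast sample size identical to the study
design (4 vs 4). `scripts/acceptance.R` re-runs the default scenario
end to end from a seed and reports the quantities it computes.

## Known limitations

The dispersion model is a single common phi per comparison; genes with
unusually high biological variability will be anti-conservative relative
to a tagwise model. BH is applied within comparisons, so membership
counts aggregate twelve separately-controlled FDRs rather than one joint
error rate -- matching the procedure this package reproduces, not
improving on it. The enrichment flag is uncorrected raw p <= 0.05 by the
same fidelity argument. Exact-test p-values are conservative at low
counts (see above). The pipeline starts at gene-level counts: read
processing, alignment and counting are out of scope.
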