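---
title: "Methods and design notes for pairomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pairomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairomics)
```

pairomics analyzes *normalized* gene-by-sample matrices — log2 FPKM from
RNA-seq, reporter-ion intensities from multiplexed proteomics, or ssGSEA
score matrices — and integrates pairs of such matrices measured on the same
experimental contrast. This vignette records the models, the parameters
that matter, the numerical conventions, and the choices we made where more
than one defensible convention exists. Normalization itself is out of
scope: the package assumes values are already on a comparable, roughly
log-like scale, and `log2_transform()` exists only for the common case of
linear-scale input.

## Data model

Expression data is a tibble whose first column holds unique gene
identifiers and whose remaining columns are numeric samples; sample
metadata is a two-column tibble (`sample`, `group`); gene sets are long
tibbles (`set`, `description`, `gene`) that round-trip through standard
GMT. Loading enforces the container invariants (unique genes and samples,
numeric or missing values). Two conventions were open and are fixed as
follows: duplicate gene rows collapse to the row with the highest mean
(the usual practice when probes or transcripts map to one symbol), and
blank or `NA` cells are kept as missing, with each downstream operation
stating its own missing-value policy (differential expression and
signal-to-noise drop incomplete genes and report them; clustering requires
an explicit opt-in to pairwise-complete distances; ssGSEA refuses missing
values because within-sample ranks would be undefined).

## Exploration

`rank_variable_genes()` scores each gene by raw median absolute deviation
(no 1.4826 consistency constant — we want the plain robust spread, not a
normal-σ estimate; this is documented because both conventions circulate)
or by sample variance, with lexicographic tie-breaking so rankings are
reproducible. The standard heatmap pipeline is: select the top-N variable
genes on the input scale, optionally log2-transform, z-normalize rows
(sample SD, n − 1), cluster. Ordering the selection before the transform
keeps "top variable" interpretable on the scale the user supplied; z-scores
computed after selection make distances comparable across genes.

`hierarchical_cluster()` wraps `stats::hclust` over `stats::dist`.
Euclidean distance on z-normalized rows is the default metric; `ward` is
Ward's minimum-variance criterion (`ward.D2`) and refuses non-Euclidean
metrics, where the criterion is undefined. Centroid linkage is fitted on
squared Euclidean distances, as it requires, and its merge heights are
mapped back to the distance scale; centroid trees may show inversions,
which is inherent to that linkage, while ward/average/complete heights are
monotone. Constant rows z-normalize to zero rather than NaN so a degenerate
gene cannot poison a distance matrix.

`compare_groups()` reports per-group n, median and quartiles plus a
two-sided test. The default is the Wilcoxon rank-sum test — exact when the
combined n is at most 12 and tie-free, otherwise the normal approximation
with tie and continuity correction — because group sizes in designed
knockdown experiments are small and normality is rarely credible; Welch's
t is available.

## Moderated-t differential expression

Two-group empirical-Bayes differential expression re-implements the
variance-shrinkage model that limma popularized, restricted deliberately
to the two-group design (no covariates, no trend or robust variants, no
count weights — inputs are already-normalized abundances). With pooled
variance $s_g^2$ on $d_g$ df, the prior $(d_0, s_0^2)$ is estimated by
moments matching on $\log s_g^2$ via the trigamma inverse, and

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
\tilde t_g = \frac{\overline{x}_{g,1}-\overline{x}_{g,2}}
{\tilde s_g \sqrt{1/n_1+1/n_2}} \sim t_{d_0+d_g}.$$

Numerical conventions: the moments estimate of $d_0$ is capped at $10^6$ so
a homoscedastic dataset (where the method-of-moments residual variance is
non-positive and the prior df is effectively infinite) stays finite and
stable; `prior_df` can be forced, with 0 recovering the ordinary pooled t
and `Inf` handled analytically ($\tilde s_g^2 = s_0^2$, normal reference).
Genes with any missing value in either group are dropped from the contrast
and listed in the fit; zero-variance genes are excluded from prior
estimation but still shrunk, so their statistics are finite. Default DE
classification is |log2FC| ≥ 1 — the conventional fold-change line for
volcano-style displays — with BH-adjusted p ≤ 0.05; the p-value threshold
and the adjusted/nominal switch are exposed because conventions differ
between labs.

A note on power that the test suite makes concrete: at the package's
reference design (6 treated vs 4 control, effect 2 log2 units, noise SD 1,
10% differential genes) the BH-0.05 median sensitivity computed by
`scripts/acceptance.R` is about 0.5, with observed FDR near 0.04. That is
what the noncentrality arithmetic predicts (≈ 3.1 against a BH-effective
cutoff near 0.003), and an independent limma fit on the same data gives the
same number — small designs detect roughly half of two-fold effects at
unit noise, and no moderated statistic changes that. FDR control, not
sensitivity, is the guarantee.

## Enrichment

**Ranking.** Signal-to-noise $(\mu_1-\mu_2)/(\sigma_1+\sigma_2)$ with each
group SD floored at $\max(0.2\,|\mu|, 0.2)$ — the floor (a desktop-GSEA
convention) stops near-constant genes from taking extreme ranks. Ties
break lexicographically; with fewer than 3 samples per group a warning is
raised.

**Enrichment score.** The weighted Kolmogorov–Smirnov running sum: hits
advance by $|r|^p / \sum_{hits}|r|^p$ (default $p = 1$; $p = 0$ gives the
unweighted KS statistic), misses retreat by $1/(N-N_h)$; the ES is the
signed maximum deviation. Ties between equal-magnitude positive and
negative extrema resolve to the positive one, with a $10^{-12}$ slack so
the choice is stable across algebraically equivalent computations. A set
covering the whole list has ES 1 by convention (there are no miss steps),
and if all hit scores are exactly zero the hit increments fall back to
equal steps. The leading edge is the hits at or before the positive
extremum (from the negative extremum onward for negative ES).

**Significance.** Phenotype permutation is the default null — group labels
are reshuffled and the whole ranking recomputed, which preserves
inter-gene correlation — and requires at least 7 samples; below that the
procedure switches, with a warning, to random same-size gene sets on the
observed ranking (mirroring desktop-GSEA guidance, since with 6 samples
there are too few distinct relabelings). NES divides ES by the mean |null
ES| of matching sign; the nominal p is the sign-matched one-sided fraction
with +1 smoothing in numerator and denominator (so p is never exactly 0);
the FDR q is the sign-stratified NES-ratio procedure with a final
monotonicity pass within each sign. A seed is mandatory: given the seed,
results are bit-identical across reruns. `precompute_summary_table()`
writes the per-collection summary TSV sorted by NES for later display and
filtering.

**ssGSEA.** Within each sample, genes get average ranks (so scores are
invariant under any strictly increasing transform of that sample), the
walk order is descending expression with lexicographic tie-breaks, and the
score is the summed difference between the rank-weighted in-set ECDF
($\mathrm{rank}^{\alpha}$, default $\alpha = 0.25$) and the unweighted
out-of-set ECDF. Scores are reported unnormalized by default; the optional
normalization divides the whole matrix by its range. Both parameters are
exposed because downstream users inherit whichever convention their
comparison data used. Only the rank-ECDF ssGSEA statistic is implemented —
the Gaussian-kernel GSVA statistic is a different estimator and out of
scope. Sets represented by a single measured gene are scored but warned
about.

## Integration of paired omics

The integration workflow assumes both matrices are analyzed under the same
declared contrast orientation (the tool refuses to guess sign
conventions). `compare_log2fc()` inner-joins the two DE tables, reports the
signed difference Δ = log2FC_A − log2FC_B (absolute value as a column) and
a quadrant label from the two classifications. `derive_signatures()`
extracts the four DE sets (up/down per matrix) as a GMT-ready collection —
empty signatures are recorded and skipped downstream. `reciprocal_gsea()`
tests A's signatures in B and B's in A; `reciprocal_ssgsea()` scores them
per sample on the reciprocal matrix and compares groups. On fully
concordant synthetic pairs the up-signatures enrich positively with p <
0.05 in essentially every seed; on independent pairs the sign is not
reproducible and p < 0.05 occurs at roughly the nominal rate — this
discrimination is asserted by the acceptance suite.

`overlap_stats()` reduces two gene sets over a declared universe to the
2×2 counts and reports one-sided Fisher p (enrichment is the question
asked; the two-sided test is an option), the sample odds ratio ad/bc,
Cohen's κ and the Jaccard index. κ is reported as `NA` when expected
agreement is 1 (both sets empty or both the whole universe) rather than
crashing on 0/0. The default universe for cross-omics comparisons is the
intersection of genes measured in both matrices: a gene absent from one
platform can never be called concordant, and counting it in `d` would
inflate agreement. `pathway_overlap_scan()` repeats the computation
against every set of a pathway collection (each intersected with the
universe) so that the cross-omics overlap can be ranked against curated
pathways.

## The synthetic generator

`simulate_paired_omics()` emulates the reference design: two omics
matrices over 6 treated vs 4 control samples, per-gene baselines uniform
on [2, 10] log2 units (a typical dynamic range for log-scale abundance),
i.i.d. Gaussian noise (default SD 1 log2 unit), and planted ±`effect_size`
shifts (default 2) for `n_de_up`/`n_de_down` genes (defaults 100/60 of
2000). The `concordance` fraction of A's differential genes carries the
identical shift in B, per direction so directional counts stay balanced;
the remainder of B's differential genes are re-drawn from genes unaffected
in A. The full truth table is returned, and everything is byte-identical
under a fixed seed.

What the generator deliberately does *not* emulate: count-level
(mean-variance) noise, normalization artifacts, batch structure,
inter-gene correlation, missing values, or platform-specific dynamic
ranges. Passing tests on this generator therefore demonstrate the
correctness and calibration of the statistics — not robustness to
real-data pathologies such as correlated nulls (which widen permutation
nulls) or uncorrected batch effects.

## Test and acceptance problem sizes

The suite checks exhaustive oracles on small inputs (all subsets of a
10-gene ranked list; ≤ 8-gene ssGSEA samples), permutation type-I error
over 200 null simulations at 200 permutations, shrinkage limits on 500
genes, recovery at the reference design over 20 seeds, and reciprocal
discrimination over 10 seeds per condition at 1000 permutations. These
sizes were chosen so the full suite completes in about a minute on a
single CPU while leaving Monte-Carlo margins comfortably wider than the
assertion bounds.

## Known limitations

Two-group contrasts only (no paired or multi-factor designs, no batch
covariates); no raw-count normalization; identifier mapping across
species or platforms is assumed done upstream; enrichment against remote
annotation services is intentionally replaced by the local Fisher
over-representation test; and sensitivity at small n is bounded by the
power arithmetic discussed above.
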