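---
title: "Methods: quantifying barcoded antigen in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying barcoded antigen in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antigentrace)
```

# Overview

`antigentrace` analyses experiments in which a protein antigen is conjugated
to a phosphorothioate-protected DNA barcode and captured, like a CITE-seq
antibody tag, alongside mRNA in droplet single-cell sequencing. Each cell
then carries two measurements: a gene-expression UMI vector and a per-tag
UMI count that is proportional to how much antigen the cell holds. The
package covers the full chain from raw tag reads to antigen-associated
marker genes. This vignette records the model behind each stage, the
parameters that matter, and the choices made where the method leaves room.

# Tag quantification

A tag read is a (cell barcode, UMI, tag barcode) triple. `collapse_umis()`
keeps reads whose cell barcode matches the whitelist exactly and whose tag
barcode is within Hamming distance 1 of a whitelisted tag. Tag whitelists
are validated to have pairwise distance ≥ 3 (`tag_whitelist()`), which makes
distance-1 correction unambiguous; `N` bases count as mismatches. Cell
barcodes are *not* corrected — cell-barcode recovery belongs to the upstream
cell-calling software and is orthogonal to tag counting.

Within each (cell, tag) group the count is the number of distinct UMIs.
Two merge policies are offered:

- `none` (default): exact deduplication.
- `hamming1_directional`: a UMI *u* is additionally absorbed by a more
  abundant UMI *v* when Hamming(u, v) = 1 and reads(v) ≥ 2·reads(u) − 1.
  This is implemented as a survivor-based greedy pass over UMIs sorted by
  read count (lexicographic tie-break for determinism), i.e. the pairwise
  directional rule without transitive network resolution; for the sparse
  UMI spaces of tag libraries the difference is negligible.

Plain deduplication is the default because upstream pipelines count tags
that way unless told otherwise. Audit tallies (`n_exact`, `n_corrected`,
`n_ambiguous`, `n_unmatched`, `n_duplicate_umi`) partition the input read
set exactly, which the tests assert.

# Preprocessing

`qc_filter()` keeps cells with detected genes strictly between 250 and 5000
and mitochondrial percentage strictly below 15%; all three inequalities are
strict, read literally from the thresholds they implement. Mitochondrial
genes are recognized by a configurable id prefix (`mt-` by default), and the
synthetic generator plants genes under that prefix so the filter is
exercised.

`lognormalize()` computes `ln(1 + count × 10⁴ / total)` per cell. The scale
factor 10⁴ and natural-log `log1p` mirror the defaults of the normalization
this step reproduces, which is cited by name but without numbers in the
protocols it follows.

`select_hvg()` ranks genes by standardized dispersion: genes are binned into
20 equal-occupancy bins by mean raw count, the per-bin median variance forms
a mean–variance trend, and each gene's variance is divided by its bin's
trend value. This is a deliberately simple, loess-free variant of
variance-stabilizing selection; ties (including the all-equal degenerate
case) break lexicographically by gene id so selection is deterministic.

`run_pca()` centers and scales each variable gene to unit variance, clips
scaled values at ±10 (standard practice so a single outlier cell cannot
dominate a component; the upstream method is silent on the cap), and takes
an exact SVD. Component signs are fixed by making the largest-magnitude
loading entry positive, so results are reproducible to the bit, not just up
to sign.

# Clustering and annotation

`cluster_cells()` builds a k-nearest-neighbour graph (k = 20, each cell's
neighbourhood includes itself), converts it to shared-nearest-neighbour
Jaccard weights, prunes edges below 1/15, and optimizes modularity with
Louvain at the requested resolution. k = 20 and the 1/15 pruning constant
follow the conventions of the graph-clustering stack this re-implements;
neither is derived from data.

`annotate_clusters()` is a reference-correlation annotator: each cluster's
mean log-expression over the variable genes is correlated (Spearman by
default, matching the cited annotation tool; Pearson available) against
per-type bulk reference profiles over the shared genes, and the cluster gets
the argmax type. Exact ties break by reference column order and are flagged;
assignments whose top1 − top2 correlation margin falls below `margin_min`
(default 0.02) are flagged ambiguous. The margin flag is a reporting device
motivated by the practical difficulty of separating closely related stromal
subtypes, not a calibrated threshold. Annotation is per cluster, not per
cell, exactly as the cluster-level tool it mirrors operates. Fewer than 10
shared genes is an error rather than a warning — a correlation over a
handful of genes is not an annotation.

# Relative antigen signal

Because capture efficiency varies between samples, raw tag counts are not
comparable across captures. T and B cells do not actively sample antigen,
so their tag counts estimate the ambient background of each sample:

\[ r_c = \frac{a_c}{\mathrm{median}\{a_{c'} : c' \in \text{T/B cells of the
sample}\}} \]

For log display a pseudocount of half the smallest positive \(r_c\) in the
sample is added. Both the divisor and the pseudocount are per sample, so
display values are comparable across samples only in units of their own
baseline.

A zero baseline median is not addressed by the procedure this implements;
silently dividing by zero is unacceptable, so `relative_signal()` falls back
to the median of the *positive* baseline counts, then to 1, and sets a
`baseline_degenerate` flag either way.

`compare_types()` mirrors the published per-type comparison tables:
two-sided Wilcoxon rank-sum on relative signal, Hodges–Lehmann estimate of
the median difference with a 95% confidence interval, and Bonferroni
correction with the family defined as the comparisons within one sample.
All pairs of types are compared by default (the published tables state
pairwise comparisons); a type-vs-pooled-reference mode is also available.

# Mixture classification

Antigen counts span roughly four orders of magnitude, so a Gaussian mixture
is only well-specified on the log scale; `classify_antigen()` fits on
`log10(r_c + pseudocount)`. The input scale is recorded in every fit object
because the choice is the package's, not dictated by the procedure it
follows.

`fit_gmm2()` is a standard two-component EM with unequal variances:

- **Initialization**: means at the 25th/75th percentiles, both sds at half
  the overall sd, weights ½/½. Deterministic quantile initialization is
  preferred over random restarts so identical inputs give identical fits;
  `n_restarts` adds seeded random initializations for robustness checks and
  keeps the best log-likelihood.
- **Convergence**: |Δ log-likelihood| < 1e-8 or 1000 iterations.
- **Degeneracy**: component sds are floored at 1e-3 × the overall sd so a
  component cannot collapse onto a single point; all-identical input is an
  error, as is n < 10.
- **Labeling**: components are ordered μ₁ < μ₂ and "high" is always the
  upper one; hard labels at posterior ≥ 0.5 (the usual convention; the
  procedure this reproduces states none).

The log-likelihood is asserted non-decreasing on every fit — a violated EM
monotonicity invariant is an implementation bug, so it raises an error
rather than a warning. Groups below 10 cells are skipped with a warning:
below that, a two-component fit is numerology.

# Marker detection

`find_markers()` computes, per gene, a midrank Mann–Whitney U between
antigen-high and antigen-low cells on log-normalized expression; AUC is
U/(n₁n₂). The p-value is exact (full enumeration of the rank-assignment
distribution) when the two groups total ≤ 12 cells without ties, otherwise
a normal approximation with tie and continuity corrections. logFC is the
difference of mean log-normalized expression (the convention of the
rank-test tool this mirrors — not the ratio-of-means convention of other
toolkits; the two differ near zero). Expression percentages use count > 0.
BH adjustment runs across all tested genes; genes silent in both classes
are reported untested rather than assigned p = 1.

The pass filter is `padj < 0.05 ∧ logFC > 0.25 ∧ AUC > 0.5 ∧ pct_in ≥ 50`,
with the percentage threshold inclusive ("at least 50%") and the others
strict, matching the filter set it implements.

# Statistical kernels

`wilcoxon_ranksum()` computes the exact null distribution of U by the
classical rank-sum count recursion c(u; m, n) = c(u−n; m−1, n) + c(u; m,
n−1) — equivalent to enumerating all C(m+n, m) rank assignments — whenever
the caller requests it or, in `auto` mode, when n₁+n₂ ≤ 12 and the pooled
data are tie-free. The two-sided exact p is 2·min(tails) capped at 1, the
most common convention; exact enumeration refuses ties and falls back to
the tie-corrected normal approximation with continuity correction. The test
suite checks the exact path against an independent brute-force `combn`
enumeration and against `stats::wilcox.test`.

`hodges_lehmann()` takes the median of all pairwise differences; the CI
comes from order statistics of the sorted differences indexed by the exact
U distribution (n₁+n₂ ≤ 40) or the normal-approximation index, with the
achieved level reported in the exact case.

`adjust_pvalues()` delegates Bonferroni and BH to `stats::p.adjust` and
implements the Benjamini–Krieger–Yekutieli two-stage step-up on top of BH:
stage 1 at q′ = q/(1+q) estimates the number of true nulls; stage 2 reruns
BH at q″ = q′·m/(m−r₁). Its natural output is a rejection set; an emulated
adjusted-p vector (BH-adjusted p × (1+q)(m−r₁)/m) is provided because
thresholding it at q reproduces the stage-2 rejections exactly. The
anti-conservativeness of BKY relative to BH (rejections ⊇ BH's at the same
q) holds under independence and is checked empirically in the tests, not
proven.

`fraction_diluted()` implements the proliferation-dye statistic
\(\sum_{i\ge 1} N_i/2^i \big/ \sum_{i\ge 0} N_i/2^i\): each observed cell in
generation *i* represents \(2^{-i}\) precursors, so the ratio is the
fraction of precursors that divided at least once. `quantify_standard_curve()`
fits Cq = slope·log₁₀(Q) + intercept by least squares, refuses non-negative
slopes, inverts for unknowns, normalizes to protein input, and flags
extrapolation outside the standard range.

# The synthetic generator

`sim_config()` / `simulate_counts()` define the study conditions every
downstream test runs under:

- **Composition**: four types (cDC2, LEC, Tcell, Bcell) mixed 4:4:1:1 —
  the myeloid-enriched sort scheme — at 2000 cells total.
- **Genes**: 1000 genes plus 10 `mt-` genes; negative binomial with mean 1
  and dispersion 0.5 (variance = μ + 0.5μ²), typical of UMI data at this
  depth; 30 disjoint signature genes per type at 4-fold elevated mean. With
  these settings cells detect ~400 genes, inside the (250, 5000) QC window.
- **Antigen tag**: per-cell counts are round(10^z) with z normal at log₁₀
  mean 1.0 (low) or 3.0 (high), sd 0.4. The two-decade separation and the
  overall four-decade span of the resulting counts reproduce the dynamic
  range the mixture classifier is designed for, and the log₁₀-normal law
  gives it a well-specified target. High fractions default to 0.7 (cDC2)
  and 0.1 (LEC); T/B types are forced low — they are the baseline, and the
  generator never grants them high-class draws.
- **Controls**: unconjugated tags are Poisson(0.05) — effectively
  undetectable, as unconjugated control tags are in practice.
- **Reads**: each true molecule emits 1 + Poisson(mean − 1) duplicate reads
  (shifted so every molecule is read once; the exact duplication law is
  irrelevant to collapse correctness) with per-base substitution probability
  0.001. Cell barcodes are 16 nt, UMIs 12 nt, tag barcodes 10 nt with
  pairwise distance ≥ 3 by construction.

Per-type high fractions, the log-means and the control rate are free
parameters of the generator, documented in the config — they are plausible
study conditions, not estimates of any particular dataset.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, gene–gene correlation beyond type signatures, read-level gene
expression, or any coupling between antigen class and gene expression.
Passing tests therefore demonstrate that the chain recovers the structure
the generator encodes — composition, signatures, mixture classes, baseline
normalization — not that it is robust to every artifact of real captures.

# Problem sizes and determinism

The test suite and workflow use 2000-cell simulations for end-to-end checks
(annotation ARI, mixture label agreement), 1000-observation mixtures over 50
seeds for parameter recovery, 200 label permutations over 1000 genes for the
FDR check, and exhaustive enumeration up to group sizes 6 for the exact-test
oracle — sizes at which every check runs in seconds to a few minutes on one
CPU while keeping Monte-Carlo error well below the asserted tolerances.
Every stochastic step is seeded; `run_pipeline()` re-run with the same
config and seed produces byte-identical tables, which the tests assert via
file hashes.

# Known limitations

- Cell barcodes are matched exactly; reads with corrupted cell barcodes are
  lost (tallied `n_unmatched`) rather than rescued.
- The directional UMI merge is single-pass greedy, not the full transitive
  network; counts can differ from network-based implementations on dense
  UMI neighbourhoods.
- Annotation assigns whole clusters: a cluster mixing two true types is
  annotated as one of them, and only the correlation margin hints at the
  problem.
- The mixture model is strictly two-component on one dimension; cell
  populations with genuinely trimodal antigen content would need model
  selection that is deliberately out of scope.
- BKY's adjusted-p emulation is exact for the stage-2 threshold but is not
  a published adjusted-p definition; the rejection set is the procedure's
  real output.
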