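# antigentrace

Quantitative analysis of DNA-barcoded protein antigens ("molecular tracking
devices") in droplet single-cell experiments.

## The problem

Protein antigens conjugated to phosphorothioate-protected DNA barcodes can be
captured alongside mRNA in feature-barcode single-cell sequencing, so that
every cell reports both its transcriptome and how much antigen it carries.
Turning those captures into biology requires a chain of quantitative steps:

1. **Tag quantification** — collapse raw tag reads (cell barcode + UMI + tag
   barcode) into a tags × cells UMI count matrix, correcting single-base tag
   errors and deduplicating PCR copies.
2. **Preprocessing** — filter cells on detected genes (>250 and <5000) and
   mitochondrial percentage (<15%), log-normalize
   (`ln(1 + count · 10⁴ / total)`), select variable genes, run PCA.
3. **Cell-type annotation** — cluster cells on a shared-nearest-neighbour
   graph (Louvain) and assign types by Spearman correlation of cluster mean
   profiles against bulk reference profiles.
4. **Relative antigen signal** — for each cell, tag count divided by the
   median tag count over T and B cells of the same sample (cells that do not
   actively sample antigen), `r_c = a_c / median(a_{T/B})`, displayed as
   `log10(r_c + p)` with pseudocount `p` = half the smallest positive `r_c`.
5. **Antigen-high/low classification** — a two-component Gaussian mixture on
   the log signal, fitted by EM, with hard labels at posterior 0.5.
6. **Marker genes** — Wilcoxon rank-sum + AUC per gene between antigen-high
   and antigen-low cells, keeping genes with BH-adjusted p < 0.05,
   logFC > 0.25, AUC > 0.5 and ≥50% of antigen-high cells expressing.

The package implements this chain as composable functions, together with the
rank-based statistical kernels the surrounding experiments use (exact
Wilcoxon rank-sum p-values, Hodges–Lehmann shift estimates with confidence
intervals, Bonferroni/BH/Benjamini–Krieger–Yekutieli two-stage FDR, the
proliferation-dye *fraction diluted* statistic, and qPCR standard-curve
quantification), and a synthetic-data generator that reproduces the
statistical structure of such captures so the whole chain is testable
without any external download.

## Worked example

```r
library(antigentrace)

cfg <- sim_config(seed = 1)        # 2000 cells, 4 types at 4:4:1:1
sim <- simulate_counts(cfg)

qc   <- qc_filter(sim$bundle)
norm <- run_pca(select_hvg(lognormalize(qc$bundle), n_hvg = 500), n_pcs = 40)
cl   <- cluster_cells(norm$pca_scores, seed = 1)
ann  <- annotate_clusters(norm, cl, make_reference(cfg))

sig  <- relative_signal(qc$bundle, "ova-psDNA", c("Tcell", "Bcell"),
                        ann$cell_types)
cls  <- classify_antigen(sig[!sig$cell_type %in% c("Tcell", "Bcell"), ],
                         grouping = "per_type")
cls$fits$cDC2
#> 2-component Gaussian mixture (log10(relative_signal + pseudocount))
#>   pi = 0.298/0.702  mu = 0.046/1.997  sd = 0.339/0.402
#>   loglik -848.080 after 13 iterations (converged)
```

The same chain as a narrated workflow lives under `analysis/`
(`01_simulate.R` … `05_classify_markers.R`); each stage prints what it found
and writes its summary tables under `results/`. On the default configuration
the run reports 4 clusters annotated to the 4 generating types (adjusted
Rand index 0.983 against truth), median relative ova signal 57.4 in cDC2
versus 0.9–1.1 in the baseline types, and per-type antigen-high fractions of
70.1% (cDC2) and 9.0% (LEC) against the generating 70%/10%, with 99.9%
per-cell agreement between mixture labels and the true class.

## Layout

- `R/` — the package: data model and IO, synthetic-data generator, tag
  quantification, QC/normalization/PCA, clustering and annotation, antigen
  signal, mixture classification, marker detection, statistical kernels,
  pipeline orchestration (`run_pipeline()` / `report_summary()`).
- `analysis/` — numbered workflow drivers over the package.
- `tests/testthat/` — unit, property and end-to-end tests with independent
  brute-force oracles.
- `vignettes/antigen-tracking.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations.
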