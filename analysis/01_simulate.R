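#!/usr/bin/env Rscript
# Stage 1: generate the synthetic feature-barcode capture that stands in for
# a barcoded-antigen single-cell experiment: 4 cell types (cDC2, LEC, T, B)
# mixed 4:4:1:1, NB gene counts with 4-fold type signatures, and an antigen
# tag whose per-cell counts follow a low/high log10-normal mixture
# (high fractions 0.7 / 0.1 / 0 / 0; T and B are the baseline).
library(antigentrace)

outdir <- "scratch/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
sim <- simulate_counts(cfg)

write_triplet_matrix(sim$bundle, outdir)
write_result_table(sim$truth$cells, file.path(outdir, "truth_cells.tsv"))
write_result_table(sim$truth$genes, file.path(outdir, "truth_genes.tsv"))
write_reference_profiles(make_reference(cfg), file.path(outdir, "reference.tsv"))
writeLines(paste(names(sim$truth$tag_barcodes), sim$truth$tag_barcodes,
                 sep = "\t"),
           file.path(outdir, "tag_barcodes.tsv"))

message(sprintf("simulated %d cells x %d genes + %d tags",
                ncol(sim$bundle$gene_counts), nrow(sim$bundle$gene_counts),
                nrow(sim$bundle$tag_counts)))
message(sprintf("antigen-high cells: %d of %d",
                sum(sim$truth$cells$true_antigen_class == "high"),
                nrow(sim$truth$cells)))
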