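#!/usr/bin/env Rscript
# Stage 2: regenerate raw tag reads (PCR duplicates + sequencing errors) from
# the simulated molecules, then recover the tags x cells UMI matrix by
# barcode matching and UMI collapsing, and audit the recovery against truth.
library(antigentrace)

datadir <- "scratch/data"
truth_cells <- read_result_table(file.path(datadir, "truth_cells.tsv"))
bars <- read.delim(file.path(datadir, "tag_barcodes.tsv"), header = FALSE)
tag_barcodes <- setNames(bars$V2, bars$V1)

# rebuild the truth object the read simulator needs
cfg <- sim_config(seed = 1)
sim <- simulate_counts(cfg)  # deterministic: identical to stage 1
stopifnot(identical(sim$truth$cells$cell_id, truth_cells$cell_id))

reads <- simulate_tag_reads(sim$truth, cfg)
message(sprintf("emitted %d reads for %d true molecules (duplication mean %.1f)",
                nrow(reads), sum(sim$truth$tag_counts),
                cfg$pcr_duplication_mean))

res <- collapse_umis(reads, tag_whitelist(tag_barcodes),
                     colnames(sim$truth$tag_counts))
audit <- data.frame(metric = names(res$audit), value = as.integer(res$audit))
write_result_table(audit, "results/tag_audit.tsv")

err <- sum(abs(res$tag_counts - sim$truth$tag_counts))
tot <- sum(sim$truth$tag_counts)
message(sprintf("count discrepancy vs truth: %d UMIs of %d (%.3f%%), driven by the %.1f%%/base error rate",
                err, tot, 100 * err / tot, 100 * cfg$seq_error_rate))
for (i in seq_len(nrow(audit)))
  message(sprintf("  %s: %d", audit$metric[i], audit$value[i]))
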