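#' Simulation configuration for synthetic antigen-tracking captures
#'
#' Defines the generative model used throughout testing: multiple cell types
#' with distinct negative-binomial gene signatures mixed at a 4:4:1:1-style
#' ratio, a conjugated antigen tag whose per-cell UMI counts follow a
#' two-component log10-normal (low/high) mixture with a type-specific high
#' fraction, near-zero Poisson counts for unconjugated control tags, and
#' negligible tag signal in the designated T/B baseline types (forced to the
#' low component).
#'
#' @param types cell-type names, in mixing order
#' @param mixing_ratio relative type weights (default 4:4:1:1)
#' @param n_cells total number of cells (split by `mixing_ratio` unless
#'   `n_cells_per_type` is given)
#' @param n_cells_per_type optional named vector overriding the split
#' @param n_genes number of non-mitochondrial genes
#' @param n_mito_genes genes carrying `mito_prefix` (QC fodder)
#' @param mito_prefix mitochondrial gene-id prefix
#' @param n_signature_genes signature genes per type (disjoint blocks)
#' @param baseline_gene_mean NB mean for non-signature genes
#' @param signature_fold mean multiplier on a type's signature genes (> 1)
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2)
#' @param tag_ids tag names; the first is the conjugated antigen tag, the
#'   rest are unconjugated controls
#' @param antigen_high_fraction named per-type probability of the high class
#'   (baseline types are forced to 0)
#' @param antigen_low_logmean,antigen_high_logmean log10-scale means of the
#'   two tag-count components
#' @param antigen_logsd log10-scale sd of both components
#' @param control_tag_rate Poisson mean for control-tag counts
#' @param baseline_types types forming the T/B normalization baseline
#' @param pcr_duplication_mean mean reads per true UMI (>= 1, shifted Poisson)
#' @param seq_error_rate per-base substitution probability in simulated reads
#' @param cell_barcode_len,umi_len,tag_barcode_len barcode widths (>= 4)
#' @param sample_label,timepoint_label,fraction_label metadata labels
#' @param seed RNG seed; identical config + seed gives bit-identical output
#' @return validated `SimConfig` list
#' @export
sim_config <- function(types = c("cDC2", "LEC", "Tcell", "Bcell"),
                       mixing_ratio = c(4, 4, 1, 1),
                       n_cells = 2000,
                       n_cells_per_type = NULL,
                       n_genes = 1000,
                       n_mito_genes = 10,
                       mito_prefix = "mt-",
                       n_signature_genes = 30,
                       baseline_gene_mean = 1,
                       signature_fold = 4,
                       nb_dispersion = 0.5,
                       tag_ids = c("ova-psDNA", "psDNA", "pDNA"),
                       antigen_high_fraction = c(cDC2 = 0.7, LEC = 0.1,
                                                 Tcell = 0, Bcell = 0),
                       antigen_low_logmean = 1.0,
                       antigen_high_logmean = 3.0,
                       antigen_logsd = 0.4,
                       control_tag_rate = 0.05,
                       baseline_types = c("Tcell", "Bcell"),
                       pcr_duplication_mean = 3,
                       seq_error_rate = 0.001,
                       cell_barcode_len = 16,
                       umi_len = 12,
                       tag_barcode_len = 10,
                       sample_label = "S1",
                       timepoint_label = "d2",
                       fraction_label = "sorted",
                       seed = 1L) {
  if (anyDuplicated(types)) stop("config error: duplicate type names")
  if (length(mixing_ratio) != length(types) || any(mixing_ratio <= 0))
    stop("config error: mixing_ratio must be positive, one weight per type")
  if (!all(names(antigen_high_fraction) %in% types))
    stop("config error: unknown type in antigen_high_fraction: ",
         paste(setdiff(names(antigen_high_fraction), types), collapse = ", "))
  if (any(antigen_high_fraction < 0 | antigen_high_fraction > 1))
    stop("config error: antigen_high_fraction must lie in [0, 1]")
  if (!all(baseline_types %in% types))
    stop("config error: unknown baseline type")
  if (seq_error_rate < 0 || seq_error_rate > 1)
    stop("config error: seq_error_rate must lie in [0, 1]")
  if (pcr_duplication_mean < 1)
    stop("config error: pcr_duplication_mean must be >= 1")
  if (min(cell_barcode_len, umi_len, tag_barcode_len) < 4)
    stop("config error: barcode lengths must be >= 4")
  if (signature_fold < 1) stop("config error: signature_fold must be >= 1")
  if (baseline_gene_mean <= 0 || nb_dispersion <= 0 || antigen_logsd <= 0)
    stop("config error: gene/tag distribution parameters must be positive")
  if (is.null(n_cells_per_type)) {
    n_cells_per_type <- round(n_cells * mixing_ratio / sum(mixing_ratio))
    names(n_cells_per_type) <- types
  } else {
    if (!all(names(n_cells_per_type) %in% types))
      stop("config error: unknown type in n_cells_per_type")
    n_cells_per_type <- n_cells_per_type[types[types %in% names(n_cells_per_type)]]
  }
  hf <- stats::setNames(rep(0, length(types)), types)
  hf[names(antigen_high_fraction)] <- antigen_high_fraction
  hf[baseline_types] <- 0  # T/B designated types are always antigen-low
  structure(list(
    types = types, mixing_ratio = mixing_ratio,
    n_cells_per_type = n_cells_per_type,
    n_genes = n_genes, n_mito_genes = n_mito_genes,
    mito_prefix = mito_prefix, n_signature_genes = n_signature_genes,
    baseline_gene_mean = baseline_gene_mean,
    signature_fold = signature_fold, nb_dispersion = nb_dispersion,
    tag_ids = tag_ids, antigen_high_fraction = hf,
    antigen_low_logmean = antigen_low_logmean,
    antigen_high_logmean = antigen_high_logmean,
    antigen_logsd = antigen_logsd,
    control_tag_rate = control_tag_rate,
    baseline_types = baseline_types,
    pcr_duplication_mean = pcr_duplication_mean,
    seq_error_rate = seq_error_rate,
    cell_barcode_len = cell_barcode_len, umi_len = umi_len,
    tag_barcode_len = tag_barcode_len,
    sample_label = sample_label, timepoint_label = timepoint_label,
    fraction_label = fraction_label,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

# deterministic tag barcode whitelist with pairwise Hamming distance >= 3:
# homopolymer codewords for <= 4 tags, greedy rejection sampling beyond
default_tag_barcodes <- function(tag_ids, width) {
  n <- length(tag_ids)
  if (n <= 4) {
    codes <- vapply(DNA_BASES[seq_len(n)], function(b)
      strrep(b, width), character(1))
  } else {
    # greedy rejection sampling; consumes the caller's RNG stream, so it is
    # deterministic under the simulation seed
    codes <- character(0)
    while (length(codes) < n) {
      cand <- paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
      if (all(vapply(codes, function(c) hamming_distance(c, cand) >= 3,
                     logical(1))))
        codes <- c(codes, cand)
    }
  }
  stats::setNames(unname(codes), tag_ids)
}

#' Simulate a synthetic feature-barcode capture with ground truth
#'
#' Gene counts are negative binomial with mean `baseline_gene_mean`,
#' multiplied by `signature_fold` on the cell type's signature genes.
#' Conjugated-tag counts are `round(10^z)` with
#' `z ~ N(low or high logmean, logsd)` according to a Bernoulli draw at the
#' type's high fraction (baseline types always low). Control tags are
#' Poisson(`control_tag_rate`). Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()]
#' @return list with `bundle` (a [counts_bundle()]) and `truth` (list with
#'   per-cell table `cells`, per-gene table `genes`, tag count matrix
#'   `tag_counts`, tag barcode whitelist `tag_barcodes`, and the `config`)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  types <- config$types
  n_per <- config$n_cells_per_type
  n_cells <- sum(n_per)
  cell_type <- rep(types, times = n_per)
  cell_ids <- random_barcodes(n_cells, config$cell_barcode_len)

  gene_ids <- c(sprintf("gene%04d", seq_len(config$n_genes)),
                if (config$n_mito_genes > 0)
                  sprintf("%sgene%02d", config$mito_prefix,
                          seq_len(config$n_mito_genes)))
  n_genes_all <- length(gene_ids)
  is_sig_of <- rep(NA_character_, n_genes_all)
  sig_sets <- vector("list", length(types)); names(sig_sets) <- types
  for (i in seq_along(types)) {
    idx <- ((i - 1) * config$n_signature_genes + 1):(i * config$n_signature_genes)
    if (max(idx) > config$n_genes)
      stop("config error: not enough genes for disjoint signatures")
    sig_sets[[i]] <- gene_ids[idx]
    is_sig_of[idx] <- types[i]
  }

  mu_base <- matrix(config$baseline_gene_mean, nrow = n_genes_all,
                    ncol = length(types), dimnames = list(gene_ids, types))
  for (ty in types)
    mu_base[sig_sets[[ty]], ty] <- config$baseline_gene_mean * config$signature_fold

  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, nrow = n_genes_all, ncol = n_cells,
                   dimnames = list(gene_ids, cell_ids))
  for (ty in types) {
    cols <- which(cell_type == ty)
    mu <- mu_base[, ty]
    counts[, cols] <- stats::rnbinom(n_genes_all * length(cols),
                                     mu = mu, size = size)
  }

  # antigen tag: two-component log10-normal mixture
  hf <- config$antigen_high_fraction[cell_type]
  is_high <- stats::runif(n_cells) < hf
  z <- stats::rnorm(n_cells,
                    mean = ifelse(is_high, config$antigen_high_logmean,
                                  config$antigen_low_logmean),
                    sd = config$antigen_logsd)
  conj_counts <- as.integer(round(10^z))
  tag_counts <- matrix(0L, nrow = length(config$tag_ids), ncol = n_cells,
                       dimnames = list(config$tag_ids, cell_ids))
  tag_counts[1, ] <- conj_counts
  if (length(config$tag_ids) > 1) {
    for (k in 2:length(config$tag_ids))
      tag_counts[k, ] <- stats::rpois(n_cells, config$control_tag_rate)
  }

  meta <- data.frame(sample = rep(config$sample_label, n_cells),
                     timepoint = config$timepoint_label,
                     fraction = config$fraction_label,
                     row.names = cell_ids)
  bundle <- counts_bundle(
    Matrix::Matrix(counts, sparse = TRUE),
    Matrix::Matrix(tag_counts, sparse = TRUE),
    meta
  )
  truth <- list(
    cells = data.frame(
      cell_id = cell_ids,
      true_type = cell_type,
      true_antigen_class = ifelse(is_high, "high", "low"),
      true_tag_umi_count = conj_counts,
      stringsAsFactors = FALSE
    ),
    genes = data.frame(gene_id = gene_ids, is_signature_of = is_sig_of,
                       stringsAsFactors = FALSE),
    tag_counts = tag_counts,
    tag_barcodes = default_tag_barcodes(config$tag_ids,
                                        config$tag_barcode_len),
    config = config
  )
  list(bundle = bundle, truth = truth)
}

#' Simulate raw tag reads from a simulated truth
#'
#' For every true UMI of every (cell, tag) pair, emits `1 + Poisson(mean - 1)`
#' duplicate reads (shifted Poisson, so every molecule is read at least
#' once), then substitutes each base independently with probability
#' `config$seq_error_rate`. UMIs are drawn uniquely within their (cell, tag)
#' group.
#'
#' @param truth the `truth` component of [simulate_counts()]
#' @param config the matching [sim_config()]
#' @return data.frame of reads with columns `cell`, `umi`, `tag` (tag barcode
#'   sequence), in emission order
#' @export
simulate_tag_reads <- function(truth, config) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(truth$tag_counts)) stop("truth lacks per-cell tag counts")
  set.seed(config$seed + 1L)
  tc <- truth$tag_counts
  bars <- truth$tag_barcodes
  cells <- colnames(tc)
  recs <- list()
  for (t in rownames(tc)) {
    nz <- which(tc[t, ] > 0)
    for (ci in nz) {
      k <- tc[t, ci]
      umis <- random_barcodes(k, config$umi_len)
      dups <- 1L + stats::rpois(k, config$pcr_duplication_mean - 1)
      recs[[length(recs) + 1L]] <- data.frame(
        cell = cells[ci],
        umi = rep(umis, dups),
        tag = bars[[t]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(recs))
    return(data.frame(cell = character(0), umi = character(0),
                      tag = character(0)))
  reads <- do.call(rbind, recs)
  rownames(reads) <- NULL
  if (config$seq_error_rate > 0) {
    reads$cell <- mutate_sequences(reads$cell, config$seq_error_rate)
    reads$umi <- mutate_sequences(reads$umi, config$seq_error_rate)
    reads$tag <- mutate_sequences(reads$tag, config$seq_error_rate)
  }
  reads
}

#' Reference expression profiles implied by a simulation config
#'
#' The per-type expected log-expression profile of the generator (baseline
#' mean times signature fold on the type's signature genes), log-normalized
#' the same way as observed cells, suitable as an annotation reference.
#'
#' @param config a [sim_config()]
#' @param scale_factor normalization scale factor (default 1e4)
#' @return list with `type_names`, `gene_ids`, `mean_expr` (genes x types,
#'   log scale)
#' @export
make_reference <- function(config, scale_factor = 1e4) {
  stopifnot(inherits(config, "SimConfig"))
  gene_ids <- c(sprintf("gene%04d", seq_len(config$n_genes)),
                if (config$n_mito_genes > 0)
                  sprintf("%sgene%02d", config$mito_prefix,
                          seq_len(config$n_mito_genes)))
  m <- matrix(config$baseline_gene_mean, nrow = length(gene_ids),
              ncol = length(config$types),
              dimnames = list(gene_ids, config$types))
  for (i in seq_along(config$types)) {
    idx <- ((i - 1) * config$n_signature_genes + 1):(i * config$n_signature_genes)
    m[idx, i] <- config$baseline_gene_mean * config$signature_fold
  }
  expr <- apply(m, 2, function(mu) log1p(mu * scale_factor / sum(mu)))
  rownames(expr) <- gene_ids
  list(type_names = config$types, gene_ids = gene_ids, mean_expr = expr)
}
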