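#' QC and preprocessing parameters
#'
#' Thresholds follow the preprocessing conventions of droplet single-cell
#' analysis: cells are kept when the number of detected genes lies strictly
#' between `min_genes` and `max_genes` and the mitochondrial read percentage
#' is strictly below `max_mito_pct`. All inequalities are strict.
#'
#' @param min_genes exclusive lower bound on detected genes (default 250)
#' @param max_genes exclusive upper bound on detected genes (default 5000)
#' @param max_mito_pct exclusive upper bound on mitochondrial percent
#'   (default 15)
#' @param mito_gene_prefix gene-id prefix marking mitochondrial genes
#' @param scale_factor library-size scale factor for log-normalization
#' @param n_hvg number of highly variable genes (default 2000)
#' @param n_pcs number of principal components (default 40)
#' @return validated `QCParams` list
#' @export
qc_params <- function(min_genes = 250, max_genes = 5000, max_mito_pct = 15,
                      mito_gene_prefix = "mt-", scale_factor = 1e4,
                      n_hvg = 2000, n_pcs = 40) {
  if (!(min_genes >= 0 && min_genes < max_genes))
    stop("require 0 <= min_genes < max_genes")
  if (!(max_mito_pct > 0 && max_mito_pct <= 100))
    stop("max_mito_pct must lie in (0, 100]")
  if (n_pcs > n_hvg) stop("n_pcs must not exceed n_hvg")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_pct = max_mito_pct,
                 mito_gene_prefix = mito_gene_prefix,
                 scale_factor = scale_factor, n_hvg = n_hvg, n_pcs = n_pcs),
            class = "QCParams")
}

cell_qc_metrics <- function(bundle, params) {
  gc <- bundle$gene_counts
  detected <- Matrix::colSums(gc > 0)
  total <- Matrix::colSums(gc)
  mito <- startsWith(rownames(gc), params$mito_gene_prefix)
  mito_counts <- if (any(mito)) Matrix::colSums(gc[mito, , drop = FALSE]) else
    rep(0, ncol(gc))
  mito_pct <- ifelse(total > 0, 100 * mito_counts / total, 0)
  data.frame(cell_id = colnames(gc), detected_genes = as.integer(detected),
             total_counts = as.numeric(total), mito_pct = as.numeric(mito_pct),
             stringsAsFactors = FALSE)
}

#' Filter cells on detected genes and mitochondrial content
#'
#' Keeps cells with detected genes strictly greater than `min_genes`,
#' strictly fewer than `max_genes`, and mitochondrial percentage strictly
#' below `max_mito_pct`. A cell with exactly `min_genes` detected genes is
#' removed.
#'
#' @param bundle a [counts_bundle()]
#' @param params a [qc_params()]
#' @return list with `bundle` (filtered) and `report` (per-cell data.frame
#'   with metrics, `pass`, and comma-joined `fail_reason`)
#' @export
qc_filter <- function(bundle, params = qc_params()) {
  qc <- cell_qc_metrics(bundle, params)
  low <- qc$detected_genes <= params$min_genes
  high <- qc$detected_genes >= params$max_genes
  mito <- qc$mito_pct >= params$max_mito_pct
  pass <- !(low | high | mito)
  reason <- vapply(seq_len(nrow(qc)), function(i) {
    r <- c(if (low[i]) "low_genes", if (high[i]) "high_genes",
           if (mito[i]) "high_mito")
    if (length(r)) paste(r, collapse = ",") else ""
  }, character(1))
  report <- cbind(qc, pass = pass, fail_reason = reason,
                  stringsAsFactors = FALSE)
  if (!any(pass))
    warning("no cells survive QC filtering; returning an empty bundle")
  list(bundle = subset_bundle(bundle, pass), report = report)
}

#' Log-normalize gene counts
#'
#' Per cell: value = ln(1 + count * scale_factor / total_counts_of_cell).
#' Cells with zero total counts yield all-zero columns with a warning.
#' The returned object also carries the raw counts, detected-gene and
#' mitochondrial metrics, and (after [select_hvg()] / [run_pca()]) the HVG
#' set, scaled matrix and PCA results.
#'
#' @param bundle a [counts_bundle()]
#' @param params a [qc_params()]
#' @return object of class `NormalizedMatrix`
#' @export
lognormalize <- function(bundle, params = qc_params()) {
  gc <- bundle$gene_counts
  if (ncol(gc) < 1) stop("at least one cell required")
  totals <- Matrix::colSums(gc)
  if (any(totals == 0))
    warning(sum(totals == 0), " cell(s) with zero total counts")
  f <- ifelse(totals > 0, params$scale_factor / totals, 0)
  log_expr <- methods::as(methods::as(gc, "CsparseMatrix"), "generalMatrix")
  if (length(log_expr@x))
    log_expr@x <- log1p(log_expr@x * rep.int(f, diff(log_expr@p)))
  qc <- cell_qc_metrics(bundle, params)
  structure(list(
    log_expr = log_expr,
    counts = gc,
    detected_genes = stats::setNames(qc$detected_genes, qc$cell_id),
    mito_pct = stats::setNames(qc$mito_pct, qc$cell_id),
    params = params,
    hvg_ids = NULL, scaled_expr = NULL,
    pca_scores = NULL, pca_loadings = NULL, pca_var = NULL
  ), class = "NormalizedMatrix")
}

#' Select highly variable genes by standardized dispersion
#'
#' Fits a mean-variance trend on the raw counts by binning genes into
#' equal-occupancy mean bins and taking the per-bin median variance, then
#' ranks genes by variance / trend. Ties (and the all-identical degenerate
#' case) break deterministically by gene id.
#'
#' @param norm a [lognormalize()] result
#' @param n_hvg number of genes to keep (default from params)
#' @param n_bins number of mean bins for the trend (default 20)
#' @return the `NormalizedMatrix` with `hvg_ids` filled
#' @export
select_hvg <- function(norm, n_hvg = norm$params$n_hvg, n_bins = 20) {
  counts <- norm$counts
  ng <- nrow(counts)
  if (n_hvg > ng) {
    warning("n_hvg (", n_hvg, ") exceeds gene count (", ng,
            "); returning all genes")
    n_hvg <- ng
  }
  mu <- Matrix::rowMeans(counts)
  v <- Matrix::rowMeans(counts^2) - mu^2
  v <- v * ncol(counts) / max(1, ncol(counts) - 1)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = max(1, min(n_bins, ng)), labels = FALSE)
  trend <- stats::ave(v, bins, FUN = stats::median)
  std_var <- ifelse(trend > 0, v / trend, 0)
  ord <- order(-std_var, rownames(counts))
  norm$hvg_ids <- rownames(counts)[ord][seq_len(n_hvg)]
  norm
}

#' Scale HVGs and run PCA
#'
#' Each HVG row of the log-normalized matrix is centered and scaled to unit
#' variance, clipped at +/-10 to keep outlier cells from dominating, and the
#' cells x HVG matrix is decomposed by exact SVD. Component signs are fixed
#' by making the largest-magnitude loading entry of each component positive,
#' so scores are fully deterministic.
#'
#' @param norm a `NormalizedMatrix` with `hvg_ids` set (via [select_hvg()])
#' @param n_pcs number of components (default from params); must satisfy
#'   n_pcs <= min(n_hvg, n_cells - 1)
#' @param clip absolute cap on scaled values (default 10)
#' @return the `NormalizedMatrix` with `scaled_expr`, `pca_scores`
#'   (cells x n_pcs), `pca_loadings` and `pca_var` (per-component variance
#'   explained, decreasing) filled
#' @export
run_pca <- function(norm, n_pcs = norm$params$n_pcs, clip = 10) {
  if (is.null(norm$hvg_ids)) stop("run select_hvg() first")
  n_cells <- ncol(norm$log_expr)
  if (n_pcs > min(length(norm$hvg_ids), n_cells - 1))
    stop("n_pcs (", n_pcs, ") exceeds min(n_hvg, n_cells - 1)")
  x <- as.matrix(norm$log_expr[norm$hvg_ids, , drop = FALSE])
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  scaled <- (x - mu) / ifelse(sd > 0, sd, 1)
  scaled[sd == 0, ] <- 0
  scaled <- pmin(pmax(scaled, -clip), clip)
  sv <- svd(t(scaled), nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  loadings <- sv$v
  for (k in seq_len(n_pcs)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- colnames(norm$log_expr)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(loadings) <- norm$hvg_ids
  colnames(loadings) <- colnames(scores)
  norm$scaled_expr <- scaled
  norm$pca_scores <- scores
  norm$pca_loadings <- loadings
  norm$pca_var <- sv$d[seq_len(n_pcs)]^2 / max(1, n_cells - 1)
  norm
}
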