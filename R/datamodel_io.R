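#' Construct a CountsBundle
#'
#' A CountsBundle holds the two count blocks of a feature-barcode single-cell
#' capture — gene UMI counts and antigen-tag UMI counts — over the same
#' ordered set of cells, plus per-cell metadata. Column order of both
#' matrices and row order of the metadata are identical by construction.
#'
#' @param gene_counts genes x cells matrix of non-negative integer UMI counts
#'   (rownames = gene ids, colnames = cell barcodes)
#' @param tag_counts tags x cells matrix of non-negative integer UMI counts
#'   over the same cells
#' @param cell_meta per-cell data.frame with columns `sample`, `timepoint`,
#'   `fraction` (defaults filled if NULL)
#' @return object of class `CountsBundle`
#' @export
counts_bundle <- function(gene_counts, tag_counts, cell_meta = NULL) {
  gene_counts <- methods::as(methods::as(gene_counts, "CsparseMatrix"), "generalMatrix")
  tag_counts <- methods::as(methods::as(tag_counts, "CsparseMatrix"), "generalMatrix")
  # Matrix normalizes empty dimnames to NULL, so zero-extent margins are
  # exempt from the naming requirement
  named <- function(m, margin) dim(m)[margin] == 0 ||
    !is.null(dimnames(m)[[margin]])
  if (!named(gene_counts, 1) || !named(gene_counts, 2))
    stop("gene_counts must have row (gene) and column (cell) names")
  if (!named(tag_counts, 1))
    stop("tag_counts must have row (tag) names")
  cells <- colnames(gene_counts)
  if (is.null(cells)) cells <- character(0)
  tag_cells <- colnames(tag_counts)
  if (ncol(tag_counts) != ncol(gene_counts) ||
      (!is.null(tag_cells) && !identical(tag_cells, cells)))
    stop("gene and tag matrices must cover the same cells in the same order")
  if (length(cells)) colnames(tag_counts) <- cells
  if (anyDuplicated(cells))
    stop("duplicate cell barcode: ", cells[anyDuplicated(cells)])
  if (anyDuplicated(rownames(gene_counts)))
    stop("duplicate gene id: ", rownames(gene_counts)[anyDuplicated(rownames(gene_counts))])
  if (anyDuplicated(rownames(tag_counts)))
    stop("duplicate tag id: ", rownames(tag_counts)[anyDuplicated(rownames(tag_counts))])
  for (m in list(gene_counts, tag_counts)) {
    if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x))))
      stop("counts must be non-negative integers")
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(sample = rep("S1", length(cells)),
                            timepoint = rep("t0", length(cells)),
                            fraction = rep("all", length(cells)),
                            row.names = cells)
  } else {
    if (nrow(cell_meta) != length(cells))
      stop("cell_meta must have one row per cell")
    rownames(cell_meta) <- cells
  }
  structure(
    list(gene_counts = gene_counts, tag_counts = tag_counts,
         cell_meta = cell_meta),
    class = "CountsBundle"
  )
}

#' @export
print.CountsBundle <- function(x, ...) {
  cat("CountsBundle:", nrow(x$gene_counts), "genes,",
      nrow(x$tag_counts), "tags,", ncol(x$gene_counts), "cells\n")
  invisible(x)
}

#' Cell ids of a CountsBundle
#' @param bundle a CountsBundle
#' @return character vector of cell barcodes
#' @export
bundle_cells <- function(bundle) {
  cells <- colnames(bundle$gene_counts)
  if (is.null(cells)) character(0) else cells
}

#' Read a sparse triplet (MatrixMarket) feature-barcode matrix
#'
#' Reads the 10x-style trio of files — a MatrixMarket coordinate matrix,
#' a features table and a barcodes list — and splits features into gene and
#' antigen-tag blocks by their feature-class column. The features table is
#' tab-separated with the feature id in the first column and the feature
#' class in the last column (2 or 3 columns accepted, matching the
#' id / id+name layouts). Cells listed in the barcodes file but absent from
#' the triplets are kept as all-zero columns.
#'
#' @param matrix_path path to the MatrixMarket coordinate file
#' @param features_path path to the features TSV
#' @param barcodes_path path to the barcodes list (one per line)
#' @param gene_class,tag_class feature-class strings identifying gene and tag
#'   rows (defaults follow the feature-barcode convention)
#' @return a [counts_bundle()]
#' @export
read_triplet_matrix <- function(matrix_path, features_path, barcodes_path,
                                gene_class = "Gene Expression",
                                tag_class = "Antibody Capture") {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop("matrix format error: ",
                                         conditionMessage(e), call. = FALSE))
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  feats <- utils::read.delim(features_path, header = FALSE,
                             colClasses = "character")
  if (ncol(feats) < 2)
    stop("features table must have an id column and a feature-class column")
  ids <- feats[[1]]
  classes <- feats[[ncol(feats)]]
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(ids))
    stop("format error: matrix header claims ", nrow(m),
         " features but features table lists ", length(ids))
  if (ncol(m) != length(barcodes))
    stop("format error: matrix header claims ", ncol(m),
         " cells but barcodes file lists ", length(barcodes))
  dup <- barcodes[duplicated(barcodes)]
  if (length(dup))
    stop("format error: duplicate barcode: ", dup[1])
  rownames(m) <- ids
  colnames(m) <- barcodes
  is_tag <- classes == tag_class
  is_gene <- !is_tag  # anything not tagged as a tag is treated as expression
  if (!any(is_gene)) stop("no gene-class features found")
  gene_m <- m[is_gene, , drop = FALSE]
  if (any(is_tag)) {
    tag_m <- m[is_tag, , drop = FALSE]
  } else {
    tag_m <- Matrix::Matrix(0, nrow = 0, ncol = ncol(m), sparse = TRUE,
                            dimnames = list(character(0), barcodes))
  }
  counts_bundle(gene_m, tag_m)
}

#' Write a CountsBundle as a triplet-matrix trio
#'
#' Inverse of [read_triplet_matrix()]: writes the stacked gene+tag matrix in
#' MatrixMarket coordinate format plus features and barcodes files into
#' `dir`.
#'
#' @param bundle a CountsBundle
#' @param dir output directory (created if missing)
#' @param gene_class,tag_class feature-class labels to write
#' @return invisibly, the three paths written
#' @export
write_triplet_matrix <- function(bundle, dir,
                                 gene_class = "Gene Expression",
                                 tag_class = "Antibody Capture") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stacked <- rbind(bundle$gene_counts, bundle$tag_counts)
  mp <- file.path(dir, "matrix.mtx")
  fp <- file.path(dir, "features.tsv")
  bp <- file.path(dir, "barcodes.tsv")
  Matrix::writeMM(stacked, mp)
  feats <- data.frame(
    id = c(rownames(bundle$gene_counts), rownames(bundle$tag_counts)),
    name = c(rownames(bundle$gene_counts), rownames(bundle$tag_counts)),
    class = c(rep(gene_class, nrow(bundle$gene_counts)),
              rep(tag_class, nrow(bundle$tag_counts)))
  )
  utils::write.table(feats, fp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(bundle_cells(bundle), bp)
  invisible(c(matrix = mp, features = fp, barcodes = bp))
}

#' Subset a CountsBundle by a cell mask
#'
#' @param bundle a CountsBundle
#' @param cell_mask logical vector, one entry per cell
#' @return CountsBundle restricted to the masked cells, order preserved
#' @export
subset_bundle <- function(bundle, cell_mask) {
  if (!is.logical(cell_mask) || length(cell_mask) != ncol(bundle$gene_counts))
    stop("cell_mask must be a logical vector with one entry per cell")
  counts_bundle(
    bundle$gene_counts[, cell_mask, drop = FALSE],
    bundle$tag_counts[, cell_mask, drop = FALSE],
    bundle$cell_meta[cell_mask, , drop = FALSE]
  )
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; numeric columns rendered with 12
#' significant digits so that [read_result_table()] round-trips values within
#' 1e-9 relative tolerance.
#'
#' @param table data.frame with unique column names
#' @param path output path
#' @return `path`, invisibly
#' @export
write_result_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) stop("column names must be unique")
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.12g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write result table to ", path)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path TSV path
#' @return data.frame
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a reference expression-profile table
#'
#' TSV with the gene id in the first column and one column of mean log-scale
#' expression per cell type.
#'
#' @param path TSV path
#' @return list with `type_names`, `gene_ids`, `mean_expr` (genes x types)
#' @export
read_reference_profiles <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("reference table needs a gene column and >= 1 type")
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate type names in reference")
  if (any(!is.finite(m))) stop("reference expression must be finite")
  rownames(m) <- genes
  list(type_names = colnames(m), gene_ids = genes, mean_expr = m)
}

#' Write a reference expression-profile table
#' @param ref list as returned by [make_reference()] / [read_reference_profiles()]
#' @param path TSV path
#' @return `path`, invisibly
#' @export
write_reference_profiles <- function(ref, path) {
  df <- data.frame(gene = ref$gene_ids, ref$mean_expr, check.names = FALSE)
  write_result_table(df, path)
}
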