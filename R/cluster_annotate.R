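#' Cluster cells on PCA scores via an SNN graph and Louvain
#'
#' Builds a k-nearest-neighbour graph in PC space (each cell's neighbourhood
#' includes itself), converts it to a shared-nearest-neighbour graph with
#' Jaccard edge weights, prunes weights below 1/15, and runs Louvain
#' modularity optimization at the given resolution. Deterministic given
#' `seed`.
#'
#' @param pca_scores cells x PCs numeric matrix (rownames = cell ids)
#' @param k_neighbors neighbourhood size (default 20)
#' @param resolution Louvain resolution (default 1)
#' @param seed RNG seed for the community search
#' @param prune Jaccard weight threshold below which edges are dropped
#' @return list of class `ClusterAssignment`: `labels` (integer per cell,
#'   contiguous from 0, named by cell id), `k_neighbors`, `resolution`,
#'   `seed`, `modularity`
#' @export
cluster_cells <- function(pca_scores, k_neighbors = 20, resolution = 1,
                          seed = 1, prune = 1 / 15) {
  n <- nrow(pca_scores)
  if (n < 2) stop("need at least 2 cells to cluster")
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the cell count")
  cells <- rownames(pca_scores)
  if (sum(apply(pca_scores, 2, stats::var)) == 0) {
    warning("all cells identical in PC space; returning a single cluster")
    return(structure(list(
      labels = stats::setNames(rep(0L, n), cells),
      k_neighbors = k_neighbors, resolution = resolution, seed = seed,
      modularity = NA_real_), class = "ClusterAssignment"))
  }
  d <- as.matrix(stats::dist(pca_scores))
  # kNN including self: the k_neighbors nearest plus the cell itself
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k_neighbors),
    j = as.vector(t(nn)),
    x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(adj)
  jac <- shared / (2 * k_neighbors - shared)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm)) - 1L
  structure(list(
    labels = stats::setNames(labels, cells),
    k_neighbors = k_neighbors, resolution = resolution, seed = seed,
    modularity = max(igraph::modularity(comm))
  ), class = "ClusterAssignment")
}

#' Annotate clusters by correlation to reference profiles
#'
#' Computes each cluster's mean log-expression over the chosen genes and
#' correlates it against every reference type over the shared genes
#' (Spearman by default). Each cluster is assigned the type maximizing the
#' correlation; exact ties break by reference column order and set the
#' ambiguity flag, as does a top1-top2 margin below `margin_min`.
#'
#' @param norm a `NormalizedMatrix`
#' @param clusters a [cluster_cells()] result
#' @param ref reference profiles (list with `type_names`, `gene_ids`,
#'   `mean_expr`)
#' @param genes gene ids to use; default HVGs intersected with the reference
#' @param method "spearman" (default) or "pearson"
#' @param margin_min margin below which the assignment is flagged ambiguous
#' @return list of class `TypeAnnotation`: `table` (data.frame cluster,
#'   assigned_type, r_top1, r_top2, margin, ambiguous), `correlations`
#'   (clusters x types), `cell_types` (per-cell assigned type)
#' @export
annotate_clusters <- function(norm, clusters, ref, genes = NULL,
                              method = c("spearman", "pearson"),
                              margin_min = 0.02) {
  method <- match.arg(method)
  if (is.null(genes)) {
    genes <- if (!is.null(norm$hvg_ids)) norm$hvg_ids else
      rownames(norm$log_expr)
  }
  shared <- intersect(intersect(genes, rownames(norm$log_expr)),
                      ref$gene_ids)
  if (length(shared) < 10)
    stop("only ", length(shared),
         " genes shared with the reference; annotation would be meaningless")
  labs <- clusters$labels
  ulabs <- sort(unique(labs))
  prof <- sapply(ulabs, function(cl)
    Matrix::rowMeans(norm$log_expr[shared, labs == cl, drop = FALSE]))
  refm <- ref$mean_expr[shared, , drop = FALSE]
  cors <- stats::cor(prof, refm, method = method)  # clusters x types
  rownames(cors) <- as.character(ulabs)
  rows <- lapply(seq_along(ulabs), function(i) {
    r <- cors[i, ]
    ord <- order(-r, seq_along(r))  # ties break by reference order
    top1 <- ord[1]; top2 <- if (length(r) > 1) ord[2] else NA_integer_
    margin <- if (is.na(top2)) Inf else r[top1] - r[top2]
    data.frame(
      cluster = ulabs[i],
      assigned_type = colnames(cors)[top1],
      r_top1 = unname(r[top1]),
      r_top2 = if (is.na(top2)) NA_real_ else unname(r[top2]),
      margin = unname(margin),
      ambiguous = is.finite(margin) && margin < margin_min,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  cell_types <- tab$assigned_type[match(labs, tab$cluster)]
  names(cell_types) <- names(labs)
  structure(list(table = tab, correlations = cors, cell_types = cell_types,
                 method = method, margin_min = margin_min),
            class = "TypeAnnotation")
}
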