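#' Rank-sum test with AUC for one gene
#'
#' Mann-Whitney U with midranks for ties; AUC = U / (n_in * n_out), the
#' probability that a random in-class cell exceeds a random out-class cell.
#' The p-value is exact by enumeration when n_in + n_out <= 12 and the data
#' are tie-free, otherwise a normal approximation with tie and continuity
#' corrections.
#'
#' @param expr_in,expr_out expression values in the two classes (nonempty)
#' @return list with `statistic` (U), `auc`, `pval`, `method`
#' @export
rank_auc_test <- function(expr_in, expr_out) {
  if (length(expr_in) == 0 || length(expr_out) == 0)
    stop("both groups must be nonempty")
  w <- wilcoxon_ranksum(expr_in, expr_out, alternative = "two_sided",
                        mode = "auto")
  list(statistic = w$statistic,
       auc = w$statistic / (length(expr_in) * length(expr_out)),
       pval = w$p, method = w$method)
}

#' Marker genes of the antigen-high class
#'
#' Per gene: rank-sum statistic and AUC on log-normalized expression between
#' high- and low-class cells, logFC as the difference of class means of
#' log-normalized expression (natural-log scale), expression percentages
#' from counts > 0, and BH adjustment across all tested genes. The pass flag
#' applies the filter set padj < alpha, logFC > min_lfc, AUC > min_auc and
#' pct_in >= min_pct_in. Genes expressed in neither class are skipped and
#' reported with `tested = FALSE`.
#'
#' @param norm a `NormalizedMatrix` (carries log-normalized and raw counts)
#' @param labels per-cell class ("high"/"low"), named by cell id or in
#'   column order; cells with NA labels are ignored
#' @param alpha adjusted p-value threshold (default 0.05, strict <)
#' @param min_lfc log fold-change threshold (default 0.25, strict >)
#' @param min_auc AUC threshold (default 0.5, strict >)
#' @param min_pct_in percent-expressing threshold in the high class
#'   (default 50, inclusive >=)
#' @return data.frame of class `MarkerTable`, one row per gene: gene,
#'   avgExpr, logFC, statistic, auc, pval, padj, pct_in, pct_out, tested,
#'   pass; ordered by increasing pval among tested genes
#' @export
find_markers <- function(norm, labels, alpha = 0.05, min_lfc = 0.25,
                         min_auc = 0.5, min_pct_in = 50) {
  expr <- norm$log_expr
  cells <- colnames(expr)
  if (!is.null(names(labels))) labels <- labels[cells]
  if (length(labels) != length(cells))
    stop("labels must cover every cell")
  keep <- !is.na(labels)
  labels <- as.character(labels[keep])
  expr <- expr[, keep, drop = FALSE]
  classes <- unique(labels)
  if (!setequal(classes, c("high", "low")))
    stop("labels must contain both classes 'high' and 'low'")
  in_idx <- labels == "high"
  n_in <- sum(in_idx); n_out <- sum(!in_idx)
  if (n_in < 2 || n_out < 2)
    stop("both classes need at least 2 cells")

  x <- as.matrix(expr)
  n <- ncol(x)
  mean_in <- rowMeans(x[, in_idx, drop = FALSE])
  mean_out <- rowMeans(x[, !in_idx, drop = FALSE])
  pct_in <- 100 * rowMeans(x[, in_idx, drop = FALSE] > 0)
  pct_out <- 100 * rowMeans(x[, !in_idx, drop = FALSE] > 0)
  tested <- (pct_in > 0) | (pct_out > 0)

  U <- rep(NA_real_, nrow(x)); pval <- rep(NA_real_, nrow(x))
  small <- (n <= 12)
  for (g in which(tested)) {
    v <- x[g, ]
    if (small && !anyDuplicated(v)) {
      res <- wilcoxon_ranksum(v[in_idx], v[!in_idx], mode = "exact")
      U[g] <- res$statistic; pval[g] <- res$p
    } else {
      r <- rank(v)
      u <- sum(r[in_idx]) - n_in * (n_in + 1) / 2
      tie_tab <- tabulate(match(v, unique(v)))
      tie_term <- sum(tie_tab^3 - tie_tab)
      sigma2 <- (n_in * n_out / 12) * ((n + 1) - tie_term / (n * (n - 1)))
      if (sigma2 <= 0) {
        p <- 1
      } else {
        mu <- n_in * n_out / 2
        z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
      }
      U[g] <- u; pval[g] <- p
    }
  }
  padj <- rep(NA_real_, nrow(x))
  padj[tested] <- stats::p.adjust(pval[tested], "BH")
  auc <- U / (n_in * n_out)
  out <- data.frame(
    gene = rownames(x),
    avgExpr = mean_in,
    logFC = mean_in - mean_out,
    statistic = U,
    auc = auc,
    pval = pval,
    padj = padj,
    pct_in = pct_in,
    pct_out = pct_out,
    tested = tested,
    stringsAsFactors = FALSE
  )
  out$pass <- !is.na(out$padj) & out$padj < alpha & out$logFC > min_lfc &
    out$auc > min_auc & out$pct_in >= min_pct_in
  out <- out[order(!out$tested, out$pval, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("MarkerTable", "data.frame")
  out
}
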