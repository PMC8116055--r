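#' Per-cell relative antigen signal against a T/B baseline
#'
#' Within each sample, the relative signal of a cell is its raw tag count
#' divided by the median tag count over the baseline (T and B) cells of that
#' sample. For log-scale display, a per-sample pseudocount of half the
#' smallest positive relative signal is added. If the baseline median is 0,
#' the median of the *positive* baseline counts is used instead; if no
#' baseline cell has a positive count the divisor falls back to 1 — both
#' fallbacks set `baseline_degenerate`.
#'
#' @param bundle a [counts_bundle()]
#' @param tag tag id to quantify (row of `tag_counts`)
#' @param baseline_types cell types forming the baseline
#' @param annotations per-cell type labels, named by cell id or in bundle
#'   cell order
#' @return data.frame of class `AntigenSignalTable`: cell_id, sample,
#'   cell_type, raw_count, baseline_median, relative_signal, pseudocount,
#'   display (log10(relative + pseudocount)), baseline_degenerate
#' @export
relative_signal <- function(bundle, tag, baseline_types, annotations) {
  if (!tag %in% rownames(bundle$tag_counts))
    stop("unknown tag: ", tag)
  cells <- bundle_cells(bundle)
  if (!is.null(names(annotations))) {
    if (!all(cells %in% names(annotations)))
      stop("annotations missing for some cells")
    annotations <- annotations[cells]
  } else if (length(annotations) != length(cells)) {
    stop("annotations must cover every cell")
  }
  a <- as.numeric(bundle$tag_counts[tag, ])
  sample <- bundle$cell_meta$sample
  out <- data.frame(cell_id = cells, sample = sample,
                    cell_type = as.character(annotations),
                    raw_count = a,
                    baseline_median = NA_real_,
                    relative_signal = NA_real_,
                    pseudocount = NA_real_,
                    display = NA_real_,
                    baseline_degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (s in unique(sample)) {
    in_s <- sample == s
    base <- in_s & out$cell_type %in% baseline_types
    if (!any(base))
      stop("no baseline cells in sample ", s)
    m <- stats::median(a[base])
    degenerate <- FALSE
    if (m == 0) {
      pos <- a[base][a[base] > 0]
      m <- if (length(pos)) stats::median(pos) else 1
      degenerate <- TRUE
    }
    r <- a[in_s] / m
    pos_r <- r[r > 0]
    p <- if (length(pos_r)) 0.5 * min(pos_r) else 1
    out$baseline_median[in_s] <- m
    out$relative_signal[in_s] <- r
    out$pseudocount[in_s] <- p
    out$display[in_s] <- log10(r + p)
    out$baseline_degenerate[in_s] <- degenerate
  }
  class(out) <- c("AntigenSignalTable", "data.frame")
  out
}

#' Compare relative antigen signal between cell types
#'
#' For each sample, runs a two-sided Wilcoxon rank-sum test on the relative
#' signal for every comparison — all pairs of types (default) or each type
#' against a reference group — with a Hodges-Lehmann estimate of the median
#' difference and its confidence interval, and Bonferroni adjustment across
#' the comparisons within the sample.
#'
#' @param signal an `AntigenSignalTable` from [relative_signal()]
#' @param mode "pairwise" (all type pairs, default) or "vs_reference"
#' @param reference_group for `vs_reference`: type name(s) pooled into the
#'   reference
#' @param level confidence level for the interval (default 0.95)
#' @return data.frame of class `GroupComparison` with columns sample, group1,
#'   group2, n_cells, frac_cells, median, n_cells_ref, median_ref, statistic,
#'   estimate, conf.low, conf.high, p, p_adj
#' @export
compare_types <- function(signal, mode = c("pairwise", "vs_reference"),
                          reference_group = NULL, level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(signal, "AntigenSignalTable") || is.data.frame(signal))
  if (mode == "vs_reference" && is.null(reference_group))
    stop("vs_reference mode needs a reference_group")
  rows <- list()
  for (s in unique(signal$sample)) {
    ss <- signal[signal$sample == s, ]
    n_sample <- nrow(ss)
    types <- sort(unique(ss$cell_type))
    pairs <- if (mode == "pairwise") {
      if (length(types) < 2) stop("need >= 2 groups to compare")
      utils::combn(types, 2, simplify = FALSE)
    } else {
      tested <- setdiff(types, reference_group)
      lapply(tested, function(t) c(t, "__reference__"))
    }
    srows <- lapply(pairs, function(pr) {
      g1 <- ss$relative_signal[ss$cell_type == pr[1]]
      g2 <- if (identical(pr[2], "__reference__"))
        ss$relative_signal[ss$cell_type %in% reference_group]
      else ss$relative_signal[ss$cell_type == pr[2]]
      g2name <- if (identical(pr[2], "__reference__"))
        paste(reference_group, collapse = "+") else pr[2]
      if (length(g1) == 0 || length(g2) == 0) {
        return(data.frame(sample = s, group1 = pr[1], group2 = g2name,
                          n_cells = length(g1),
                          frac_cells = length(g1) / n_sample,
                          median = NA_real_, n_cells_ref = length(g2),
                          median_ref = NA_real_, statistic = NA_real_,
                          estimate = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      w <- wilcoxon_ranksum(g1, g2, alternative = "two_sided")
      hl <- hodges_lehmann(g1, g2, level = level)
      data.frame(sample = s, group1 = pr[1], group2 = g2name,
                 n_cells = length(g1), frac_cells = length(g1) / n_sample,
                 median = stats::median(g1),
                 n_cells_ref = length(g2), median_ref = stats::median(g2),
                 statistic = w$statistic, estimate = hl$estimate,
                 conf.low = hl$conf.low, conf.high = hl$conf.high,
                 p = w$p, stringsAsFactors = FALSE)
    })
    stab <- do.call(rbind, srows)
    stab$p_adj <- NA_real_
    ok <- !is.na(stab$p)
    stab$p_adj[ok] <- adjust_pvalues(stab$p[ok], "bonferroni")
    rows[[length(rows) + 1L]] <- stab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("GroupComparison", "data.frame")
  out
}
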