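#' Validate a tag barcode whitelist
#'
#' A whitelist maps tag ids to equal-length DNA barcodes whose pairwise
#' Hamming distance is at least 3, so that single-mismatch correction is
#' unambiguous.
#'
#' @param barcodes named character vector (names = tag ids)
#' @return the whitelist, invisibly classed `TagWhitelist`
#' @export
tag_whitelist <- function(barcodes) {
  if (is.null(names(barcodes)) || anyDuplicated(names(barcodes)))
    stop("whitelist must be named by unique tag ids")
  w <- nchar(barcodes)
  if (length(unique(w)) != 1)
    stop("all tag barcodes must have equal length")
  if (length(barcodes) > 1) {
    for (i in seq_len(length(barcodes) - 1)) {
      for (j in (i + 1):length(barcodes)) {
        d <- hamming_distance(barcodes[[i]], barcodes[[j]])
        if (d < 3)
          stop("tag barcodes ", names(barcodes)[i], " and ",
               names(barcodes)[j], " are at Hamming distance ", d,
               " (< 3); distance-1 correction would be ambiguous")
      }
    }
  }
  structure(barcodes, class = "TagWhitelist")
}

# Hamming distances from many query sequences to each whitelist barcode.
# N (or any non-matching character) counts as a mismatch.
# Returns a length(queries) x length(whitelist) integer matrix.
tag_distance_matrix <- function(queries, whitelist) {
  width <- nchar(whitelist[[1]])
  qmat <- matrix(unlist(strsplit(queries, "")), ncol = width, byrow = TRUE)
  d <- matrix(0L, nrow = length(queries), ncol = length(whitelist),
              dimnames = list(NULL, names(whitelist)))
  for (j in seq_along(whitelist)) {
    ref <- strsplit(whitelist[[j]], "")[[1]]
    d[, j] <- as.integer(rowSums(qmat != matrix(ref, nrow = length(queries),
                                                ncol = width, byrow = TRUE)))
  }
  d
}

#' Match a tag barcode against a whitelist
#'
#' Returns the unique tag within Hamming distance `max_mismatch`; `NA` when
#' no tag qualifies or two tags tie at the minimum distance. N bases count
#' as mismatches.
#'
#' @param read_barcode observed barcode (same length as whitelist entries)
#' @param whitelist a [tag_whitelist()]
#' @param max_mismatch 0 or 1
#' @return tag id or `NA_character_`
#' @export
match_tag <- function(read_barcode, whitelist, max_mismatch = 1) {
  if (!max_mismatch %in% c(0, 1)) stop("max_mismatch must be 0 or 1")
  if (nchar(read_barcode) != nchar(whitelist[[1]]))
    stop("read barcode length (", nchar(read_barcode),
         ") differs from whitelist barcode length (",
         nchar(whitelist[[1]]), ")")
  d <- tag_distance_matrix(read_barcode, whitelist)[1, ]
  dmin <- min(d)
  if (dmin > max_mismatch || sum(d == dmin) > 1) return(NA_character_)
  names(whitelist)[which.min(d)]
}

# directional UMI merge within one (cell, tag) group: sort UMIs by read count
# descending (lexicographic tie-break), then absorb any unassigned UMI u into
# the current survivor v when Hamming(u, v) = 1 and reads(v) >= 2*reads(u)-1.
merge_umis_directional <- function(umi_reads) {
  if (length(umi_reads) <= 1) return(length(umi_reads))
  ord <- order(-umi_reads, names(umi_reads))
  umis <- names(umi_reads)[ord]
  cnts <- unname(umi_reads[ord])
  assigned <- rep(FALSE, length(umis))
  survivors <- 0L
  for (i in seq_along(umis)) {
    if (assigned[i]) next
    survivors <- survivors + 1L
    assigned[i] <- TRUE
    if (i < length(umis)) {
      for (j in (i + 1):length(umis)) {
        if (assigned[j]) next
        if (cnts[i] >= 2 * cnts[j] - 1 &&
            hamming_distance(umis[i], umis[j]) == 1)
          assigned[j] <- TRUE
      }
    }
  }
  survivors
}

#' Collapse tag reads to a tags x cells UMI count matrix
#'
#' Reads are first filtered on an exact cell-barcode match, then their tag
#' barcodes are matched against the whitelist allowing at most one mismatch
#' (unambiguous by the distance >= 3 whitelist design). Within each
#' (cell, tag) group, UMIs are deduplicated exactly; with
#' `umi_merge = "hamming1_directional"`, a UMI u is additionally merged into
#' a more abundant UMI v when Hamming(u, v) = 1 and reads(v) >= 2*reads(u)-1.
#' The count is the number of surviving UMIs. Per-read audit tallies
#' partition the input: n_exact + n_corrected + n_ambiguous + n_unmatched =
#' total reads (reads failing the cell match are tallied unmatched).
#'
#' @param reads data.frame with columns `cell`, `umi`, `tag` (sequences)
#' @param whitelist a [tag_whitelist()]
#' @param cell_whitelist character vector of valid cell barcodes
#' @param umi_merge "none" (plain dedup, default) or "hamming1_directional"
#' @return list with `tag_counts` (tags x cells over the full whitelists) and
#'   `audit` (named tallies incl. `n_duplicate_umi`)
#' @export
collapse_umis <- function(reads, whitelist, cell_whitelist,
                          umi_merge = c("none", "hamming1_directional")) {
  umi_merge <- match.arg(umi_merge)
  stopifnot(all(c("cell", "umi", "tag") %in% names(reads)))
  n_total <- nrow(reads)
  tags <- names(whitelist)
  counts <- matrix(0L, nrow = length(tags), ncol = length(cell_whitelist),
                   dimnames = list(tags, cell_whitelist))
  audit <- c(n_exact = 0L, n_corrected = 0L, n_ambiguous = 0L,
             n_unmatched = 0L, n_duplicate_umi = 0L)
  if (n_total == 0)
    return(list(tag_counts = Matrix::Matrix(counts, sparse = TRUE),
                audit = audit))

  cell_ok <- reads$cell %in% cell_whitelist
  width <- nchar(whitelist[[1]])
  tag_ok_len <- nchar(reads$tag) == width

  # classify unique tag sequences once
  useq <- unique(reads$tag[tag_ok_len])
  assign_tag <- rep(NA_character_, length(useq))
  kind <- rep("unmatched", length(useq))
  if (length(useq)) {
    d <- tag_distance_matrix(useq, whitelist)
    dmin <- apply(d, 1, min)
    nmin <- rowSums(d == dmin)
    hit <- dmin <= 1 & nmin == 1
    assign_tag[hit] <- tags[apply(d[hit, , drop = FALSE], 1, which.min)]
    kind[hit & dmin == 0] <- "exact"
    kind[hit & dmin == 1] <- "corrected"
    kind[dmin <= 1 & nmin > 1] <- "ambiguous"
  }
  idx <- match(reads$tag, useq)
  read_tag <- ifelse(tag_ok_len, assign_tag[idx], NA_character_)
  read_kind <- ifelse(tag_ok_len, kind[idx], "unmatched")

  keep <- cell_ok & !is.na(read_tag)
  # audit partition: bad cell barcode dominates, then tag-match outcome
  audit["n_unmatched"] <- sum(!cell_ok | read_kind == "unmatched")
  audit["n_ambiguous"] <- sum(cell_ok & read_kind == "ambiguous")
  audit["n_exact"] <- sum(cell_ok & read_kind == "exact")
  audit["n_corrected"] <- sum(cell_ok & read_kind == "corrected")

  if (any(keep)) {
    dt <- data.table::data.table(
      cell = reads$cell[keep], tag = read_tag[keep], umi = reads$umi[keep]
    )
    per_umi <- dt[, list(n_reads = .N), by = c("cell", "tag", "umi")]
    audit["n_duplicate_umi"] <- sum(keep) - nrow(per_umi)
    if (umi_merge == "none") {
      grp <- per_umi[, list(count = .N), by = c("cell", "tag")]
    } else {
      grp <- per_umi[, list(count = merge_umis_directional(
        stats::setNames(n_reads, umi))), by = c("cell", "tag")]
    }
    counts[cbind(match(grp$tag, tags), match(grp$cell, cell_whitelist))] <-
      as.integer(grp$count)
  }
  list(tag_counts = Matrix::Matrix(counts, sparse = TRUE), audit = audit)
}
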