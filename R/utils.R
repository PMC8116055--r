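DNA_BASES <- c("A", "C", "G", "T")

# random DNA barcodes, unique within the returned set
random_barcodes <- function(n, width) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    new <- vapply(seq_len(need), function(i)
      paste(sample(DNA_BASES, width, replace = TRUE), collapse = ""),
      character(1))
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

#' Hamming distance between equal-length strings
#' @param a,b character strings of equal length
#' @return integer number of differing positions (N never matches)
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length
#' @return numeric ARI
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxidx - expected)
}

# substitute each base independently with probability rate (to a different
# random base); vectorized over reads
mutate_sequences <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  chars <- strsplit(seqs, "")
  widths <- lengths(chars)
  flat <- unlist(chars)
  hit <- stats::runif(length(flat)) < rate
  if (any(hit)) {
    # draw a base different from the current one
    repl <- vapply(flat[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1), character(1))
    flat[hit] <- repl
  }
  idx <- rep(seq_along(seqs), widths)
  vapply(split(flat, idx), paste, character(1), collapse = "")
}
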