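# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths.

# exact two-sided rank-sum p by full enumeration of all choose(n1+n2, n1)
# group assignments of the pooled values (tie-free data only)
brute_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(N, n1)
  us <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# AUC by pairwise win counting (ties count half)
brute_auc <- function(x_in, x_out) {
  wins <- outer(x_in, x_out, ">") + 0.5 * outer(x_in, x_out, "==")
  mean(wins)
}

# grid-search oracle for the 2-component Gaussian mixture log-likelihood
gmm2_grid_loglik <- function(values, n_grid = 8) {
  mus <- seq(min(values), max(values), length.out = n_grid)
  sds <- seq(stats::sd(values) / 4, stats::sd(values), length.out = 4)
  pis <- c(0.25, 0.5, 0.75)
  best <- -Inf
  for (m1 in mus) for (m2 in mus) for (s1 in sds) for (s2 in sds)
    for (p1 in pis) {
      ll <- sum(log(p1 * stats::dnorm(values, m1, s1) +
                      (1 - p1) * stats::dnorm(values, m2, s2)))
      if (ll > best) best <- ll
    }
  best
}

# tiny CountsBundle with explicit values
toy_bundle <- function(gene_counts, tag_counts = NULL, meta = NULL) {
  if (is.null(colnames(gene_counts)))
    colnames(gene_counts) <- sprintf("cell%02d", seq_len(ncol(gene_counts)))
  if (is.null(rownames(gene_counts)))
    rownames(gene_counts) <- sprintf("gene%02d", seq_len(nrow(gene_counts)))
  if (is.null(tag_counts))
    tag_counts <- matrix(0L, nrow = 1, ncol = ncol(gene_counts),
                         dimnames = list("tagA", colnames(gene_counts)))
  counts_bundle(Matrix::Matrix(gene_counts, sparse = TRUE),
                Matrix::Matrix(tag_counts, sparse = TRUE), meta)
}

# expression fixture with one planted marker gene ("g01"): a `fold`-times
# mean shift in the high class, expressed in `pct` of high cells
marker_fixture <- function(n_per = 100, n_genes = 40, seed = 5,
                           planted = "g01", fold = 3, pct = 0.8) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  cells <- sprintf("c%03d", seq_len(2 * n_per))
  counts <- matrix(stats::rpois(n_genes * 2 * n_per, 2), nrow = n_genes,
                   dimnames = list(genes, cells))
  labels <- stats::setNames(rep(c("high", "low"), each = n_per), cells)
  hi <- which(labels == "high")
  expressed <- sample(hi, round(pct * n_per))
  counts[planted, hi] <- 0L
  counts[planted, expressed] <- stats::rpois(length(expressed),
                                             2 * fold / pct) + 1L
  b <- toy_bundle(counts)
  list(norm = lognormalize(b), labels = labels)
}

# random mixed-type result table for round-trip property tests
random_result_table <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    id = replicate(n, paste(sample(letters, 5), collapse = "")),
    count = sample.int(1000, n, replace = TRUE),
    value = stats::rnorm(n) * 10^sample(-4:4, n, replace = TRUE),
    flag = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
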