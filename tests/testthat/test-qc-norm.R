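# bundle with controlled detected-gene and mito profiles: each cell expresses
# its first `detected` genes once
qc_fixture <- function(detected, mito_counts = NULL, n_genes = 6000) {
  n <- length(detected)
  genes <- c(sprintf("gene%05d", seq_len(n_genes - 5)), sprintf("mt-g%d", 1:5))
  m <- matrix(0L, nrow = n_genes, ncol = n,
              dimnames = list(genes, sprintf("cell%02d", seq_len(n))))
  for (i in seq_len(n)) m[seq_len(detected[i]), i] <- 1L
  if (!is.null(mito_counts))
    for (i in seq_len(n)) m[n_genes - 5 + 1, i] <- mito_counts[i]
  toy_bundle(m)
}

test_that("QC thresholds are strict at every boundary", {
  b <- qc_fixture(c(100, 250, 251, 4999, 5000, 300))
  res <- qc_filter(b, qc_params())
  kept <- bundle_cells(res$bundle)
  expect_equal(res$report$pass,
               c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(res$report$fail_reason[c(1, 2, 5)],
               c("low_genes", "low_genes", "high_genes"))
  # mito boundary: exactly 15% fails, just below passes
  # cell with 300 detected + mito load pushing pct to 15
  b2 <- qc_fixture(c(300, 300), mito_counts = NULL)
  gc <- as.matrix(b2$gene_counts)
  gc["mt-g1", 1] <- 53L   # 53/(300+53) = 15.01% -> fail
  gc["mt-g1", 2] <- 52L   # 52/352 = 14.77% -> pass
  res2 <- qc_filter(toy_bundle(gc), qc_params())
  expect_equal(res2$report$pass, c(FALSE, TRUE))
  expect_equal(res2$report$fail_reason[1], "high_mito")
})

test_that("toy bundle of 5 cells keeps exactly the in-range cells", {
  b <- qc_fixture(c(100, 251, 4999, 5000, 300))
  gc <- as.matrix(b$gene_counts)
  # last cell gets 20% mito
  gc["mt-g1", 5] <- as.integer(round(0.25 * 300))  # 75/375 = 20%
  res <- qc_filter(toy_bundle(gc), qc_params())
  expect_equal(sum(res$report$pass), 2)
  expect_equal(bundle_cells(res$bundle), c("cell02", "cell03"))
})

test_that("qc_filter is idempotent and warns when nothing survives", {
  b <- qc_fixture(c(300, 400, 500))
  once <- qc_filter(b)$bundle
  twice <- qc_filter(once)$bundle
  expect_equal(bundle_cells(twice), bundle_cells(once))
  expect_warning(res <- qc_filter(qc_fixture(c(10, 20))), "no cells survive")
  expect_equal(ncol(res$bundle$gene_counts), 0L)
})

test_that("log-normalization follows ln(1 + count * sf / total)", {
  m <- matrix(c(7L, 0L), nrow = 2,
              dimnames = list(c("gA", "gB"), "c1"))
  norm <- lognormalize(toy_bundle(m))
  expect_equal(norm$log_expr["gA", "c1"], log(1 + 1e4))
  expect_equal(norm$log_expr["gB", "c1"], 0)

  # scale invariance: doubling all counts of a cell leaves the column fixed
  set.seed(2)
  m2 <- matrix(rpois(40, 3), nrow = 10,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:4)))
  n1 <- lognormalize(toy_bundle(m2))
  m2[, 2] <- m2[, 2] * 2L
  n2 <- lognormalize(toy_bundle(m2))
  expect_equal(as.matrix(n1$log_expr)[, 2], as.matrix(n2$log_expr)[, 2])
  # monotone in counts within a cell
  col <- as.matrix(n1$log_expr)[, 1]
  expect_equal(order(col), order(m2[, 1], seq_len(10)))

  m3 <- cbind(m2, c0 = 0L)
  expect_warning(n3 <- lognormalize(toy_bundle(m3)), "zero total")
  expect_true(all(as.matrix(n3$log_expr)[, "c0"] == 0))
})

test_that("HVG selection ranks by standardized variance with id tie-break", {
  set.seed(4)
  n <- 200
  base <- matrix(rpois(100 * n, 5), nrow = 100,
                 dimnames = list(sprintf("g%03d", 1:100), sprintf("c%03d", 1:n)))
  # one gene with inflated variance at equal mean (the trend bins hold ~5
  # same-mean peers, so its standardized variance stands out)
  base["g013", ] <- rep(c(0L, 10L), length.out = n)  # mean 5, variance ~25
  norm <- select_hvg(lognormalize(toy_bundle(base)), n_hvg = 3)
  expect_equal(norm$hvg_ids[1], "g013")

  # identical distributions: selection is the lexicographic prefix
  flat <- matrix(2L, nrow = 6, ncol = 5,
                 dimnames = list(c("gd", "gb", "ga", "gc", "gf", "ge"),
                                 sprintf("c%d", 1:5)))
  norm2 <- select_hvg(lognormalize(toy_bundle(flat)), n_hvg = 3)
  expect_equal(norm2$hvg_ids, c("ga", "gb", "gc"))

  # n_hvg = n_genes returns everything; larger warns
  norm3 <- select_hvg(lognormalize(toy_bundle(base)), n_hvg = 100)
  expect_setequal(norm3$hvg_ids, rownames(base))
  expect_warning(select_hvg(lognormalize(toy_bundle(base)), n_hvg = 200),
                 "exceeds gene count")
})

test_that("PCA is exact, sign-fixed, and respects rank structure", {
  # collinear toy set: PC1 carries all variance
  m <- matrix(c(0, 0, 1, 1, 2, 2), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  norm <- lognormalize(toy_bundle(m + 1))  # +1 keeps totals positive
  norm$hvg_ids <- c("g1", "g2")
  # bypass log scaling effects by injecting the raw coordinates
  norm$log_expr <- Matrix::Matrix(m, sparse = TRUE)
  res <- run_pca(norm, n_pcs = 2)
  expect_gt(res$pca_var[1] / sum(res$pca_var), 1 - 1e-10)

  # rank-2 data: no variance beyond PC2; duplicated cells share scores
  set.seed(6)
  u <- matrix(rnorm(20), 10, 2); v <- matrix(rnorm(8), 2, 4)
  x <- u %*% v
  x <- cbind(x, x[, 4])  # duplicate a cell
  dimnames(x) <- list(sprintf("g%02d", 1:10), sprintf("c%d", 1:5))
  normr <- lognormalize(toy_bundle(matrix(1L, 10, 5,
                                          dimnames = dimnames(x))))
  normr$hvg_ids <- rownames(x)
  # inject the rank-2 coordinates directly: row centering/scaling keeps
  # rank <= 2, so variance past PC2 must vanish
  normr$log_expr <- Matrix::Matrix(x, sparse = TRUE)
  resr <- run_pca(normr, n_pcs = 4)
  expect_lt(sum(resr$pca_var[3:4]), 1e-12 * sum(resr$pca_var))
  expect_equal(resr$pca_scores["c4", ], resr$pca_scores["c5", ])
  # scaled rows are centered and unit-variance pre-clipping
  expect_true(all(abs(rowMeans(resr$scaled_expr)) < 1e-8))
  sds <- apply(resr$scaled_expr, 1, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-6))
  # sign convention: largest-magnitude loading entry is positive
  for (k in seq_len(ncol(resr$pca_loadings)))
    expect_gt(resr$pca_loadings[which.max(abs(resr$pca_loadings[, k])), k], 0)
  expect_error(run_pca(normr, n_pcs = 10), "exceeds")
})

test_that("PCA reconstruction error decreases with more components", {
  set.seed(8)
  x <- matrix(rpois(50 * 30, 4), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:30)))
  norm <- select_hvg(lognormalize(toy_bundle(x)), n_hvg = 50)
  errs <- sapply(c(2, 5, 10, 20), function(k) {
    r <- run_pca(norm, n_pcs = k)
    recon <- r$pca_scores %*% t(r$pca_loadings)
    sum((t(r$scaled_expr) - recon)^2)
  })
  expect_true(all(diff(errs) < 1e-8))
})
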