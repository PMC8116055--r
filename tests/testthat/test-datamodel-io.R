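write_trio <- function(dir, bundle) {
  dir.create(dir, showWarnings = FALSE)
  write_triplet_matrix(bundle, dir)
}

test_that("triplet reader splits gene and tag blocks by feature class", {
  b <- toy_bundle(
    matrix(c(1, 0, 2, 0, 3, 0), nrow = 3,
           dimnames = list(c("g1", "g2", "g3"), c("c1", "c2"))),
    matrix(c(5, 0, 0, 7), nrow = 2,
           dimnames = list(c("t1", "t2"), c("c1", "c2")))
  )
  d <- tempfile()
  write_trio(d, b)
  b2 <- read_triplet_matrix(file.path(d, "matrix.mtx"),
                            file.path(d, "features.tsv"),
                            file.path(d, "barcodes.tsv"))
  expect_equal(dim(b2$gene_counts), c(3L, 2L))
  expect_equal(dim(b2$tag_counts), c(2L, 2L))
  expect_equal(as.matrix(b2$gene_counts), as.matrix(b$gene_counts))
  expect_equal(as.matrix(b2$tag_counts), as.matrix(b$tag_counts))
  # gene/tag split is a partition conserving total counts
  expect_equal(sum(b2$gene_counts) + sum(b2$tag_counts),
               sum(b$gene_counts) + sum(b$tag_counts))
  expect_length(intersect(rownames(b2$gene_counts),
                          rownames(b2$tag_counts)), 0)
})

test_that("zero-cell matrices and all-zero columns are valid", {
  d <- tempfile(); dir.create(d)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "5 0 0"), file.path(d, "matrix.mtx"))
  writeLines(sprintf("f%d\tGene Expression", 1:5), file.path(d, "features.tsv"))
  writeLines(character(0), file.path(d, "barcodes.tsv"))
  b <- read_triplet_matrix(file.path(d, "matrix.mtx"),
                           file.path(d, "features.tsv"),
                           file.path(d, "barcodes.tsv"))
  expect_equal(ncol(b$gene_counts), 0L)

  # a barcode absent from the triplets is kept as an all-zero column
  d2 <- tempfile(); dir.create(d2)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 1", "1 1 4"), file.path(d2, "matrix.mtx"))
  writeLines(c("g1\tGene Expression", "g2\tGene Expression"),
             file.path(d2, "features.tsv"))
  writeLines(c("AAAA", "CCCC"), file.path(d2, "barcodes.tsv"))
  b2 <- read_triplet_matrix(file.path(d2, "matrix.mtx"),
                            file.path(d2, "features.tsv"),
                            file.path(d2, "barcodes.tsv"))
  expect_equal(unname(Matrix::colSums(b2$gene_counts)), c(4, 0))
})

test_that("header/feature mismatches and duplicate barcodes are format errors", {
  d <- tempfile(); dir.create(d)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "10 2 1", "1 1 3"), file.path(d, "matrix.mtx"))
  writeLines(sprintf("f%d\tGene Expression", 1:9), file.path(d, "features.tsv"))
  writeLines(c("AAAA", "CCCC"), file.path(d, "barcodes.tsv"))
  expect_error(read_triplet_matrix(file.path(d, "matrix.mtx"),
                                   file.path(d, "features.tsv"),
                                   file.path(d, "barcodes.tsv")),
               "claims 10 features but features table lists 9")
  writeLines(sprintf("f%d\tGene Expression", 1:10), file.path(d, "features.tsv"))
  writeLines(c("AAAA", "AAAA"), file.path(d, "barcodes.tsv"))
  expect_error(read_triplet_matrix(file.path(d, "matrix.mtx"),
                                   file.path(d, "features.tsv"),
                                   file.path(d, "barcodes.tsv")),
               "duplicate barcode: AAAA")
})

test_that("result tables round-trip losslessly through TSV", {
  for (seed in 1:5) {
    tab <- random_result_table(12, seed = seed)
    path <- tempfile(fileext = ".tsv")
    write_result_table(tab, path)
    back <- read_result_table(path)
    expect_equal(names(back), names(tab))
    expect_equal(back$id, tab$id)
    expect_equal(back$count, tab$count)
    expect_equal(back$flag, tab$flag)
    expect_equal(back$value, tab$value, tolerance = 1e-9)
  }
  # empty table: header-only file
  empty <- random_result_table(2)[0, ]
  p <- tempfile()
  write_result_table(empty, p)
  expect_length(readLines(p), 1)
  expect_equal(nrow(read_result_table(p)), 0)
  expect_error(write_result_table(random_result_table(2), "/nonexistent/x/y"),
               "could not write")
})

test_that("subset_bundle respects masks and is idempotent", {
  b <- toy_bundle(matrix(1:12, nrow = 3), meta = NULL)
  all_true <- rep(TRUE, 4)
  expect_equal(as.matrix(subset_bundle(b, all_true)$gene_counts),
               as.matrix(b$gene_counts))
  empty <- subset_bundle(b, rep(FALSE, 4))
  expect_equal(ncol(empty$gene_counts), 0L)
  pick <- c(TRUE, FALSE, TRUE, FALSE)
  sub <- subset_bundle(b, pick)
  expect_equal(bundle_cells(sub), bundle_cells(b)[pick])
  # idempotence: re-subsetting with all-true changes nothing
  expect_equal(as.matrix(subset_bundle(sub, rep(TRUE, 2))$gene_counts),
               as.matrix(sub$gene_counts))
  expect_equal(rownames(sub$cell_meta), bundle_cells(sub))
  expect_error(subset_bundle(b, c(TRUE, FALSE)), "one entry per cell")
})

test_that("bundle invariants are enforced at construction", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  t <- matrix(0L, 1, 2, dimnames = list("t1", c("c1", "c2")))
  expect_error(counts_bundle(m, t[, 2:1, drop = FALSE] * 1), "same cells")
  neg <- m; neg[1] <- -1
  expect_error(counts_bundle(neg, t), "non-negative")
  frac <- m * 1; frac[1] <- 1.5
  expect_error(counts_bundle(frac, t), "integers")
  dup <- m; rownames(dup) <- c("g1", "g1")
  expect_error(counts_bundle(dup, t), "duplicate gene")
})

test_that("reference profiles round-trip through TSV", {
  ref <- make_reference(sim_config(n_cells = 40))
  p <- tempfile()
  write_reference_profiles(ref, p)
  back <- read_reference_profiles(p)
  expect_equal(back$type_names, ref$type_names)
  expect_equal(back$mean_expr, ref$mean_expr, tolerance = 1e-9)
})
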