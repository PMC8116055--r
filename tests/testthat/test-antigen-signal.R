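# bundle with given per-cell tag counts and types
signal_fixture <- function(tag_counts, types, samples = NULL) {
  n <- length(tag_counts)
  cells <- sprintf("cell%03d", seq_len(n))
  gc <- matrix(1L, nrow = 2, ncol = n,
               dimnames = list(c("g1", "g2"), cells))
  tc <- matrix(as.integer(tag_counts), nrow = 1,
               dimnames = list("ova", cells))
  meta <- data.frame(
    sample = if (is.null(samples)) rep("S1", n) else samples,
    timepoint = "d2", fraction = "all", row.names = cells)
  b <- counts_bundle(Matrix::Matrix(gc, sparse = TRUE),
                     Matrix::Matrix(tc, sparse = TRUE), meta)
  list(bundle = b, types = stats::setNames(types, cells))
}

test_that("relative signal divides by the baseline median", {
  fx <- signal_fixture(c(1, 2, 3, 14), c("T", "T", "T", "DC"))
  sig <- relative_signal(fx$bundle, "ova", "T", fx$types)
  expect_equal(sig$baseline_median, rep(2, 4))
  expect_equal(sig$relative_signal[4], 7)
  # baseline cells' median relative signal is exactly 1
  expect_equal(median(sig$relative_signal[sig$cell_type == "T"]), 1)
})

test_that("pseudocount is half the smallest positive relative signal", {
  fx <- signal_fixture(c(0, 1, 4, 2, 2), c("DC", "DC", "DC", "T", "T"))
  sig <- relative_signal(fx$bundle, "ova", "T", fx$types)
  # baseline median 2 -> r = {0, 0.5, 2, 1, 1}; min positive 0.5
  expect_equal(unique(sig$pseudocount), 0.25)
  expect_equal(sig$display, log10(sig$relative_signal + 0.25))
})

test_that("zero baseline median falls back with an explicit flag", {
  # positive-median fallback
  fx <- signal_fixture(c(0, 0, 0, 4, 8), c("T", "T", "T", "T", "DC"))
  sig <- relative_signal(fx$bundle, "ova", "T", fx$types)
  expect_true(all(sig$baseline_degenerate))
  expect_equal(unique(sig$baseline_median), 4)  # median of positive {4}
  # all-zero baseline: divisor 1, r = raw counts
  fx2 <- signal_fixture(c(0, 0, 5), c("T", "T", "DC"))
  sig2 <- relative_signal(fx2$bundle, "ova", "T", fx2$types)
  expect_equal(unique(sig2$baseline_median), 1)
  expect_equal(sig2$relative_signal[3], 5)
  expect_true(all(sig2$baseline_degenerate))
})

test_that("a sample without baseline cells is an error naming the sample", {
  fx <- signal_fixture(c(1, 2, 3, 4), c("T", "T", "DC", "DC"),
                       samples = c("S1", "S1", "S1", "S2"))
  expect_error(relative_signal(fx$bundle, "ova", "T", fx$types),
               "no baseline cells in sample S2")
  expect_error(relative_signal(fx$bundle, "nope", "T", fx$types),
               "unknown tag")
})

test_that("signals and pseudocounts are computed per sample", {
  fx <- signal_fixture(c(2, 8, 4, 40), c("T", "DC", "T", "DC"),
                       samples = c("S1", "S1", "S2", "S2"))
  sig <- relative_signal(fx$bundle, "ova", "T", fx$types)
  expect_equal(sig$relative_signal, c(1, 4, 1, 10))
  expect_equal(sig$baseline_median, c(2, 2, 4, 4))
})

test_that("group comparison reproduces exact rank-sum identities", {
  fx <- signal_fixture(c(6, 7, 8, 9, 10, 1, 2, 3, 4, 5),
                       c(rep("DC", 5), rep("T", 5)))
  sig <- relative_signal(fx$bundle, "ova", "T", fx$types)
  comp <- compare_types(sig, mode = "pairwise")
  expect_equal(nrow(comp), 1)
  expect_equal(comp$p, 2 / 252, tolerance = 1e-12)
  expect_equal(round(comp$p, 4), 0.0079)
  expect_true(comp$conf.low <= comp$estimate &
                comp$estimate <= comp$conf.high)
  # frac_cells across groups sums to 1
  expect_equal(comp$n_cells / 10 + comp$n_cells_ref / 10, 1)
})

test_that("identical groups give p = 1 and near-zero estimate", {
  fx <- signal_fixture(rep(c(1, 2, 3), 2),
                       rep(c("A", "T"), each = 3))
  sig <- relative_signal(fx$bundle, "ova", "T", fx$types)
  suppressWarnings(comp <- compare_types(sig, mode = "pairwise"))
  expect_equal(comp$p, 1)
  expect_equal(comp$estimate, 0)
})

test_that("frac_cells reflects group sizes within the sample", {
  fx <- signal_fixture(c(1:10), c(rep("A", 2), rep("B", 3), rep("T", 5)))
  sig <- relative_signal(fx$bundle, "ova", "T", fx$types)
  comp <- compare_types(sig, mode = "vs_reference", reference_group = "T")
  expect_equal(comp$frac_cells[match(c("A", "B"), comp$group1)],
               c(0.2, 0.3))
  expect_equal(comp$group2, rep("T", 2))
})

test_that("Bonferroni family is the within-sample set of comparisons", {
  set.seed(3)
  fx <- signal_fixture(rpois(40, 5) + 1,
                       rep(c("A", "B", "C", "T"), each = 10))
  sig <- relative_signal(fx$bundle, "ova", "T", fx$types)
  comp <- compare_types(sig, mode = "pairwise")
  expect_equal(nrow(comp), choose(4, 2))
  expect_equal(comp$p_adj, pmin(1, comp$p * nrow(comp)))
})

test_that("rank-based p is invariant to monotone transforms of the signal", {
  set.seed(8)
  fx <- signal_fixture(rpois(30, 4) + 1, rep(c("A", "T"), each = 15))
  sig <- relative_signal(fx$bundle, "ova", "T", fx$types)
  p1 <- compare_types(sig, mode = "pairwise")$p
  sig2 <- sig
  sig2$relative_signal <- log1p(sig$relative_signal)^3
  p2 <- compare_types(sig2, mode = "pairwise")$p
  expect_equal(p1, p2)
})
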