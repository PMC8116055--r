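test_that("complete separation gives the minimal exact two-sided p", {
  r <- wilcoxon_ranksum(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
  expect_equal(r$method, "exact")
  expect_equal(r$p, 2 / 252)
  expect_equal(round(r$p, 3), 0.008)

  r2 <- wilcoxon_ranksum(c(1, 2, 3, 4, 5), c(6, 7, 8, 9))
  expect_equal(r2$p, 2 / 126)
  expect_equal(round(r2$p, 3), 0.016)

  r3 <- wilcoxon_ranksum(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r3$p, 2 / 6)
})

test_that("exact p matches brute-force enumeration and wilcox.test", {
  set.seed(11)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    mine <- wilcoxon_ranksum(x, y, mode = "exact")
    expect_equal(mine$p, brute_wilcox_p(x, y))
    expect_equal(mine$p, wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("one-sided exact tails are coherent", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  lo <- wilcoxon_ranksum(x, y, "less", "exact")$p
  hi <- wilcoxon_ranksum(x, y, "greater", "exact")$p
  expect_lt(lo, 0.06)          # 1/20
  expect_equal(hi, 1)
  expect_equal(wilcoxon_ranksum(x, y, "two_sided", "exact")$p, 2 * lo)
})

test_that("normal approximation is close to exact at n1 = n2 = 12", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12, 0.5)
    pe <- wilcoxon_ranksum(x, y, mode = "exact")$p
    pa <- wilcoxon_ranksum(x, y, mode = "approx")$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("ties force fallback from exact to approximation", {
  expect_warning(r <- wilcoxon_ranksum(c(1, 1, 2), c(2, 3), mode = "exact"),
                 "ties")
  expect_equal(r$method, "approx")
  # identical singletons: p = 1
  expect_equal(wilcoxon_ranksum(1, 1)$p, 1)
  expect_error(wilcoxon_ranksum(numeric(0), 1), "nonempty")
})

test_that("Hodges-Lehmann estimate and CI match hand and base-R oracles", {
  h <- hodges_lehmann(c(1, 2), c(0, 1))
  expect_equal(h$estimate, 1)  # diffs {1, 0, 2, 1}
  x <- c(3, 1, 4); expect_equal(hodges_lehmann(x, x)$estimate, 0)
  # shift equivariance
  set.seed(3)
  a <- rnorm(8); b <- rnorm(6)
  expect_equal(hodges_lehmann(a + 2.5, b)$estimate,
               hodges_lehmann(a, b)$estimate + 2.5)
  # cross-check estimate and interval against wilcox.test
  for (i in 1:10) {
    x <- rnorm(sample(5:15, 1)); y <- rnorm(sample(5:15, 1), 1)
    h <- hodges_lehmann(x, y)
    w <- wilcox.test(x, y, conf.int = TRUE, exact = TRUE)
    expect_equal(h$estimate, unname(w$estimate))
    expect_equal(h$conf.low, w$conf.int[1])
    expect_equal(h$conf.high, w$conf.int[2])
    expect_true(h$conf.low <= h$estimate && h$estimate <= h$conf.high)
  }
})

test_that("HL interval width shrinks with sample size", {
  set.seed(9)
  widths <- sapply(c(6, 12, 24, 48), function(n) {
    mean(replicate(20, {
      h <- hodges_lehmann(rnorm(n), rnorm(n))
      h$conf.high - h$conf.low
    }))
  })
  expect_true(all(diff(widths) < 0))
})

test_that("p-value adjustment matches worked examples and step-up rule", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")

  bky <- adjust_pvalues(c(0.001, 0.01, 0.02, 0.2), "bky_two_stage", q = 0.05)
  expect_equal(bky$n_rejected, 3)
  expect_equal(bky$r1, 3)
  expect_equal(bky$q_stage1, 0.05 / 1.05)
  expect_equal(bky$q_stage2, (0.05 / 1.05) * 4 / 1)
  expect_equal(which(bky$reject), 1:3)

  # BH rejection via adjusted values equals the direct step-up rule, and BKY
  # rejects at least as much as BH, over random inputs
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(5:40, 1))^2
    q <- runif(1, 0.01, 0.2)
    adj <- adjust_pvalues(p, "bh")
    m <- length(p)
    ord <- order(p)
    k <- which(p[ord] <= seq_len(m) / m * q)
    direct <- logical(m)
    if (length(k)) direct[ord[seq_len(max(k))]] <- TRUE
    expect_equal(adj <= q, direct)
    bky <- adjust_pvalues(p, "bky_two_stage", q = q)
    expect_true(all(direct <= bky$reject))  # BKY superset of BH rejections
  }
})

test_that("fraction diluted follows the precursor-weighted formula", {
  expect_equal(fraction_diluted(c(100, 0, 0)), 0)
  expect_equal(fraction_diluted(c(0, 100)), 1)
  expect_equal(fraction_diluted(c(50, 50)), 1 / 3)
  # invariant to rescaling the event counts
  prof <- c(30, 20, 10, 5)
  expect_equal(fraction_diluted(prof), fraction_diluted(prof * 7.3))
  expect_error(fraction_diluted(c(0, 0)), "all-zero")
  # concentrating events in high generations drives the fraction toward 1
  expect_gt(fraction_diluted(c(1, rep(0, 5), 1e5)), 0.999)
})

test_that("standard-curve quantification inverts a linear dilution series", {
  standards <- data.frame(log10_quantity = c(6, 5, 4),
                          cq = c(20, 23.32, 26.64))
  res <- quantify_standard_curve(standards, 23.32, protein_mass = 2)
  expect_equal(res$samples$quantity, 1e5, tolerance = 1e-9)
  expect_equal(res$samples$normalized, 5e4, tolerance = 1e-9)
  expect_equal(res$efficiency, 10^(1 / 3.32) - 1, tolerance = 1e-6)
  expect_equal(res$r_squared, 1)
  expect_false(res$samples$extrapolated)
  # Cq outside the standards is flagged
  res2 <- quantify_standard_curve(standards, 35)
  expect_true(res2$samples$extrapolated)
  # ascending series is rejected
  bad <- data.frame(log10_quantity = c(4, 5, 6), cq = c(20, 23, 26))
  expect_error(quantify_standard_curve(bad, 21), "invalid dilution series")
})
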