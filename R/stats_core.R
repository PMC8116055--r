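# Exact null distribution of the Mann-Whitney U statistic for tie-free group
# sizes m and n: the count of rank assignments giving U = u satisfies
# c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1), i.e. restricted-partition
# counts (at most m parts, each <= n). p[u + 1] = P(U = u), u = 0..m*n.
u_distribution <- function(m, n) {
  stopifnot(m >= 1, n >= 1)
  maxu <- m * n
  prev <- matrix(0, nrow = maxu + 1, ncol = n + 1)  # rows u, cols n' = 0..n
  prev[1, ] <- 1  # m' = 0: only u = 0
  for (mp in seq_len(m)) {
    cur <- matrix(0, nrow = maxu + 1, ncol = n + 1)
    # n' = 0: c(u; mp, 0) = 1 if u == 0
    cur[1, 1] <- 1
    for (np in seq_len(n)) {
      shifted <- c(rep(0, np), prev[seq_len(maxu + 1 - np), np + 1])
      cur[, np + 1] <- shifted + cur[, np]
    }
    prev <- cur
  }
  counts <- prev[, n + 1]
  counts / sum(counts)
}

#' Wilcoxon rank-sum (Mann-Whitney) test with exact or approximate p-value
#'
#' Computes the Mann-Whitney U statistic for `x` relative to `y` using
#' midranks for ties, with the p-value either exact (from the full null
#' distribution of U, i.e. enumeration over all choose(n1+n2, n1) equally
#' likely rank assignments) or by normal approximation with tie correction
#' and continuity correction. The exact route is used when requested, or in
#' `auto` mode when n1 + n2 <= 12 and the pooled data are tie-free; exact
#' enumeration refuses ties and falls back to the approximation.
#'
#' The two-sided exact p-value is defined as min(1, 2 * min(tail
#' probabilities)).
#'
#' @param x,y numeric vectors (both nonempty)
#' @param alternative "two_sided", "less" (x tends smaller) or "greater"
#' @param mode "auto", "exact" or "approx"
#' @return object of class `ranksum_result`: list with `statistic` (U for x),
#'   `p`, `method` ("exact" or "approx"), `alternative`, `tie_var`
#'   (tie-corrected variance used by the approximation, NA for exact)
#' @export
#' @examples
#' wilcoxon_ranksum(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))$p  # 2/252
wilcoxon_ranksum <- function(x, y,
                             alternative = c("two_sided", "less", "greater"),
                             mode = c("auto", "exact", "approx")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stop("both input vectors must be nonempty")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("inputs must be finite and non-missing")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L

  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = (N <= 12L) && !ties
  )
  if (use_exact && ties) {
    warning("ties present; exact enumeration unavailable, using normal approximation")
    use_exact <- FALSE
  }

  if (use_exact) {
    probs <- u_distribution(n1, n2)
    u <- as.integer(round(U))
    p_le <- sum(probs[seq_len(u + 1)])
    p_ge <- sum(probs[(u + 1):length(probs)])
    p <- switch(alternative,
      two_sided = min(1, 2 * min(p_le, p_ge)),
      less = p_le,
      greater = p_ge
    )
    method <- "exact"; tie_var <- NA_real_
  } else {
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      # all values identical: no evidence against the null
      p <- 1
    } else {
      mu <- n1 * n2 / 2
      z_num <- switch(alternative,
        two_sided = U - mu - sign(U - mu) * 0.5,
        less = U - mu + 0.5,
        greater = U - mu - 0.5
      )
      z <- z_num / sqrt(sigma2)
      p <- switch(alternative,
        two_sided = min(1, 2 * stats::pnorm(-abs(z))),
        less = stats::pnorm(z),
        greater = stats::pnorm(z, lower.tail = FALSE)
      )
    }
    method <- "approx"
    tie_var <- sigma2
  }
  structure(
    list(statistic = U, p = p, method = method,
         alternative = alternative, tie_var = tie_var,
         n1 = n1, n2 = n2),
    class = "ranksum_result"
  )
}

#' Hodges-Lehmann shift estimate with confidence interval
#'
#' Estimate is the median of all n1*n2 pairwise differences x_i - y_j. The
#' confidence interval comes from the exact rank-sum distribution (order
#' statistics of the sorted pairwise differences) for small tie-free inputs,
#' and from the normal-approximation index otherwise. The achieved confidence
#' level is reported in the exact case.
#'
#' @param x,y numeric vectors
#' @param level confidence level in (0, 1); default 0.95
#' @return list with `estimate`, `conf.low`, `conf.high`, `level`,
#'   `achieved_level` (NA for the approximate route), `method`
#' @export
hodges_lehmann <- function(x, y, level = 0.95) {
  if (length(x) == 0L || length(y) == 0L) stop("both inputs must be nonempty")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  n1 <- length(x); n2 <- length(y)
  diffs <- sort(as.vector(outer(x, y, "-")))
  est <- stats::median(diffs)
  alpha <- 1 - level
  nprod <- n1 * n2
  exact_ok <- (n1 + n2) <= 40
  if (exact_ok) {
    probs <- u_distribution(n1, n2)
    cum <- cumsum(probs)
    # smallest u with P(U <= u) >= alpha/2
    qu <- which(cum >= alpha / 2)[1] - 1L
    if (qu == 0L) qu <- 1L
    ql <- nprod - qu
    achieved <- 1 - 2 * (if (qu >= 1) cum[qu] else 0)
    lo <- diffs[qu]
    hi <- diffs[ql + 1L]
    method <- "exact"
  } else {
    k <- round(nprod / 2 - stats::qnorm(1 - alpha / 2) *
                 sqrt(n1 * n2 * (n1 + n2 + 1) / 12))
    k <- max(1L, as.integer(k))
    lo <- diffs[k]
    hi <- diffs[nprod - k + 1L]
    achieved <- NA_real_
    method <- "approx"
  }
  # degenerate tiny samples: interval still brackets the estimate
  lo <- min(lo, est); hi <- max(hi, est)
  list(estimate = est, conf.low = lo, conf.high = hi,
       level = level, achieved_level = achieved, method = method)
}

#' Multiple-testing adjustment: Bonferroni, BH, and BKY two-stage
#'
#' `bonferroni` and `bh` return adjusted p-values (via [stats::p.adjust()]).
#' `bky_two_stage` runs the adaptive two-stage step-up procedure of
#' Benjamini, Krieger and Yekutieli at level `q`: stage 1 is BH at
#' q' = q/(1+q), yielding r1 rejections; if r1 is 0 or m the procedure stops
#' there, otherwise stage 2 is BH at q'' = q' * m/(m - r1). Returns the
#' rejection indicator set plus stagewise diagnostics and an emulated
#' adjusted-p vector (BH-adjusted p scaled by (1+q)(m-r1)/m, capped at 1,
#' whose comparison against q reproduces the stage-2 rejections).
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @param method "bonferroni", "bh" or "bky_two_stage"
#' @param q FDR level for the BKY procedure (default 0.05)
#' @return adjusted p-value vector, or for BKY a list with `reject` (logical),
#'   `n_rejected`, `r1`, `q_stage1`, `q_stage2`, `p_adj_emulated`
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "bky_two_stage"),
                           q = 0.05) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (method == "bonferroni") return(stats::p.adjust(p, "bonferroni"))
  if (method == "bh") return(stats::p.adjust(p, "BH"))
  q1 <- q / (1 + q)
  bh_adj <- stats::p.adjust(p, "BH")
  r1 <- sum(bh_adj <= q1)
  if (r1 == 0L || r1 == m) {
    reject <- bh_adj <= q1
    q2 <- NA_real_
    scale <- (1 + q)  # stage-1 emulation
  } else {
    q2 <- q1 * m / (m - r1)
    reject <- bh_adj <= q2
    scale <- (1 + q) * (m - r1) / m
  }
  list(
    reject = reject,
    n_rejected = sum(reject),
    r1 = r1,
    q_stage1 = q1,
    q_stage2 = q2,
    p_adj_emulated = pmin(1, bh_adj * scale)
  )
}

#' Fraction of cells that divided, from a proliferation-dye generation profile
#'
#' The precursor-weighted fraction diluted:
#' sum_{i>=1}(N_i / 2^i) / sum_{i>=0}(N_i / 2^i), where generation 0 is the
#' undivided population and N_i the number of events in generation i. Each
#' observed cell in generation i is weighted by 2^-i, the number of precursor
#' cells it represents, so the statistic is the fraction of *precursors* that
#' divided at least once.
#'
#' @param profile non-negative numeric vector N_0, N_1, ... (generation 0 first)
#' @return value in \[0, 1\]
#' @export
#' @examples
#' fraction_diluted(c(50, 50))  # 1/3
fraction_diluted <- function(profile) {
  if (length(profile) == 0L || anyNA(profile) || any(profile < 0))
    stop("profile must be a non-negative vector")
  if (sum(profile) == 0) stop("all-zero division profile")
  i <- seq_along(profile) - 1
  w <- profile / 2^i
  sum(w[i >= 1]) / sum(w)
}

#' qPCR absolute quantification from an external standard curve
#'
#' Fits Cq = slope * log10(Q) + intercept by least squares on a dilution
#' series, inverts the fit for unknown Cq values, and normalizes recovered
#' quantities to lysate protein content. Reports r-squared and amplification
#' efficiency 10^(-1/slope) - 1; unknowns whose Cq falls outside the range
#' spanned by the standards are flagged extrapolated.
#'
#' @param standards data.frame with columns `log10_quantity` and `cq`
#'   (>= 3 points spanning >= 2 log decades)
#' @param unknowns Cq vector for the samples to quantify
#' @param protein_mass protein amounts used for normalization (recycled)
#' @return list with `slope`, `intercept`, `r_squared`, `efficiency`, and a
#'   data.frame `samples` (cq, quantity, normalized, extrapolated)
#' @export
quantify_standard_curve <- function(standards, unknowns, protein_mass = 1) {
  stopifnot(is.data.frame(standards),
            all(c("log10_quantity", "cq") %in% names(standards)))
  if (nrow(standards) < 3)
    stop("at least 3 standards are required")
  span <- diff(range(standards$log10_quantity))
  if (span < 2)
    stop("standards must span at least 2 log10 decades (span = ", span, ")")
  fit <- stats::lm(cq ~ log10_quantity, data = standards)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) stop("invalid dilution series: fitted slope is not negative")
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((standards$cq - mean(standards$cq))^2)
  eff <- 10^(-1 / slope) - 1
  logq <- (unknowns - intercept) / slope
  qty <- 10^logq
  cq_range <- range(stats::fitted(fit))
  extrap <- unknowns < min(cq_range) | unknowns > max(cq_range)
  list(
    slope = slope, intercept = intercept,
    r_squared = r2, efficiency = eff,
    samples = data.frame(
      cq = unknowns,
      quantity = qty,
      normalized = qty / protein_mass,
      extrapolated = extrap
    )
  )
}
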