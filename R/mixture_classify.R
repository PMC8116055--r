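#' Fit a two-component Gaussian mixture by EM
#'
#' Expectation-maximization for a two-component univariate Gaussian mixture
#' with unequal variances, used to split log-scale antigen signal into low
#' and high populations. Initialization is deterministic — means at the
#' 25th/75th percentiles, both sds at half the overall sd, equal weights —
#' with optional random restarts for robustness checks. Component sds are
#' floored at `min_sd` to prevent degenerate single-point spikes, and the
#' components are relabeled so that mu1 < mu2 ("high" is always the upper
#' component). The log-likelihood is checked to be non-decreasing across
#' iterations.
#'
#' @param values numeric vector (n >= 10, finite, not all identical)
#' @param tol convergence tolerance on the log-likelihood change
#' @param max_iter maximum EM iterations
#' @param seed RNG seed (used only when `n_restarts > 0`)
#' @param min_sd sd floor; default 1e-3 times the overall sd
#' @param n_restarts additional random initializations; the best
#'   log-likelihood fit is kept
#' @return object of class `MixtureFit`: `pi` (length 2, sums to 1), `mu`
#'   (mu1 < mu2), `sd`, `loglik` (final), `loglik_trace`, `n_iter`,
#'   `converged`, `posterior_high` (per-observation P(high)), `labels`
#'   ("low"/"high" by posterior >= 0.5), `scale` descriptor
#' @export
fit_gmm2 <- function(values, tol = 1e-8, max_iter = 1000, seed = 1,
                     min_sd = NULL, n_restarts = 0,
                     scale = "log10(relative_signal + pseudocount)") {
  if (length(values) < 10) stop("need at least 10 observations")
  if (any(!is.finite(values))) stop("values must be finite")
  overall_sd <- stats::sd(values)
  if (overall_sd == 0) stop("degenerate input: all values identical")
  if (is.null(min_sd)) min_sd <- 1e-3 * overall_sd

  run_em <- function(mu, sd, pi) {
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0
    ll_old <- -Inf
    repeat {
      iter <- iter + 1
      d1 <- stats::dnorm(values, mu[1], sd[1]) * pi[1]
      d2 <- stats::dnorm(values, mu[2], sd[2]) * pi[2]
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      gamma2 <- d2 / tot
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_old <- ll
      n2 <- sum(gamma2); n1 <- length(values) - n2
      # guard against a component collapsing to zero responsibility
      n1 <- max(n1, 1e-10); n2 <- max(n2, 1e-10)
      pi <- c(n1, n2) / length(values)
      mu <- c(sum((1 - gamma2) * values) / n1, sum(gamma2 * values) / n2)
      sd <- sqrt(c(sum((1 - gamma2) * (values - mu[1])^2) / n1,
                   sum(gamma2 * (values - mu[2])^2) / n2))
      sd <- pmax(sd, min_sd)
    }
    list(mu = mu, sd = sd, pi = pi, trace = trace, converged = converged,
         n_iter = iter, gamma2 = gamma2, ll = ll)
  }

  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  if (q[1] == q[2]) q <- range(values)
  inits <- list(list(mu = q, sd = rep(max(overall_sd / 2, min_sd), 2),
                     pi = c(0.5, 0.5)))
  if (n_restarts > 0) {
    set.seed(seed)
    for (i in seq_len(n_restarts)) {
      mu0 <- sort(sample(values, 2))
      if (mu0[1] == mu0[2]) mu0 <- mu0 + c(-1, 1) * overall_sd / 4
      inits[[i + 1]] <- list(mu = mu0,
                             sd = rep(max(overall_sd / 2, min_sd), 2),
                             pi = c(0.5, 0.5))
    }
  }
  fits <- lapply(inits, function(ini) run_em(ini$mu, ini$sd, ini$pi))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]

  if (any(diff(best$trace) < -1e-6 * max(1, abs(best$trace[1]))))
    stop("internal error: EM log-likelihood decreased")
  # relabel so the larger-mean component is "high"
  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu); best$sd <- rev(best$sd); best$pi <- rev(best$pi)
    best$gamma2 <- 1 - best$gamma2
  }
  structure(list(
    pi = best$pi, mu = best$mu, sd = best$sd,
    loglik = best$ll, loglik_trace = best$trace,
    n_iter = best$n_iter, converged = best$converged,
    posterior_high = best$gamma2,
    labels = ifelse(best$gamma2 >= 0.5, "high", "low"),
    scale = scale, min_sd = min_sd
  ), class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf(
    "2-component Gaussian mixture (%s)\n  pi = %.3f/%.3f  mu = %.3f/%.3f  sd = %.3f/%.3f\n  loglik %.3f after %d iterations (%s)\n",
    x$scale, x$pi[1], x$pi[2], x$mu[1], x$mu[2], x$sd[1], x$sd[2],
    x$loglik, x$n_iter, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Classify cells into antigen-low/high populations
#'
#' Fits a two-component Gaussian mixture on the log10 display value of the
#' relative antigen signal, pooled over all cells or independently per cell
#' type, and assigns hard labels by posterior >= 0.5. Groups with fewer than
#' `min_cells` cells are skipped with a warning (their labels are NA).
#'
#' @param signal an `AntigenSignalTable` from [relative_signal()]
#' @param grouping "pooled" (one fit) or "per_type"
#' @param min_cells smallest group eligible for a fit (default 10)
#' @param ... further arguments to [fit_gmm2()]
#' @return list with `fits` (named per group; includes per-class means,
#'   the display-scale analogue of the population mean lines), `labels`
#'   (data.frame cell_id, group, posterior_high, antigen_class)
#' @export
classify_antigen <- function(signal, grouping = c("pooled", "per_type"),
                             min_cells = 10, ...) {
  grouping <- match.arg(grouping)
  groups <- if (grouping == "pooled") rep("all", nrow(signal)) else
    signal$cell_type
  fits <- list()
  labels <- data.frame(cell_id = signal$cell_id, group = groups,
                       posterior_high = NA_real_,
                       antigen_class = NA_character_,
                       stringsAsFactors = FALSE)
  for (g in unique(groups)) {
    idx <- groups == g
    if (sum(idx) < min_cells) {
      warning("group ", g, " has ", sum(idx), " cells (< ", min_cells,
              "); skipped")
      next
    }
    fit <- fit_gmm2(signal$display[idx], ...)
    x <- signal$display[idx]
    fit$class_means <- c(
      low = mean(x[fit$labels == "low"]),
      high = mean(x[fit$labels == "high"])
    )
    fits[[g]] <- fit
    labels$posterior_high[idx] <- fit$posterior_high
    labels$antigen_class[idx] <- fit$labels
  }
  list(fits = fits, labels = labels, grouping = grouping)
}
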