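#' Hurwitz zeta function
#'
#' sum_{k>=0} (a + k)^(-s) for s > 1, by direct summation of the first terms
#' plus an Euler-Maclaurin tail correction. Normalizes the discrete power-law
#' distribution over \{a, a+1, ...\}.
#'
#' @param s Exponent (> 1).
#' @param a Offset (>= 1), the lower support bound.
#' @return The zeta value.
#' @keywords internal
hurwitz_zeta <- function(s, a = 1) {
  if (s <= 1) stopf("hurwitz_zeta requires s > 1")
  n <- 30
  k <- 0:(n - 1)
  head_sum <- sum((a + k)^(-s))
  b <- a + n
  tail <- b^(1 - s) / (s - 1) + 0.5 * b^(-s) + s / 12 * b^(-s - 1) -
    s * (s + 1) * (s + 2) / 720 * b^(-s - 3)
  head_sum + tail
}

powerlaw_loglik <- function(alpha, x, xmin) {
  -length(x) * log(hurwitz_zeta(alpha, xmin)) - alpha * sum(log(x))
}

powerlaw_mle <- function(x, xmin) {
  opt <- optimize(function(a) powerlaw_loglik(a, x, xmin),
                  interval = c(1 + 1e-6, 25), maximum = TRUE)
  list(alpha = opt$maximum, loglik = opt$objective)
}

powerlaw_cdf <- function(x, alpha, xmin) {
  # P(X <= x) over support {xmin, xmin+1, ...}
  z <- hurwitz_zeta(alpha, xmin)
  vapply(x, function(v) 1 - hurwitz_zeta(alpha, v + 1) / z, 0)
}

powerlaw_ks <- function(x, alpha, xmin) {
  xs <- sort(unique(x))
  emp <- ecdf(x)(xs)
  fit <- powerlaw_cdf(xs, alpha, xmin)
  max(abs(emp - fit))
}

#' Draw from the discrete power-law (zeta) distribution
#'
#' P(X = k) proportional to k^(-alpha) for integer k >= xmin. The bulk is
#' drawn by table inversion; the far tail (beyond the tabulated coverage) by
#' the asymptotic inverse of the survival function.
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param xmin Lower support bound (integer >= 1).
#' @return Integer-valued numeric vector of length `n`.
#' @keywords internal
make_rzeta <- function(alpha, xmin = 1) {
  if (alpha <= 1) stopf("alpha must exceed 1")
  z <- hurwitz_zeta(alpha, xmin)
  # table long enough that the untabulated tail mass is ~1e-6 (capped; the
  # far tail is drawn from the asymptotic inverse survival function)
  x_star <- (1e-6 * (alpha - 1) * z)^(-1 / (alpha - 1))
  len <- as.integer(min(1e5, max(1024, ceiling(x_star))))
  vals <- xmin:(xmin + len - 1L)
  cdf <- cumsum(vals^(-alpha) / z)
  coverage <- cdf[len]
  function(n) {
    u <- runif(n)
    out <- numeric(n)
    bulk <- u <= coverage
    out[bulk] <- vals[findInterval(u[bulk], cdf) + 1L]
    if (any(!bulk)) {
      # tail: P(X >= x) ~ x^(1-alpha) / ((alpha-1) z)
      out[!bulk] <- ceiling((((1 - u[!bulk]) * (alpha - 1) * z))^(-1 / (alpha - 1)))
    }
    out
  }
}

rzeta <- function(n, alpha, xmin = 1) make_rzeta(alpha, xmin)(n)

#' Fit a discrete power law to a degree vector
#'
#' Three complementary views of scale-free behavior, computed on the nonzero
#' degrees: (1) `gamma` and `r_squared` from the linear regression of
#' log P(k) on log k (the decay exponent of the degree distribution);
#' (2) `alpha`, the exponent of the discrete power law P(X = x) ~ x^(-alpha)
#' fitted by maximum likelihood with zeta normalization, and its `loglik`;
#' (3) the Kolmogorov-Smirnov statistic between the empirical and fitted
#' distributions, with a bootstrap p-value under the fitted model (the null
#' hypothesis that the data are power-law distributed; p >= 0.05 together
#' with a low KS statistic fails to reject the power law).
#'
#' @param degrees Numeric degree vector; zeros are dropped.
#' @param bootstrap_reps Bootstrap replicates for the KS p-value.
#' @param seed Seed for the bootstrap.
#' @param xmin Lower cut-off; defaults to the smallest positive degree (whole
#'   distributions are fitted).
#' @return Object of class `ef_powerlaw`: `gamma`, `r_squared`, `alpha`,
#'   `ks_stat`, `ks_p`, `loglik`, `xmin`, `n`, `bootstrap_reps`.
#' @export
fit_power_law <- function(degrees, bootstrap_reps = 100, seed = 1L,
                          xmin = NULL) {
  k <- degrees[!is.na(degrees) & degrees > 0]
  if (any(k != floor(k))) k <- round(k)
  if (length(k) < 10)
    stopf("need at least 10 nonzero degrees (got %d)", length(k))
  if (length(unique(k)) < 2)
    stopf("degenerate degree distribution: all degrees equal %s", k[1])
  if (is.null(xmin)) xmin <- min(k)
  k <- k[k >= xmin]

  tab <- table(k)
  kk <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(k)
  reg <- lm(log(pk) ~ log(kk))
  gamma <- abs(unname(coef(reg)[2]))
  r2 <- summary(reg)$r.squared

  mle <- powerlaw_mle(k, xmin)
  ks <- powerlaw_ks(k, mle$alpha, xmin)

  ks_p <- NA_real_
  if (bootstrap_reps > 0) {
    sampler <- make_rzeta(mle$alpha, xmin)
    boot <- with_seed(seed, vapply(seq_len(bootstrap_reps), function(i) {
      sim <- sampler(length(k))
      powerlaw_ks(sim, powerlaw_mle(sim, xmin)$alpha, xmin)
    }, 0))
    ks_p <- mean(boot >= ks)
  }
  structure(list(gamma = gamma, r_squared = r2, alpha = mle$alpha,
                 ks_stat = ks, ks_p = ks_p, loglik = mle$loglik,
                 xmin = xmin, n = length(k),
                 bootstrap_reps = bootstrap_reps),
            class = "ef_powerlaw")
}

#' @export
print.ef_powerlaw <- function(x, ...) {
  cat(sprintf("<ef_powerlaw> n=%d xmin=%d | gamma=%.3f (R2=%.3f) | alpha=%.3f | KS=%.4f p=%s\n",
              x$n, x$xmin, x$gamma, x$r_squared, x$alpha, x$ks_stat,
              format(x$ks_p)))
  invisible(x)
}
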