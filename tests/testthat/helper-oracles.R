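# Independent oracles and small fixture builders used across the suite.
# Each oracle is a brute-force or closed-form computation kept deliberately
# separate from the package's own algorithms.

# Brute-force LAD/quantile optimum: an optimal fit interpolates ncol(x)
# observations, so enumerate every exact fit through an ncol(x)-subset and
# take the smallest check loss.
lad_oracle <- function(x, y, tau = 0.5) {
  k <- ncol(x)
  subsets <- combn(nrow(x), k)
  best <- Inf
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    b <- tryCatch(solve(x[idx, , drop = FALSE], y[idx]), error = function(e) NULL)
    if (is.null(b)) next
    r <- y - drop(x %*% b)
    best <- min(best, sum(r * (tau - (r < 0))))
  }
  best
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments
# (midranks handled naturally), using the same two-sided definition as the
# package: 2 * min(P(V <= v), P(V >= v)) capped at 1.
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  p_le <- mean(vs <= v + 1e-9)
  p_ge <- mean(vs >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Monte-Carlo permutation p-value for the trend statistic T = sum(score * rank).
trend_perm_oracle <- function(values, group, scores, nperm = 1e5, seed = 42) {
  set.seed(seed)
  lev <- sort(unique(group))
  cvec <- scores[match(group, lev)]
  a <- rank(values)
  t_obs <- sum(cvec * a)
  e_t <- length(a) * mean(cvec) * mean(a)
  t_perm <- replicate(nperm, sum(sample(cvec) * a))
  mean(abs(t_perm - e_t) >= abs(t_obs - e_t) - 1e-9)
}

# Small deterministic cohort with no ceiling, for exercising fitters.
toy_cohort <- function(n = 60, seed = 123, intercept = 0.28, noise = 0.05) {
  set.seed(seed)
  co <- data.frame(
    PWB = sample(5:28, n, replace = TRUE),
    SWB = sample(5:28, n, replace = TRUE),
    EWB = sample(4:24, n, replace = TRUE),
    FWB = sample(5:28, n, replace = TRUE),
    BCS = sample(8:40, n, replace = TRUE)
  )
  co$utility <- intercept + 0.008 * co$PWB + 0.004 * co$EWB +
    0.004 * co$FWB + 0.002 * co$BCS + rnorm(n, 0, noise)
  co$status <- sample(0:4, n, replace = TRUE)
  co
}

expect_rounds_to <- function(x, printed, digits = 4) {
  expect_equal(round(x, digits), printed, tolerance = 1e-9)
}
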