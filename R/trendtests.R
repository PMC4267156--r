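#' Wilcoxon signed-rank test for paired utilities
#'
#' Two-sided signed-rank test of observed vs predicted utilities within a
#' group.  Zero differences are dropped before ranking (the classic
#' Wilcoxon convention); ties among the remaining absolute differences get
#' midranks.  With 25 or fewer nonzero pairs the exact permutation null is
#' used (computed by dynamic programming over the 2^n sign assignments,
#' which handles midranks exactly); otherwise a normal approximation with
#' continuity and tie correction.  If every difference is zero the test
#' carries no evidence and p = 1 by convention.
#'
#' @param observed,predicted Paired numeric vectors.
#' @param exact_limit Largest number of nonzero pairs for the exact branch.
#' @return List with `statistic` (V, the positive-rank sum), `n` (nonzero
#'   pairs), `p.value`, and `method` ("exact" or "normal").
#' @examples
#' signed_rank_test(c(1, 2, 3, 4), c(1.1, 1.8, 3.4, 3.9))
#' @export
signed_rank_test <- function(observed, predicted, exact_limit = 25L) {
  if (length(observed) != length(predicted)) stop("paired vectors required")
  d <- observed - predicted
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, n = 0L, p.value = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # exact null via DP on doubled ranks (midranks become integers)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)  # counts[w+1] = #assignments with doubled sum w
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(total + 1L - rr)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(w + 1L)])
    p_ge <- sum(probs[seq.int(w + 1L, total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = v, n = n, p.value = p, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sigma2)
  list(statistic = v, n = n, p.value = 2 * pnorm(-abs(z)), method = "normal")
}

#' Cuzick's nonparametric test for trend across ordered groups
#'
#' Rank-based trend test: with all observations ranked jointly (midranks
#' for ties), the statistic T = sum of group score x rank is standardized
#' by its exact permutation mean and variance,
#' `E(T) = N c̄ ā` and `Var(T) = Σ(c - c̄)² Σ(a - ā)² / (N - 1)`,
#' where c are the per-observation group scores and a the ranks.  With two
#' groups this reduces exactly to the (tie-corrected, uncorrected-for-
#' continuity) Wilcoxon rank-sum test.
#'
#' @param values Numeric outcome vector.
#' @param group Group membership, coercible to ordered numeric scores
#'   (e.g. performance status 0..3).
#' @param scores Optional numeric score per group level (default: the sorted
#'   unique group values).
#' @return List with `z`, `p.value` (two-sided), `p.one.sided`
#'   (increasing-trend alternative), `statistic` (T).
#' @examples
#' cuzick_trend(c(1, 2, 2, 3, 4, 5), group = c(0, 0, 1, 1, 2, 2))
#' @export
cuzick_trend <- function(values, group, scores = NULL) {
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- group[ok]
  lev <- sort(unique(group))
  if (length(lev) < 2L) stop("degenerate: need at least 2 distinct groups")
  if (is.null(scores)) {
    scores <- suppressWarnings(as.numeric(as.character(lev)))
    if (anyNA(scores)) scores <- seq_along(lev)
  }
  if (length(scores) != length(lev)) stop("one score per group level required")
  cvec <- scores[match(group, lev)]
  a <- rank(values)
  N <- length(values)
  t_stat <- sum(cvec * a)
  e_t <- N * mean(cvec) * mean(a)
  v_t <- sum((cvec - mean(cvec))^2) * sum((a - mean(a))^2) / (N - 1)
  if (v_t <= 0) {
    return(list(z = 0, p.value = 1, p.one.sided = 0.5, statistic = t_stat))
  }
  z <- (t_stat - e_t) / sqrt(v_t)
  list(z = z, p.value = 2 * pnorm(-abs(z)), p.one.sided = pnorm(-z),
       statistic = t_stat)
}
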