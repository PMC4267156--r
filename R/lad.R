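# Least-absolute-deviation / quantile regression core.
#
# The tau-th regression quantile minimizes the check loss
#   sum_i rho_tau(y_i - x_i'b),  rho_tau(r) = r * (tau - 1(r < 0)).
# Solved here by iteratively reweighted least squares on a smoothed check
# loss with a decreasing smoothing floor, then refined by a basic-solution
# search: an optimal quantile fit interpolates ncol(X) observations, so
# exact fits through subsets of the smallest-|residual| observations are
# enumerated and the best objective kept.  Deterministic: no randomness,
# ties resolved by the fixed enumeration order.

check_loss <- function(r, tau = 0.5) {
  sum(r * (tau - (r < 0)))
}

# weighted LS via normal equations (k is tiny, so this dominates the QR
# route on speed); falls back to QR if the cross-product is near-singular
wls_coef <- function(x, y, w) {
  xw <- x * w
  cf <- tryCatch(
    drop(solve(crossprod(xw, x), crossprod(xw, y))),
    error = function(e) NULL
  )
  if (is.null(cf)) {
    ws <- sqrt(w)
    cf <- lm.fit(x * ws, y * ws)$coefficients
    if (anyNA(cf)) return(NULL)  # singular weighted system
  }
  cf
}

lad_irls <- function(x, y, tau = 0.5, start = NULL, max_iter = 120L) {
  n <- nrow(x)
  beta <- start
  if (is.null(beta)) {
    fit <- lm.fit(x, y)
    if (anyNA(fit$coefficients)) {
      stop("collinear design: cannot initialize quantile fit")
    }
    beta <- fit$coefficients
  }
  best <- beta
  r <- y - drop(x %*% beta)
  best_obj <- check_loss(r, tau)
  eps_schedule <- c(1e-3, 1e-6, 1e-9)
  iters <- 0L
  for (eps in eps_schedule) {
    stalled <- 0L
    for (it in seq_len(max_iter)) {
      iters <- iters + 1L
      asym <- ifelse(r >= 0, tau, 1 - tau)
      w <- asym / pmax(abs(r), eps)
      beta_new <- wls_coef(x, y, w)
      if (is.null(beta_new)) break
      r_new <- y - drop(x %*% beta_new)
      obj_new <- check_loss(r_new, tau)
      improved <- obj_new < best_obj - 1e-13 * (1 + abs(best_obj))
      if (obj_new < best_obj) {
        best <- beta_new
        best_obj <- obj_new
      }
      step <- max(abs(beta_new - beta)) / (1 + max(abs(beta)))
      beta <- beta_new
      r <- r_new
      stalled <- if (improved) 0L else stalled + 1L
      if (step < 1e-12 || stalled >= 4L) break
    }
  }
  list(coefficients = best, objective = best_obj, iterations = iters)
}

# Exact-fit refinement over subsets of near-active observations.
lad_polish <- function(x, y, tau, beta, objective) {
  n <- nrow(x)
  k <- ncol(x)
  if (n <= k) return(list(coefficients = beta, objective = objective))
  r <- y - drop(x %*% beta)
  m <- if (n <= 500L) min(n, k + 7L) else if (n <= 5000L) k + 4L else k + 2L
  cand <- order(abs(r))[seq_len(m)]
  subsets <- combn(cand, k)
  best <- beta
  best_obj <- objective
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    xs <- x[idx, , drop = FALSE]
    b <- tryCatch(solve(xs, y[idx]), error = function(e) NULL)
    if (is.null(b)) next
    obj <- check_loss(y - drop(x %*% b), tau)
    if (obj < best_obj - 1e-14 * (1 + abs(best_obj))) {
      best <- b
      best_obj <- obj
    }
  }
  list(coefficients = best, objective = best_obj)
}

lad_fit <- function(x, y, tau = 0.5, start = NULL) {
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly inside (0, 1)")
  if (nrow(x) <= ncol(x)) stop("need more observations than design columns")
  irls <- lad_irls(x, y, tau, start = start)
  pol <- lad_polish(x, y, tau, irls$coefficients, irls$objective)
  list(coefficients = setNames(pol$coefficients, colnames(x)),
       objective = pol$objective, iterations = irls$iterations)
}

# Nonparametric bootstrap standard errors for a refitting function
# fit_fun(x, y) -> coefficient vector.  Seeded and deterministic.
bootstrap_se <- function(x, y, fit_fun, B = 200L, seed = 1L) {
  n <- nrow(x)
  est <- matrix(NA_real_, nrow = B, ncol = ncol(x))
  rng <- local({ set.seed(seed); lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE)) })
  for (b in seq_len(B)) {
    idx <- rng[[b]]
    cf <- tryCatch(fit_fun(x[idx, , drop = FALSE], y[idx]), error = function(e) NULL)
    if (!is.null(cf)) est[b, ] <- cf
  }
  apply(est, 2L, sd, na.rm = TRUE)
}
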