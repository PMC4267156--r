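#' Fit the mapping by ordinary least squares
#'
#' The workhorse fitters all take a design matrix with a leading intercept
#' column (as produced by [build_design()]) and the utility outcome, and
#' return a [fit_mapping()]-style `factb_mapping` object.  OLS minimizes the
#' sum of squared residuals; with an intercept present, residuals sum to
#' zero, so the mean predicted utility always equals the mean observed
#' utility on the training data.
#'
#' @param x Design matrix (n x (p+1), leading intercept column).
#' @param y Utility outcome vector.
#' @return A `factb_mapping` object.
#' @seealso [fit_mapping()] for the formula-free front end.
#' @export
fit_ols <- function(x, y) {
  check_design(x, y)
  fit <- lm.fit(x, y)
  if (fit$rank < ncol(x) || anyNA(fit$coefficients)) {
    stop("collinear design: rank ", fit$rank, " < ", ncol(x), " columns")
  }
  beta <- fit$coefficients
  res <- y - drop(x %*% beta)
  k <- ncol(x)
  n <- length(y)
  sigma2 <- sum(res^2) / (n - k)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(x), colnames(x))
  new_mapping(
    method = "ols", coefficients = setNames(beta, colnames(x)),
    n = n, y = y, fitted = drop(x %*% beta),
    sigma = sqrt(sigma2), vcov = vcov, se = sqrt(diag(vcov)),
    converged = TRUE, iterations = 1L
  )
}

#' Fit the mapping by an upper-censored Tobit model
#'
#' Utilities are treated as realizations of a latent normal variable
#' censored from above at `censor_point` (the ceiling 1).  The maximum
#' likelihood estimate over (coefficients, sigma) combines normal density
#' terms for uncensored observations with survival terms for observations at
#' the ceiling.  Optimization is quasi-Newton (BFGS) on (beta, log sigma)
#' with analytic gradients, started at the OLS solution.  Prediction uses
#' the latent linear index, which may exceed 1.
#'
#' @inheritParams fit_ols
#' @param censor_point Upper censoring threshold (default 1).
#' @return A `factb_mapping` object (with `sigma` and `vcov` from the
#'   inverse observed information).
#' @export
fit_tobit <- function(x, y, censor_point = 1) {
  check_design(x, y)
  if (any(y > censor_point + 1e-12)) {
    stop("observations above the censor point: Tobit model undefined")
  }
  cens <- y >= censor_point - 1e-12
  if (all(cens)) stop("degenerate likelihood: all observations censored")
  k <- ncol(x)
  n <- length(y)

  ols <- lm.fit(x, y)
  if (anyNA(ols$coefficients)) stop("collinear design")
  start <- c(ols$coefficients, log(max(sd(ols$residuals), 1e-3)))

  xu <- x[!cens, , drop = FALSE]; yu <- y[!cens]
  xc <- x[cens, , drop = FALSE]

  nll <- function(par) {
    beta <- par[seq_len(k)]; s <- exp(par[k + 1L])
    zu <- (yu - drop(xu %*% beta)) / s
    ll <- sum(dnorm(zu, log = TRUE) - log(s))
    if (nrow(xc)) {
      ac <- (drop(xc %*% beta) - censor_point) / s
      ll <- ll + sum(pnorm(ac, log.p = TRUE))
    }
    -ll
  }
  ngr <- function(par) {
    beta <- par[seq_len(k)]; s <- exp(par[k + 1L])
    zu <- (yu - drop(xu %*% beta)) / s
    gb <- drop(crossprod(xu, zu)) / s
    gs <- sum(zu^2 - 1)
    if (nrow(xc)) {
      ac <- (drop(xc %*% beta) - censor_point) / s
      lambda <- exp(dnorm(ac, log = TRUE) - pnorm(ac, log.p = TRUE))
      gb <- gb + drop(crossprod(xc, lambda)) / s
      gs <- gs - sum(lambda * ac)
    }
    -c(gb, gs)
  }

  opt <- optim(start, nll, ngr, method = "BFGS",
               control = list(maxit = 1000L, reltol = 1e-14))
  par <- opt$par
  # Newton polish: BFGS can stall short of the gradient tolerance on large
  # cohorts; the likelihood is smooth, so a few damped Newton steps finish it
  for (step in 1:25) {
    g <- ngr(par)
    if (max(abs(g)) < 1e-8) break
    hess <- tryCatch(optimHess(par, nll, ngr), error = function(e) NULL)
    delta <- if (!is.null(hess)) {
      tryCatch(solve(hess, g), error = function(e) NULL)
    }
    if (is.null(delta)) break
    f0 <- nll(par)
    lam <- 1
    repeat {
      cand <- par - lam * delta
      if (is.finite(nll(cand)) && nll(cand) <= f0 + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- par; break }
    }
    if (identical(cand, par)) break
    par <- cand
  }
  gnorm <- max(abs(ngr(par)))
  converged <- is.finite(gnorm) && gnorm < 1e-6
  if (!converged) {
    warning(sprintf("Tobit optimization did not meet the gradient tolerance (sup-norm %.2e)",
                    gnorm))
  }
  beta <- setNames(par[seq_len(k)], colnames(x))
  sigma <- exp(par[[k + 1L]])

  hess <- tryCatch(stats::optimHess(par, nll, ngr), error = function(e) NULL)
  vcov <- NULL; se <- NULL
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc)) {
      vcov <- vc[seq_len(k), seq_len(k), drop = FALSE]
      dimnames(vcov) <- list(colnames(x), colnames(x))
      se <- sqrt(pmax(diag(vcov), 0))
    }
  }
  new_mapping(
    method = "tobit", coefficients = beta, n = n, y = y,
    fitted = drop(x %*% beta), sigma = sigma, vcov = vcov, se = se,
    censor_point = censor_point, converged = converged,
    iterations = opt$counts[["function"]], n_censored = sum(cens)
  )
}

#' Fit the mapping by quantile (median) regression
#'
#' Minimizes the check loss at quantile `tau`; the default `tau = 0.5` is
#' median regression, minimizing the sum of absolute deviations.  Solved by
#' iteratively reweighted least squares on the smoothed check loss followed
#' by a basic-solution refinement (an optimal fit interpolates as many
#' observations as design columns).
#'
#' @inheritParams fit_ols
#' @param tau Quantile in (0, 1); 0.5 = median regression.
#' @return A `factb_mapping` object (with the attained `objective`).
#' @export
fit_quantile <- function(x, y, tau = 0.5) {
  check_design(x, y)
  fit <- lad_fit(x, y, tau = tau)
  new_mapping(
    method = "quantile", coefficients = fit$coefficients, n = length(y),
    y = y, fitted = drop(x %*% fit$coefficients), tau = tau,
    objective = fit$objective, converged = TRUE, iterations = fit$iterations
  )
}

#' Fit the mapping by censored least absolute deviations (CLAD)
#'
#' Powell's estimator: median regression acknowledging censoring at the
#' ceiling.  Estimated by iterative trimming: fit median regression, drop
#' observations whose fitted value reaches the censor point (ties included),
#' refit on the kept set, and iterate until the kept set stabilizes.  The
#' kept set only ever shrinks under this scheme, so the iteration always
#' terminates.  When trimming never activates, CLAD coincides exactly with
#' median regression.
#'
#' @inheritParams fit_tobit
#' @param tau Quantile (default 0.5, the standard CLAD).
#' @param max_iter Maximum trimming iterations.
#' @param start Optional starting coefficients for the inner median fits
#'   (used e.g. to warm-start bootstrap replicates).
#' @return A `factb_mapping` object (with `n_trimmed` and `trim_iterations`).
#' @export
fit_clad <- function(x, y, censor_point = 1, tau = 0.5, max_iter = 50L,
                     start = NULL) {
  check_design(x, y)
  n <- length(y)
  kept <- seq_len(n)
  beta <- start
  iter <- 0L
  total_lad_iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    if (length(kept) <= ncol(x)) {
      stop("CLAD degenerated: fewer usable observations (", length(kept),
           ") than design columns after trimming")
    }
    fit <- lad_fit(x[kept, , drop = FALSE], y[kept], tau = tau, start = beta)
    beta <- fit$coefficients
    total_lad_iter <- total_lad_iter + fit$iterations
    fitted_kept <- drop(x[kept, , drop = FALSE] %*% beta)
    drop_idx <- fitted_kept >= censor_point - 1e-12
    if (!any(drop_idx)) { converged <- TRUE; break }
    kept <- kept[!drop_idx]
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("CLAD trimming did not stabilize within ", max_iter,
            " iterations; returning the last fit (", length(kept), " rows kept)")
  }
  new_mapping(
    method = "clad", coefficients = beta, n = n, y = y,
    fitted = drop(x %*% beta), tau = tau, censor_point = censor_point,
    objective = check_loss(y[kept] - drop(x[kept, , drop = FALSE] %*% beta), tau),
    converged = converged, iterations = total_lad_iter,
    trim_iterations = iter, n_trimmed = n - length(kept), kept = kept
  )
}

#' Fit the mapping by logistic quantile regression
#'
#' For a bounded outcome, the logistic transform
#' `h(y) = log((y - y_min)/(y_max - y))` maps utilities onto the real line;
#' a quantile regression of `h(y)` on the covariates is then fitted.
#' Coefficients live on the transformed scale; predictions are
#' back-transformed automatically and therefore always lie strictly inside
#' `(y_min, y_max)` - the mechanism by which this method never predicts at
#' or above the ceiling.
#'
#' @inheritParams fit_quantile
#' @param bounds A [derive_bounds()] / [bounds_preset()] object; every
#'   observation must lie strictly inside `(y_min, y_max)`.
#' @return A `factb_mapping` object with transformed-scale coefficients and
#'   the bounds attached.
#' @export
fit_logistic_quantile <- function(x, y, bounds = bounds_preset("japanese"), tau = 0.5) {
  check_design(x, y)
  stopifnot(inherits(bounds, "transform_bounds"))
  h <- logit_transform(y, bounds)  # errors naming offending rows if out of bounds
  fit <- lad_fit(x, h, tau = tau)
  eta <- drop(x %*% fit$coefficients)
  new_mapping(
    method = "lqr", coefficients = fit$coefficients, n = length(y),
    y = y, fitted = inverse_logit_transform(eta, bounds),
    tau = tau, bounds = bounds, objective = fit$objective,
    converged = TRUE, iterations = fit$iterations
  )
}

check_design <- function(x, y) {
  if (!is.matrix(x)) stop("x must be a design matrix (use build_design())")
  if (nrow(x) != length(y)) stop("x and y dimensions disagree")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in the design")
  if (nrow(x) < ncol(x) + 1L) {
    stop("too few observations (", nrow(x), ") for ", ncol(x), " design columns")
  }
  invisible(TRUE)
}
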