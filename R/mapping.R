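#' Fit a FACT-B to EQ-5D-5L mapping
#'
#' Front end tying the cohort interface to the five fitters.  The EQ-5D-5L
#' utility index is regressed on FACT-B subscale scores under one of the
#' preset model specifications (see [model_spec()]); rows with undefined
#' required covariates are dropped with a message.
#'
#' Methods available on the result: `print`, `summary` (coefficient table
#' with standard errors), `coef`, `predict`, `fitted`, `residuals`, `plot`
#' (observed vs predicted) and `simulate` (OLS/Tobit only, which carry a
#' full distributional model).
#'
#' @param cohort Data frame with subscale columns (`PWB`..`BCS`), a
#'   `utility` column, and any extra covariates.
#' @param model Preset model id 1..5 (default 4, the recommended mapping).
#' @param method Regression method: `"ols"` (recommended), `"tobit"`,
#'   `"clad"`, `"quantile"` or `"lqr"` (logistic quantile).
#' @param covariates,extra Optional explicit covariate choice overriding
#'   `model`; see [model_spec()].
#' @param tau Quantile for the quantile-based methods (default 0.5).
#' @param censor_point Ceiling for Tobit/CLAD (default 1).
#' @param bounds Transform bounds for `"lqr"` (default the Japanese preset).
#' @return An object of class `factb_mapping`.
#' @examples
#' cohort <- generate_cohort(synth_config(n = 300, seed = 7))
#' m <- fit_mapping(cohort, model = 4, method = "ols")
#' coef(m)
#' predict(m, data.frame(PWB = 21.1, EWB = 18.0, FWB = 20.0, BCS = 21.7))
#' @export
fit_mapping <- function(cohort, model = 4, method = .METHODS,
                        covariates = NULL, extra = character(),
                        tau = 0.5, censor_point = 1, bounds = NULL) {
  method <- match.arg(method)
  spec <- if (is.null(covariates)) model_spec(model) else
    model_spec(covariates = covariates, extra = extra)
  des <- build_design(cohort, spec)
  if (des$dropped > 0) {
    message(des$dropped, " row(s) dropped: undefined covariate or utility")
  }
  m <- switch(method,
    ols      = fit_ols(des$x, des$y),
    tobit    = fit_tobit(des$x, des$y, censor_point = censor_point),
    quantile = fit_quantile(des$x, des$y, tau = tau),
    clad     = fit_clad(des$x, des$y, censor_point = censor_point, tau = tau),
    lqr      = fit_logistic_quantile(des$x, des$y,
                 bounds = if (is.null(bounds)) bounds_preset("japanese") else bounds,
                 tau = tau)
  )
  m$model <- spec$model
  m$spec <- spec
  m$dropped <- des$dropped
  m$call <- match.call()
  m
}

new_mapping <- function(method, coefficients, n, y = NULL, fitted = NULL,
                        sigma = NULL, bounds = NULL, tau = NULL,
                        censor_point = NULL, objective = NULL,
                        vcov = NULL, se = NULL, converged = NA,
                        iterations = NA_integer_, source = "fitted", ...) {
  covariates <- setdiff(names(coefficients), "(Intercept)")
  structure(
    c(list(
      method = method, coefficients = coefficients, covariates = covariates,
      n = as.integer(n), p = length(covariates),
      y = y, fitted.values = fitted,
      residuals = if (!is.null(y) && !is.null(fitted)) y - fitted,
      sigma = sigma, bounds = bounds, tau = tau,
      censor_point = censor_point, objective = objective,
      vcov = vcov, se = se, converged = converged,
      iterations = iterations, source = source,
      model = NA_integer_, dropped = 0L
    ), list(...)),
    class = "factb_mapping"
  )
}

#' @export
print.factb_mapping <- function(x, digits = 4, ...) {
  label <- c(ols = "ordinary least squares", tobit = "Tobit (upper-censored)",
             clad = "censored least absolute deviations",
             quantile = "quantile (median) regression",
             lqr = "logistic quantile regression")[[x$method]]
  cat("FACT-B -> EQ-5D-5L mapping:", label, "\n")
  if (!is.na(x$model)) cat("  model spec: Model", x$model, "\n")
  if (identical(x$source, "published")) {
    cat("  published coefficients (development sample, n = ", x$n, ")\n", sep = "")
  } else {
    cat("  fitted on n =", x$n, "subjects\n")
  }
  if (x$method == "lqr") {
    cat(sprintf("  coefficients on the logit scale, bounds (%g, %g)\n",
                x$bounds$y_min, x$bounds$y_max))
  }
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.factb_mapping <- function(object, ...) object$coefficients

#' @export
fitted.factb_mapping <- function(object, ...) object$fitted.values

#' @export
residuals.factb_mapping <- function(object, ...) object$residuals

#' Predict utilities from a fitted or published mapping
#'
#' OLS, Tobit, CLAD and quantile mappings predict with the linear index
#' (for Tobit the latent index, which may exceed 1); logistic quantile
#' mappings back-transform the linear index, so their predictions always lie
#' strictly inside the transform bounds.
#'
#' @param object A `factb_mapping`.
#' @param newdata Data frame with the mapping's covariate columns, or a
#'   named numeric vector (a single profile).  Omitted: training fits are
#'   returned.
#' @param ... Unused.
#' @return Numeric vector of predicted utilities.
#' @export
predict.factb_mapping <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted.values)) stop("no training data stored; supply newdata")
    return(object$fitted.values)
  }
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  missing_cols <- setdiff(object$covariates, names(newdata))
  if (length(missing_cols)) {
    stop("undefined prediction: newdata lacks covariate(s) ",
         paste(missing_cols, collapse = ", "))
  }
  block <- newdata[, object$covariates, drop = FALSE]
  if (anyNA(block)) stop("undefined prediction: missing covariate values")
  eta <- drop(as.matrix(block) %*% object$coefficients[object$covariates]) +
    object$coefficients[["(Intercept)"]]
  if (object$method == "lqr") inverse_logit_transform(eta, object$bounds) else eta
}

#' @export
summary.factb_mapping <- function(object, se = c("default", "none", "bootstrap"),
                                  B = 200L, seed = 1L, x = NULL, ...) {
  se <- match.arg(se)
  ses <- object$se
  if (se == "none") ses <- NULL
  if (se == "bootstrap" || (se == "default" && is.null(ses))) {
    ses <- bootstrap_mapping_se(object, B = B, seed = seed, x = x)
  }
  tab <- cbind(Estimate = object$coefficients)
  if (!is.null(ses)) {
    z <- object$coefficients / ses
    tab <- cbind(Estimate = object$coefficients, `Std. Error` = ses,
                 `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  }
  out <- list(method = object$method, model = object$model, n = object$n,
              p = object$p, coefficients = tab, sigma = object$sigma,
              converged = object$converged, source = object$source)
  class(out) <- "summary.factb_mapping"
  out
}

#' @export
print.summary.factb_mapping <- function(x, digits = 4, ...) {
  cat("FACT-B -> EQ-5D-5L mapping (", x$method, "), n = ", x$n,
      ", p = ", x$p, "\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, has.Pvalue = ncol(x$coefficients) > 1)
  if (!is.null(x$sigma)) cat("residual sigma:", format(x$sigma, digits = digits), "\n")
  invisible(x)
}

# Bootstrap SEs for quantile-family mappings; needs the training design,
# which is reconstructed from stored y/fitted only if x is supplied.
bootstrap_mapping_se <- function(object, B = 200L, seed = 1L, x = NULL) {
  if (is.null(x)) {
    stop("bootstrap standard errors need the training design matrix; ",
         "pass it as summary(..., x = design$x)")
  }
  y <- object$y
  fit_fun <- switch(object$method,
    quantile = function(xx, yy) lad_fit(xx, yy, tau = object$tau)$coefficients,
    clad     = function(xx, yy) fit_clad(xx, yy, censor_point = object$censor_point,
                                         tau = object$tau)$coefficients,
    lqr      = function(xx, yy) lad_fit(xx, logit_transform(yy, object$bounds),
                                        tau = object$tau)$coefficients,
    ols      = function(xx, yy) lm.fit(xx, yy)$coefficients,
    tobit    = function(xx, yy) fit_tobit(xx, yy,
                                          censor_point = object$censor_point)$coefficients
  )
  setNames(bootstrap_se(x, y, fit_fun, B = B, seed = seed), names(object$coefficients))
}

#' @export
plot.factb_mapping <- function(x, ...) {
  if (is.null(x$y)) stop("no training data stored on this mapping")
  plot(x$y, x$fitted.values, xlab = "observed utility",
       ylab = "predicted utility",
       main = paste("FACT-B mapping:", x$method), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.factb_mapping <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!object$method %in% c("ols", "tobit")) {
    stop("simulate() requires a full distributional model; only OLS and ",
         "Tobit mappings carry one")
  }
  if (is.null(object$sigma) || is.na(object$sigma)) {
    stop("no residual scale stored on this mapping (published Tobit entries ",
         "do not print sigma)")
  }
  if (!is.null(seed)) set.seed(seed)
  eta <- if (is.null(newdata)) {
    if (object$method == "tobit") {
      # latent index, not the stored censored fits
      object$fitted.values
    } else object$fitted.values
  } else predict(object, newdata)
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    draw <- eta + rnorm(length(eta), sd = object$sigma)
    if (object$method == "tobit") draw <- pmin(draw, object$censor_point %||% 1)
    draw
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
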