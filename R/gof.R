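#' Goodness-of-fit for utility predictions
#'
#' The r-squared used to compare regression methods is the squared Pearson
#' correlation between observed and predicted utilities (which equals the
#' usual R-squared for OLS but stays comparable across methods).  It is
#' penalized for model complexity as
#' `adjusted r2 = 1 - (n - 1) / (n - p - 1) * (1 - r2)`,
#' with `p` the number of covariates excluding the intercept.  MSE and MAD
#' are the mean squared and mean absolute observed-minus-predicted
#' deviations; MSE structurally favors least-squares fits and MAD
#' least-absolute-deviation fits, so neither is read in isolation.
#'
#' @param observed,predicted Paired utility vectors.
#' @param p Number of covariates in the model (excluding the intercept).
#' @return An object of class `gof_report`: list with `r2`, `adjusted_r2`,
#'   `mse`, `mad`, `n`, `p`.
#' @examples
#' gof(c(0.7, 0.8, 0.9, 1.0), c(0.72, 0.79, 0.88, 0.97), p = 1)
#' @export
gof <- function(observed, predicted, p) {
  if (length(observed) != length(predicted)) stop("paired vectors required")
  n <- length(observed)
  if (n <= p + 1) stop("need n > p + 1")
  if (sd(observed) == 0 || sd(predicted) == 0) {
    stop("undefined correlation: constant observed or predicted vector")
  }
  r2 <- cor(observed, predicted)^2
  structure(list(
    r2 = r2,
    adjusted_r2 = adjusted_r2(r2, n, p),
    mse = mean((observed - predicted)^2),
    mad = mean(abs(observed - predicted)),
    n = n, p = as.integer(p)
  ), class = "gof_report")
}

#' @export
print.gof_report <- function(x, digits = 4, ...) {
  cat(sprintf("goodness of fit (n = %d, p = %d):\n", x$n, x$p))
  cat(sprintf("  r2 %.*f  adjusted r2 %.*f  MSE %.*f  MAD %.*f\n",
              digits, x$r2, digits, x$adjusted_r2, digits, x$mse, digits, x$mad))
  invisible(x)
}

#' @rdname gof
#' @param r2 Squared correlation between observed and predicted values.
#' @param n Sample size.
#' @export
adjusted_r2 <- function(r2, n, p) {
  1 - (n - 1) / (n - p - 1) * (1 - r2)
}

#' Distribution summary of a utility vector
#'
#' Mean, SD, minimum, 10th percentile, quartiles, 90th percentile, maximum,
#' and the fractions sitting exactly (within 1e-12) at the floor and
#' ceiling of the utility scale.
#'
#' @param values Utility vector (non-empty).
#' @param u_min Floor of the scale (default -0.111, the Japanese crosswalk
#'   range); the ceiling is 1.
#' @return One-row data frame with columns `mean, sd, min, p10, q1, median,
#'   q3, p90, max, floor_frac, ceiling_frac`.
#' @export
describe_utilities <- function(values, u_min = -0.111) {
  if (!length(values)) stop("empty vector")
  q <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  data.frame(
    mean = mean(values), sd = sd(values), min = min(values),
    p10 = q[1], q1 = q[2], median = q[3], q3 = q[4], p90 = q[5],
    max = max(values),
    floor_frac = mean(abs(values - u_min) < 1e-12),
    ceiling_frac = mean(abs(values - 1) < 1e-12)
  )
}
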