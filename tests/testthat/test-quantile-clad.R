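test_that("LAD objective equals the brute-force subset oracle on tiny data", {
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(5:8, 1)
    p <- sample(1:2, 1)
    x <- cbind(1, matrix(rnorm(n * p), n, p))
    colnames(x) <- c("(Intercept)", paste0("v", seq_len(p)))
    y <- drop(x %*% runif(p + 1, -1, 1)) + rnorm(n, 0, 0.5)
    m <- fit_quantile(x, y)
    expect_equal(m$objective, lad_oracle(x, y), tolerance = 1e-8)
  }
})

test_that("median regression on symmetric noiseless data equals OLS", {
  x <- cbind(`(Intercept)` = 1, v = seq(-3, 3, length.out = 21))
  y <- 0.5 + 0.2 * x[, 2]
  q <- fit_quantile(x, y)
  o <- fit_ols(x, y)
  expect_equal(coef(q), coef(o), tolerance = 1e-8)
  expect_equal(q$objective, 0, tolerance = 1e-10)
})

test_that("the LAD optimum beats the OLS solution on absolute loss", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 40
    x <- cbind(1, rnorm(n), rnorm(n))
    colnames(x) <- c("(Intercept)", "a", "b")
    y <- drop(x %*% c(1, 0.5, -0.2)) + rt(n, df = 2)
    q <- fit_quantile(x, y)
    o <- fit_ols(x, y)
    expect_lte(q$objective, sum(abs(residuals(o))) / 2 + 1e-10)
  }
})

test_that("quantile solutions scale linearly under positive rescaling of y", {
  set.seed(9)
  n <- 80
  x <- cbind(`(Intercept)` = 1, a = rnorm(n), b = runif(n))
  y <- drop(x %*% c(2, 1, -1)) + rnorm(n)
  m1 <- fit_quantile(x, y)
  m2 <- fit_quantile(x, 3.5 * y)
  expect_equal(coef(m2), 3.5 * coef(m1), tolerance = 1e-6)
})

test_that("the solver agrees with the quantreg oracle away from tau = 0.5", {
  set.seed(19)
  n <- 150
  x <- cbind(`(Intercept)` = 1, a = rnorm(n))
  y <- drop(x %*% c(1, 2)) + rnorm(n)
  for (tau in c(0.25, 0.5, 0.75)) {
    m <- fit_quantile(x, y, tau = tau)
    rf <- quantreg::rq(y ~ x[, 2], tau = tau)
    r <- y - fitted(rf)
    expect_equal(m$objective, sum(r * (tau - (r < 0))), tolerance = 1e-8)
  }
  expect_error(fit_quantile(x, y, tau = 0), "tau")
  expect_error(fit_quantile(x, y, tau = 1.2), "tau")
})

test_that("CLAD equals median regression when trimming never activates", {
  co <- toy_cohort(n = 150, seed = 8)  # utilities well below 1
  d <- build_design(co, model_spec(4))
  clad <- fit_clad(d$x, d$y)
  lad <- fit_quantile(d$x, d$y)
  expect_identical(coef(clad), coef(lad))
  expect_identical(clad$n_trimmed, 0L)
  expect_identical(clad$trim_iterations, 1L)
})

test_that("CLAD trims ceiling-bound fits and recovers the latent slopes", {
  truth <- c(0.4160, 0.0121, 0.0041, 0.0044, 0.0034)
  cfg <- synth_config(n = 2000, seed = 77,
                      true_mapping = local({
                        m <- published_mapping("ols", 4)
                        m$coefficients[1] <- truth[1]
                        m
                      }),
                      target_ceiling_fraction = NULL)
  co <- generate_cohort(cfg)
  d <- build_design(co, model_spec(4))
  clad <- fit_clad(d$x, d$y)
  expect_gt(clad$n_trimmed, 0L)
  expect_true(clad$converged)
  se <- factbmap:::bootstrap_se(
    d$x, d$y, function(xx, yy) fit_clad(xx, yy)$coefficients,
    B = 100L, seed = 7L
  )
  z <- abs(coef(clad) - truth) / se
  expect_true(all(z < 3))
})

test_that("CLAD degenerates cleanly when everything is trimmed", {
  x <- cbind(`(Intercept)` = 1, v = 1:20)
  y <- pmin(2 + 0.1 * (1:20), 1)  # latent far above the ceiling everywhere
  expect_error(fit_clad(x, y, censor_point = 1), "degenerated")
})

test_that("the CLAD kept set shrinks monotonically across iterations", {
  cfg <- synth_config(n = 400, seed = 13)
  co <- generate_cohort(cfg)
  d <- build_design(co, model_spec(4))
  clad <- fit_clad(d$x, d$y)
  expect_lte(length(clad$kept), length(d$y))
  expect_identical(clad$n_trimmed, length(d$y) - length(clad$kept))
  # all surviving fitted values sit below the censor point
  kept_fit <- drop(d$x[clad$kept, ] %*% coef(clad))
  expect_true(all(kept_fit < 1 - 1e-12))
})
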