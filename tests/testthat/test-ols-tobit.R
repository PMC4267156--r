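test_that("OLS interpolates exact linear data and flags collinearity", {
  x <- cbind(`(Intercept)` = 1, x = c(1, 2, 3, 4, 5))
  y <- 0.3 + 0.01 * x[, 2]
  m <- fit_ols(x, y)
  expect_equal(unname(coef(m)), c(0.3, 0.01), tolerance = 1e-10)
  expect_error(fit_ols(cbind(x, dup = x[, 2]), y), "collinear")
})

test_that("OLS preserves the training mean and recovers known coefficients", {
  truth <- c(`(Intercept)` = 0.10, PWB = 0.0121, EWB = 0.0041,
             FWB = 0.0044, BCS = 0.0034)
  cfg <- synth_config(n = 1000, seed = 31, noise_sd = 0.08,
                      true_mapping = local({
                        m <- published_mapping("ols", 4)
                        m$coefficients[] <- truth
                        m
                      }),
                      ceiling_rule = "clip", target_ceiling_fraction = NULL)
  co <- generate_cohort(cfg)
  expect_lt(mean(co$utility == 1), 0.01)  # intercept 0.10 keeps data off the ceiling
  d <- build_design(co, model_spec(4))
  m <- fit_ols(d$x, d$y)
  expect_equal(mean(fitted(m)), mean(d$y), tolerance = 1e-10)
  expect_equal(sum(residuals(m)), 0, tolerance = 1e-8)
  z <- abs(coef(m) - truth) / m$se
  expect_true(all(z < 3))
})

test_that("Tobit equals OLS when nothing is censored", {
  co <- toy_cohort(n = 200, seed = 5)
  d <- build_design(co, model_spec(4))
  ols <- fit_ols(d$x, d$y)
  # censor point far above the bounded data: the MLE is the normal MLE
  tob <- fit_tobit(d$x, d$y, censor_point = 10)
  expect_equal(coef(tob), coef(ols), tolerance = 1e-4)
  expect_gt(tob$sigma, 0)
  expect_true(tob$converged)
})

test_that("Tobit matches the survreg oracle on censored data", {
  cfg <- synth_config(n = 1500, seed = 41,
                      true_mapping = local({
                        m <- published_mapping("ols", 4)
                        m$coefficients[1] <- 0.4160
                        m
                      }),
                      target_ceiling_fraction = NULL)
  co <- generate_cohort(cfg)
  expect_gt(mean(co$utility == 1), 0.10)
  d <- build_design(co, model_spec(4))
  tob <- fit_tobit(d$x, d$y)
  sv <- survival::survreg(
    survival::Surv(utility, utility < 1, type = "right") ~ PWB + EWB + FWB + BCS,
    data = co, dist = "gaussian"
  )
  expect_equal(unname(coef(tob)), unname(coef(sv)), tolerance = 1e-5)
  expect_equal(tob$sigma, sv$scale, tolerance = 1e-5)
})

test_that("under ceiling censoring Tobit is less biased than OLS and on target", {
  truth <- c(0.4160, 0.0121, 0.0041, 0.0044, 0.0034)
  cfg <- synth_config(n = 2000, seed = 57,
                      true_mapping = local({
                        m <- published_mapping("ols", 4)
                        m$coefficients[1] <- truth[1]
                        m
                      }),
                      target_ceiling_fraction = NULL)
  co <- generate_cohort(cfg)
  ceiling_mass <- mean(co$utility == 1)
  expect_gt(ceiling_mass, 0.15)
  d <- build_design(co, model_spec(4))
  ols <- fit_ols(d$x, d$y)
  tob <- fit_tobit(d$x, d$y)
  slope_bias <- function(m) mean(abs(coef(m)[-1] - truth[-1]))
  expect_lt(slope_bias(tob), slope_bias(ols))
  z <- abs(coef(tob) - truth) / tob$se
  expect_true(all(z < 3))
  expect_gt(tob$sigma, 0)
})

test_that("Tobit rejects degenerate inputs", {
  x <- cbind(`(Intercept)` = 1, x = 1:10)
  expect_error(fit_tobit(x, rep(1, 10)), "all observations censored")
  expect_error(fit_tobit(x, rep(1.2, 10)), "above the censor point")
})
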