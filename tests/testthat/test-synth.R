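test_that("the generator is deterministic given the config", {
  cfg <- synth_config(n = 200, seed = 55)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- synth_config(n = 200, seed = 56)
  expect_false(identical(generate_cohort(cfg)$utility,
                         generate_cohort(cfg2)$utility))
})

test_that("default cohorts match the published ceiling mass and mean utility", {
  co <- generate_cohort(synth_config(n = 1e4, seed = 61))
  expect_lt(abs(mean(co$utility == 1) - 0.248), 0.02)
  expect_lt(abs(mean(co$utility) - 0.777), 0.02)
  # status mix calibrated to the published frequencies
  mix <- prop.table(table(pmin(co$status, 3)))
  expect_equal(as.numeric(mix), c(0.408, 0.483, 0.071, 0.038), tolerance = 0.02)
})

test_that("generated data respect instrument ranges and the utility ceiling", {
  co <- generate_cohort(synth_config(n = 3000, seed = 63))
  for (s in c("PWB", "SWB", "EWB", "FWB")) {
    expect_true(all(co[[s]] == round(co[[s]])))
  }
  expect_true(all(co$PWB >= 0 & co$PWB <= 28))
  expect_true(all(co$EWB >= 0 & co$EWB <= 24))
  expect_true(all(co$BCS >= 0 & co$BCS <= 40))
  expect_true(all(co$utility <= 1))
  expect_true(all(co$status %in% 0:4))
})

test_that("group mean utility decreases strictly with status at large n", {
  co <- generate_cohort(synth_config(n = 2000, seed = 65))
  means <- tapply(co$utility, pmin(co$status, 3), mean)
  expect_true(all(diff(means) < 0))
})

test_that("OLS recovers the generator's coefficients on ceiling-free data", {
  truth <- c(`(Intercept)` = 0.10, PWB = 0.0121, EWB = 0.0041,
             FWB = 0.0044, BCS = 0.0034)
  make_cfg <- function(seed) {
    synth_config(n = 2000, seed = seed,
                 true_mapping = local({
                   m <- published_mapping("ols", 4)
                   m$coefficients[] <- truth
                   m
                 }),
                 ceiling_rule = "clip", target_ceiling_fraction = NULL)
  }
  co <- generate_cohort(make_cfg(71))
  d <- build_design(co, model_spec(4))
  m <- fit_ols(d$x, d$y)
  expect_true(all(abs(coef(m) - truth) / m$se < 3))

  # recovery sweep: across 20 seeds the mean estimate is unbiased
  # (|mean bias| below 3 standard errors of the 20-seed mean)
  ests <- t(vapply(1:20, function(s) {
    d <- build_design(generate_cohort(make_cfg(100 + s)), model_spec(4))
    coef(fit_ols(d$x, d$y))
  }, numeric(5)))
  bias <- colMeans(ests) - truth
  tol <- 3 * apply(ests, 2, sd) / sqrt(20)
  expect_true(all(abs(bias) < tol))
})

test_that("follow-up waves behave like the validation survey", {
  cfg <- synth_config(n = 238, seed = 81)
  base <- generate_cohort(cfg)

  # no attrition, no drift: identical wave
  fu0 <- generate_followup(base, cfg, attrition = 0, drift_sd = 0)
  expect_equal(fu0$utility, base$utility)
  expect_equal(fu0$PWB, base$PWB)
  expect_identical(fu0$status, base$status)

  # default attrition: about 221 of 238 retained (binomial, sd ~3.9)
  sizes <- vapply(1:20, function(s) {
    nrow(generate_followup(base, cfg, seed = 1000 + s))
  }, numeric(1))
  expect_lt(abs(mean(sizes) - 221.3), 4)
  fu <- generate_followup(base, cfg)
  expect_true(all(fu$id %in% base$id))
  expect_true(all(fu$utility <= 1))
  expect_true(all(fu$PWB >= 0 & fu$PWB <= 28))
})

test_that("config validation catches bad inputs", {
  expect_error(synth_config(subscale_correlation = 1), "subscale_correlation")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_warning(synth_config(ceiling_rule = "clip"),
                 "target_ceiling_fraction is ignored")
  expect_error(synth_config(target_ceiling_fraction = 1.2),
               "target_ceiling_fraction")
})

test_that("cohort CSV round trip preserves the fitting schema", {
  co <- generate_cohort(synth_config(n = 50, seed = 91))
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_identical(names(back), c("id", "PWB", "SWB", "EWB", "FWB", "BCS",
                                  "utility", "status"))
  expect_equal(back$utility, co$utility, tolerance = 1e-12)
  expect_identical(back$status, co$status)
})
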