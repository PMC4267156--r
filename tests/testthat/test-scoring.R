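test_that("item recoding reverses negatively worded items and is an involution", {
  expect_equal(recode_item(3, FALSE), 3)
  expect_equal(recode_item(2, TRUE), 2)  # midpoint fixed under reversal
  expect_equal(recode_item(0, TRUE), 4)
  for (x in 0:4) {
    expect_equal(recode_item(recode_item(x, TRUE), TRUE), x)
  }
  expect_error(recode_item(5, FALSE), "invalid item response")
  expect_error(recode_item(-1, TRUE), "invalid item response")
})

test_that("half-rule scoring prorates and fails at exactly half answered", {
  expect_equal(score_subscale(rep(4, 7)), 28)
  # 4 of 7 answered, each 2: sum 8, imputed total 8 + 3*2; ratio form 8*7/4
  expect_equal(score_subscale(c(2, 2, 2, 2, NA, NA, NA)), 14)
  expect_equal(score_subscale(c(2, 2, 2, 2, NA, NA, NA)), 8 * 7 / 4)
  # strictly more than half: 3 of 7 and 3 of 6 fail, 4 of 7 and 4 of 6 pass
  expect_true(is.na(score_subscale(c(1, 2, 3, NA, NA, NA, NA))))
  expect_true(is.na(score_subscale(c(1, 2, 3, NA, NA, NA))))
  expect_false(is.na(score_subscale(c(1, 2, 3, 4, NA, NA))))
  # BCS needs at least 6 of 10
  expect_true(is.na(score_subscale(c(rep(2, 5), rep(NA, 5)))))
  expect_false(is.na(score_subscale(c(rep(2, 6), rep(NA, 4)))))
  expect_error(score_subscale(rep(1, 6), n_items = 7), "expected 7 items")
})

test_that("ratio form and impute-the-mean form agree at full precision", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(c(6, 7, 10), 1)
    vals <- sample(0:4, n, replace = TRUE)
    n_miss <- sample(0:(floor(n / 2) - 1), 1)
    vals[sample(n, n_miss)] <- NA
    answered <- vals[!is.na(vals)]
    imputed <- sum(answered) + (n - length(answered)) * mean(answered)
    expect_equal(score_subscale(vals, n), imputed, tolerance = 1e-12)
    expect_gte(score_subscale(vals, n), 0)
    expect_lte(score_subscale(vals, n), 4 * n)
  }
})

test_that("composites sum the printed baseline subscale means", {
  means <- c(PWB = 21.1, SWB = 22.2, EWB = 18.0, FWB = 20.0, BCS = 21.7)
  comp <- compute_composites(means)
  expect_equal(comp$FACTG, 81.3)
  expect_equal(comp$TOI, 62.8)
  expect_equal(comp$FACTB, 103.0)
  zero <- compute_composites(c(PWB = 0, SWB = 0, EWB = 0, FWB = 0, BCS = 0))
  expect_equal(unlist(zero), c(FACTG = 0, TOI = 0, FACTB = 0))
})

test_that("composites are undefined when a component is undefined", {
  comp <- compute_composites(c(PWB = 20, SWB = NA, EWB = 18, FWB = 20, BCS = 21))
  expect_true(is.na(comp$FACTG))
  expect_true(is.na(comp$FACTB))
  expect_equal(comp$TOI, 61)  # TOI does not use SWB
})

test_that("composite of cohort means equals mean of composites (linearity)", {
  co <- generate_cohort(synth_config(n = 500, seed = 21))
  per_subject <- compute_composites(co[c("PWB", "SWB", "EWB", "FWB", "BCS")])
  of_means <- compute_composites(colMeans(co[c("PWB", "SWB", "EWB", "FWB", "BCS")]))
  expect_equal(colMeans(per_subject), unlist(of_means), tolerance = 1e-9)
})

test_that("item-level scoring applies recoding and the half-rule per subscale", {
  man <- fact_b_manifest()
  man$negatively_worded[man$item_id %in% c("PWB1", "PWB2", "BCS1")] <- TRUE
  resp <- as.data.frame(as.list(setNames(rep(4L, 37L), man$item_id)))
  resp$subject <- "a"
  scored <- score_factb(resp, man)
  # all raw 4s, but PWB1/PWB2 reverse to 0: PWB = 5*4; BCS1 reverses: BCS = 9*4
  expect_equal(scored$PWB, 20)
  expect_equal(scored$BCS, 36)
  expect_equal(scored$SWB, 28)
  expect_equal(scored$FACTB, 20 + 28 + 24 + 28 + 36)
  expect_identical(scored$subject, "a")

  resp2 <- resp
  resp2[paste0("EWB", 1:3)] <- NA  # exactly half of EWB missing
  scored2 <- score_factb(resp2, man)
  expect_true(is.na(scored2$EWB))
  expect_true(is.na(scored2$FACTG))
  expect_false(is.na(scored2$TOI))
})

test_that("manifest validation enforces the 37-item subscale layout", {
  man <- fact_b_manifest()
  expect_identical(nrow(man), 37L)
  expect_identical(as.integer(table(man$subscale)), c(7L, 7L, 6L, 7L, 10L))
  bad <- man[-1, ]
  expect_error(score_factb(data.frame(), bad), "7/7/6/7/10")
  dup <- man
  dup$item_id[2] <- dup$item_id[1]
  expect_error(factbmap:::validate_manifest(dup), "unique")
})
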