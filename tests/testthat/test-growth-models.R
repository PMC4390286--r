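test_that("breast-height age converts to growth time by the half-year rule", {
  expect_equal(bh_age_to_t(50), 49.5)
  expect_equal(bh_age_to_t(0.5), 0)
  expect_equal(bh_age_to_t(5), 4.5)
  expect_equal(bh_age_to_t(c(5, 10, 50)), c(4.5, 9.5, 49.5))
  expect_error(bh_age_to_t(0.4), "0.5")
  expect_error(bh_age_to_t("a"), "numeric")
})

test_that("base curves reproduce independently transcribed values", {
  cr <- base_params("CR", a0 = 37.819, a1 = -0.01183, a2 = 1.5097)
  expect_equal(predict_height(cr, 49.5), 12.371621, tolerance = 1e-6)
  sch <- base_params("SCH", c0 = 4.7801, c1 = -13.6931, c2 = -0.4476)
  expect_equal(predict_height(sch, 49.5), 12.238711, tolerance = 1e-6)
  hiv <- base_params("HIV", b0 = 182.3, b1 = 3.5483, b2 = 120360)
  expect_equal(predict_height(hiv, 49.5), 12.298485, tolerance = 1e-6)

  # grids against the transcription oracles
  tg <- c(0.5, 4.5, 20, 49.5, 99.5, 199.5)
  expect_equal(predict_height(cr, tg), oracle_cr(37.819, -0.01183, 1.5097, tg))
  expect_equal(predict_height(hiv, tg), oracle_hiv(182.3, 3.5483, 120360, tg))
  expect_equal(predict_height(sch, tg), oracle_sch(4.7801, -13.6931, -0.4476, tg))
})

test_that("curve boundary behaviour and domain handling are correct", {
  cr <- base_params("CR", a0 = 37.819, a1 = -0.01183, a2 = 1.5097)
  expect_identical(predict_height(cr, 0), 1.3)
  sch <- base_params("SCH", c0 = 4.78, c1 = -13.7, c2 = -0.45)
  expect_equal(predict_height(sch, 0), 1.3)
  expect_error(predict_height(cr, -1), "non-negative")
  # HIV with a negative denominator at small t must name the offending t
  hiv_bad <- base_params("HIV", b0 = 182.3, b1 = 3.5483, b2 = -100)
  expect_error(predict_height(hiv_bad, 2), "denominator")
  expect_warning(base_params("SCH", c0 = 4.78, c1 = -13.7, c2 = 0.2), "c2")
})

test_that("CR curves are strictly increasing for admissible parameters", {
  set.seed(42)
  for (i in 1:10) {
    p <- base_params("CR", a0 = runif(1, 10, 60), a1 = -runif(1, 0.005, 0.03),
                     a2 = runif(1, 0.8, 2.5))
    h <- predict_height(p, seq(0.5, 250, length.out = 400))
    expect_true(all(diff(h) > 0))
  }
})

test_that("site index is the height at breast-height age 50", {
  cr <- base_params("CR", a0 = 37.819, a1 = -0.01183, a2 = 1.5097)
  expect_identical(site_index(cr), predict_height(cr, 49.5))
  expect_identical(site_index(cr), predict_height(cr, bh_age_to_t(50)))
})

test_that("admissibility scan flags the documented failure modes", {
  # negative asymptote-like HIV parameter
  bad <- base_params("HIV", b0 = -1, b1 = 3.5, b2 = 120360)
  chk <- admissible_prediction_check(bad)
  expect_false(chk$pass)
  expect_true(any(grepl("asymptote-like", chk$reasons)))
  # published-scale CR parameters pass over the whole age range
  ok <- admissible_prediction_check(
    base_params("CR", a0 = 37.819, a1 = -0.01183, a2 = 1.5097), c(0.5, 250))
  expect_true(ok$pass)
  # strongly negative b2 fails at small t
  bad2 <- admissible_prediction_check(
    base_params("HIV", b0 = 182.3, b1 = 3.5483, b2 = -1e4), c(0.5, 250))
  expect_false(bad2$pass)
})
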