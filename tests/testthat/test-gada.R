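test_that("growth-intensity solutions match hand-derived values", {
  chi <- solve_chi0(tbl_gada$CR, t0 = 49.5, y0 = 20)
  expect_equal(chi, 4.028503, tolerance = 1e-6)
  expect_equal(exp(chi), 56.1767, tolerance = 1e-4)                 # implied a0
  expect_equal(-1.7580 + 11.6209 / chi, 1.126670, tolerance = 1e-5) # implied a2
  expect_equal(solve_chi0(tbl_gada$SCH, 49.5, 20), 5.168783, tolerance = 1e-6)
})

test_that("chi0 domain errors are raised", {
  expect_error(solve_chi0(tbl_gada$CR, 49.5, 1.3), "1.3")
  expect_error(solve_chi0(tbl_gada$HIV, 49.5, 1.2), "1.3")
  # negative discriminant: strongly negative a21 with a low anchor height
  g_neg <- gada_globals("CR", a1 = -0.01, a20 = 0, a21 = -50)
  expect_error(solve_chi0(g_neg, 49.5, 2), "no real root")
  # degenerate chi0 = 0 for CR (a21 = 0 and anchor below the a20 curve)
  g_deg <- gada_globals("CR", a1 = -0.01, a20 = 1, a21 = 0)
  expect_error(solve_chi0(g_deg, 49.5, 1.5), "degenerate")
})

test_that("anchoring identity holds for all families and anchors", {
  set.seed(7)
  for (fam in c("CR", "HIV", "SCH")) {
    g <- tbl_gada[[fam]]
    for (i in 1:20) {
      t0 <- runif(1, 20, 120)
      y0 <- runif(1, 5, 30)
      expect_lt(abs(gada_predict(g, t0, t0, y0) - y0), 1e-10)
    }
  }
})

test_that("GADA curves are base-age invariant", {
  tg <- seq(0.5, 250, length.out = 200)
  for (fam in c("CR", "HIV", "SCH")) {
    g <- tbl_gada[[fam]]
    h1 <- gada_predict(g, tg, t0 = 49.5, y0 = 20)
    # re-anchor the same curve at breast-height age 100
    y1 <- gada_predict(g, 99.5, t0 = 49.5, y0 = 20)
    h2 <- gada_predict(g, tg, t0 = 99.5, y0 = y1)
    expect_lt(max(abs(h1 - h2)), 1e-8)
  }
  g <- tbl_gada$CR
  expect_equal(gada_predict(g, 99.5, 49.5, 20), 33.687, tolerance = 1e-4)
  expect_equal(gada_predict(g, 49.5, 49.5, 20), 20)
})

test_that("the negative quadratic branch is exposed for root screening", {
  g <- tbl_gada$CR
  cp <- solve_chi0(g, 49.5, 20, root = "positive")
  cn <- solve_chi0(g, 49.5, 20, root = "negative")
  expect_true(cn < cp)
  # both branches anchor the curve through the initial condition
  expect_lt(abs(gada_predict(g, 49.5, 49.5, 20, root = "negative") - 20), 1e-10)
})

test_that("GADA and gada-equivalent g-GADA curves coincide pointwise", {
  tg <- seq(4.5, 250, length.out = 100)
  for (fam in c("CR", "HIV", "SCH")) {
    g <- tbl_gada[[fam]]
    chi <- solve_chi0(g, 49.5, 18)
    local <- switch(fam, CR = exp(chi), HIV = g$b00 + chi, SCH = chi)
    p <- ggada_local_to_params(local, g)
    expect_lt(max(abs(gada_predict(g, tg, 49.5, 18) - predict_height(p, tg))), 1e-8)
  }
})

test_that("g-GADA relations reproduce hand-evaluated parameter values", {
  p <- ggada_local_to_params(30, tbl_opt$CR)
  expect_equal(p$a2, 1.576256, tolerance = 1e-5)
  p <- ggada_local_to_params(-0.4494, tbl_opt$SCH)
  expect_equal(p$c0, 4.863475, tolerance = 1e-5)
  p <- ggada_local_to_params(210, tbl_opt$HIV)
  expect_equal(p$b1, 3.2877 * exp(0.0003071 * 210), tolerance = 1e-10)
  expect_equal(p$b2, 306100 - 604.5 * 210, tolerance = 1e-10)
  # relation collapses when the chi-coupling coefficient vanishes
  g0 <- gada_globals("CR", a1 = -0.01, a20 = 1.4, a21 = 0)
  expect_equal(ggada_local_to_params(30, g0)$a2, 1.4)
})

test_that("g-GADA relation domain violations error clearly", {
  expect_error(ggada_local_to_params(1, tbl_gada$CR), "log\\(a0\\)")
  expect_error(ggada_local_to_params(-5, tbl_opt$CR), "a0 > 0")
  expect_error(ggada_local_to_params(tbl_gada$HIV$b00, tbl_gada$HIV), "b00")
  expect_error(ggada_local_to_params(0.2, tbl_opt$SCH), "c2 < 0")
})
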