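test_that("GADA calibration anchors the curve exactly through one point", {
  for (fam in c("CR", "HIV", "SCH")) {
    g <- tbl_gada[[fam]]
    nm <- setdiff(names(g), c("family", "c00_dropped"))
    m <- si_model(fam, "gada", unlist(g[nm]))
    cal <- calibrate(tibble::tibble(bh_age = 50, height = 16), m)
    expect_equal(predict_height(cal$params, 49.5), 16, tolerance = 1e-10)
    expect_identical(cal$method, "closed_form")
  }
})

test_that("calibration round-trips a noise-free trajectory for every parameterization", {
  ages <- c(50, 90, 140)
  # optimal g-GADA: one driving local
  for (fam in c("CR", "HIV", "SCH")) {
    g <- tbl_opt[[fam]]
    truth <- switch(fam, CR = 30, HIV = 210, SCH = -0.4494)
    p <- ggada_local_to_params(truth, g)
    m <- si_model(fam, "ggada", unlist(g[setdiff(names(g), c("family", "relation"))]),
                  relation = "optimal")
    for (k in c(1, 3)) {
      obs <- tibble::tibble(bh_age = ages[seq_len(k)],
                            height = predict_height(p, bh_age_to_t(ages[seq_len(k)])))
      cal <- calibrate(obs, m)
      expect_lt(abs(cal$local / truth - 1), 1e-6)
    }
  }
  # gada-equivalent g-GADA
  g <- tbl_gada$CR
  chi <- solve_chi0(g, 49.5, 20)
  p <- ggada_local_to_params(exp(chi), g)
  m <- si_model("CR", "ggada", unlist(g[c("a1", "a20", "a21")]),
                relation = "gada_equivalent")
  obs <- tibble::tibble(bh_age = c(30, 80), height = predict_height(p, bh_age_to_t(c(30, 80))))
  cal <- calibrate(obs, m)
  expect_lt(abs(cal$local / exp(chi) - 1), 1e-6)
  # indicator: needs one observation per local parameter
  pi <- base_params("CR", a0 = 40, a1 = -0.0119, a2 = 1.6)
  mi <- si_model("CR", "indicator", c(a1 = -0.0119))
  obs <- tibble::tibble(bh_age = c(30, 90), height = predict_height(pi, bh_age_to_t(c(30, 90))))
  cal <- calibrate(obs, mi)
  expect_lt(abs(cal$local[["a0"]] / 40 - 1), 1e-5)
  expect_lt(abs(cal$local[["a2"]] / 1.6 - 1), 1e-5)
})

test_that("indicator calibration refuses too few observations", {
  m <- si_model("CR", "indicator", c(a1 = -0.0119))
  expect_error(calibrate(tibble::tibble(bh_age = 50, height = 20), m),
               "at least 2 observations")
})

test_that("closed-form and numeric single-point calibrations agree", {
  g <- tbl_gada$CR
  m_gada <- si_model("CR", "gada", unlist(g[c("a1", "a20", "a21")]))
  m_equiv <- si_model("CR", "ggada", unlist(g[c("a1", "a20", "a21")]),
                      relation = "gada_equivalent")
  obs <- tibble::tibble(bh_age = 60, height = 22)
  c1 <- calibrate(obs, m_gada)    # closed-form chi0
  c2 <- calibrate(obs, m_equiv)   # 1-D nonlinear solve
  tg <- seq(4.5, 249.5, 5)
  expect_lt(max(abs(predict_height(c1$params, tg) - predict_height(c2$params, tg))),
            1e-8)
})

test_that("root screening rejects inadmissible candidates and breaks ties by residual", {
  g <- tbl_opt$CR
  scr <- screen_roots(c(-5, 30), g, residuals = c(0, 0.01))
  expect_false(scr$admissible[1])
  expect_match(scr$reason[1], "a0 > 0|asymptote|relation")
  expect_true(scr$selected[2])
  # two admissible candidates: smaller residual wins
  scr2 <- screen_roots(c(25, 40), g, residuals = c(0.3, 0.01))
  expect_true(scr2$selected[2] && !scr2$selected[1])
  # a candidate outside the published admissible range is screened out
  scr3 <- screen_roots(c(80, 30), g, residuals = c(0, 1))
  expect_false(scr3$admissible[1])
  expect_true(scr3$selected[2])
  expect_error(screen_roots(-5, g), "no admissible")
})

test_that("more calibration points give better curves under noise", {
  g <- tbl_opt$CR
  m <- si_model("CR", "ggada", unlist(g[c("a1", "a20", "a21", "a22")]),
                relation = "optimal")
  truth <- 34
  p <- ggada_local_to_params(truth, g)
  grid <- bh_age_to_t(seq(10, 200, 10))
  h_true <- predict_height(p, grid)
  set.seed(77)
  mse1 <- mse5 <- numeric(12)
  for (r in 1:12) {
    ages <- c(25, 50, 80, 120, 160)
    noisy <- predict_height(p, bh_age_to_t(ages)) + rnorm(5, 0, 0.8)
    noisy <- pmax(noisy, 1.4)
    c1 <- calibrate(tibble::tibble(bh_age = ages[2], height = noisy[2]), m)
    c5 <- calibrate(tibble::tibble(bh_age = ages, height = noisy), m)
    mse1[r] <- mean((predict_height(c1$params, grid) - h_true)^2)
    mse5[r] <- mean((predict_height(c5$params, grid) - h_true)^2)
  }
  expect_lt(mean(mse5), mean(mse1))
})

test_that("mixed-model calibration delegates to empirical Bayes prediction", {
  d <- sim_small("mixed", "CR", n_trees = 15, seed = 51)
  f <- suppressWarnings(fit_mixed(d, "CR", control = fast_ctrl()))
  cal <- calibrate(d[d$tree_id == d$tree_id[1], c("bh_age", "height")], f)
  expect_identical(cal$method, "empirical_bayes")
  expect_s3_class(cal$params, "base_params")
  pred <- predict(cal, bh_age = c(50, 100))
  expect_true(all(pred$height > 1.3))
})
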