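test_that("AICc follows its finite-sample formula", {
  expect_equal(aicc(-100, 0, 50), 200)  # correction vanishes at k = 0
  expect_equal(aicc(-100, 3, 50), 200 + 6 + 24 / 46)
  expect_error(aicc(-100, 49, 50), "n > k")
})

test_that("parameter counts follow the package conventions", {
  d <- sim_small("gada", "CR", n_trees = 8, seed = 41)
  fi <- fit_indicator(d, "CR", control = fast_ctrl())
  expect_equal(count_parameters(fi), 1 + 2 * 8 + 1)
  fg <- fit_gada(d, "CR", control = fast_ctrl())
  expect_equal(count_parameters(fg), 3 + 8 + 1)
  fo <- fit_ggada(d, "CR", "optimal", control = fast_ctrl())
  expect_equal(count_parameters(fo), 4 + 8 + 1)
  expect_equal(fg$aicc, aicc(fg$loglik, 12, fg$n_obs))
})

test_that("error profiles summarise residuals in protocol-age bins", {
  d <- sim_small("indicator", "CR", n_trees = 6, seed = 42, sigma2 = 1e-10)
  f <- fit_indicator(d, "CR", control = fast_ctrl())
  ep <- error_profile(f)
  expect_lt(max(abs(ep$mean_error)), 1e-4)   # near-perfect fit
  expect_equal(sum(ep$n), f$n_obs)           # bins partition the data
  expect_true(all(ep$bh_age %% 5 == 0))
  # a constant +0.5 m bias in the predictions shifts every bin mean to -0.5
  f2 <- f
  f2$data$.fitted <- f2$data$.fitted + 0.5
  f2$data$.resid <- f2$data$height - f2$data$.fitted
  ep2 <- error_profile(f2)
  expect_equal(ep2$mean_error, rep(-0.5, nrow(ep2)), tolerance = 1e-4)
  ov <- attr(ep2, "overall")
  expect_false(ov$zero_mean_at_05)
})

test_that("overall mean error is small relative to its standard error", {
  d <- sim_small("indicator", "CR", n_trees = 20, seed = 43)
  f <- fit_indicator(d, "CR", control = fast_ctrl())
  ov <- attr(error_profile(f), "overall")
  expect_lt(abs(ov$mean_error), 3 * ov$se)
})

test_that("comparison report tabulates fits and variance increases", {
  d <- sim_small("gada", "CR", n_trees = 10, seed = 44)
  fi <- fit_indicator(d, "CR", control = fast_ctrl())
  fg <- fit_gada(d, "CR", control = fast_ctrl())
  rep1 <- comparison_report(fi, fg)
  expect_s3_class(rep1, "si_comparison")
  expect_equal(nrow(rep1), 2)
  base <- rep1$sigma2[rep1$parameterization == "indicator"]
  expect_equal(rep1$pct_variance_increase,
               100 * (rep1$sigma2 / base - 1))
  expect_equal(rep1$sigma2_se, rep1$sigma2 * sqrt(2 / rep1$n_obs))
  # order invariance
  rep2 <- comparison_report(fg, fi)
  expect_equal(sort(rep2$pct_variance_increase),
               sort(rep1$pct_variance_increase))
  # identical fits show a 0% increase
  rep3 <- comparison_report(fi, fi)
  expect_equal(rep3$pct_variance_increase, c(0, 0))
})

test_that("fits on different datasets are refused", {
  d1 <- sim_small("gada", "CR", n_trees = 6, seed = 45)
  d2 <- sim_small("gada", "CR", n_trees = 6, seed = 46)
  f1 <- fit_indicator(d1, "CR", control = fast_ctrl())
  f2 <- fit_gada(d2, "CR", control = fast_ctrl())
  expect_error(comparison_report(f1, f2), "not.*comparable|different datasets")
})

test_that("variance increase arithmetic matches its definition", {
  expect_equal(variance_increase_pct(0.3104, 0.2850), 100 * (0.3104 / 0.2850 - 1))
  expect_equal(variance_increase_pct(c(1, 2), 1), c(0, 100))
  expect_error(variance_increase_pct(1, 0), "positive")
})
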