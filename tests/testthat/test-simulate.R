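test_that("identical seeds reproduce identical datasets and truth records", {
  d1 <- simulate_trees(sim_config(), seed = 61)
  d2 <- simulate_trees(sim_config(), seed = 61)
  expect_identical(d1$height, d2$height)
  expect_identical(attr(d1, "truth")$locals, attr(d2, "truth")$locals)
  d3 <- simulate_trees(sim_config(), seed = 62)
  expect_false(identical(d1$height, d3$height))
  # the generator restores the global RNG state
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(simulate_trees(sim_config(n_trees = 5), seed = 1))
  expect_identical(runif(1), x1)
})

test_that("default simulations reproduce the target study structure", {
  d <- simulate_trees(sim_config(), seed = 63)
  expect_equal(length(unique(d$tree_id)), 84)
  ages <- tapply(d$bh_age, d$tree_id, max)
  expect_true(all(ages >= 70 & ages <= 255 & ages %% 5 == 0))
  expect_true(all(d$bh_age %% 5 == 0))
  expect_true(all(d$height > 1.29))
  expect_lt(max(d$height), 50)
  expect_gt(nrow(d), 2200)   # ~84 trees x ~32 protocol ages
  expect_lt(nrow(d), 3200)
  expect_true(all(d$subzone %in% essf_subzones()$subzone))
})

test_that("driving locals respect the truncation range and the relation", {
  cfg <- sim_config()
  loc <- sample_locals(cfg, seed = 64)
  expect_true(all(loc$driving >= 12.1933 & loc$driving <= 58.3228))
  # scatter 0 puts the partner parameter exactly on the optimal relation
  cfg0 <- sim_config(relation_scatter_sd = 0)
  loc0 <- sample_locals(cfg0, seed = 64)
  la <- log(loc0$p0)
  expect_equal(loc0$p2, -9.6725 + 6.7925 * la - 1.0247 * la^2, tolerance = 1e-12)
  # the default free-locals law scatters off the relation
  la <- log(loc$p0)
  expect_gt(max(abs(loc$p2 - (-9.6725 + 6.7925 * la - 1.0247 * la^2))), 0.01)
  expect_error(sim_config(local_law = list(lower = 50, upper = 40)), "empty")
})

test_that("exact-noise residuals of the true curves are Gaussian", {
  d <- simulate_trees(sim_config(relation_scatter_sd = 0,
                                 parameterization = "ggada_optimal"), seed = 65)
  tr <- attr(d, "truth")$locals
  idx <- match(d$tree_id, tr$tree_id)
  mu <- sitegada:::.h_pred("CR", tr$p0[idx], tr$p1[idx], tr$p2[idx],
                           bh_age_to_t(d$bh_age))
  r <- d$height - mu
  keep <- d$height > 1.31   # exclude the truncation-affected floor
  expect_gt(shapiro.test(sample(r[keep], 2000))$p.value, 0.05)
  expect_lt(abs(sd(r[keep]) - sqrt(0.285)), 0.03)
})

test_that("protocol filter keeps multiples of five years", {
  raw <- tibble::tibble(tree_id = "A", bh_age = 1:170,
                        height = 1.4 + (1:170) * 0.2)
  f <- protocol_filter(raw)
  expect_equal(nrow(f), 34)
  expect_equal(f$bh_age, seq(5, 170, 5))
  expect_identical(protocol_filter(f), f)          # idempotent
  expect_warning(protocol_filter(raw[raw$bh_age < 5, ]), "protocol")
})

test_that("each generating law produces data its fit expects", {
  for (pz in c("gada", "ggada_optimal", "mixed")) {
    d <- simulate_trees(sim_config(n_trees = 6, parameterization = pz),
                        seed = 66)
    expect_equal(length(unique(d$tree_id)), 6)
    expect_true(all(is.finite(d$height)))
  }
})
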