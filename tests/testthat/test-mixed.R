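# The marginal-likelihood machinery is checked against exact oracles on
# small problems: a linear sub-model with a closed-form Gaussian marginal,
# and brute-force quadrature on a coarse grid.

test_that("zero random-effect covariance degenerates to the fixed-only likelihood", {
  d <- sim_small("mixed", "CR", n_trees = 6, seed = 21)
  fx <- c(a0 = 37.8, a1 = -0.0118, a2 = 1.51)
  p <- base_params("CR", a0 = fx[[1]], a1 = fx[[2]], a2 = fx[[3]])
  r <- d$height - predict_height(p, bh_age_to_t(d$bh_age))
  for (m in c("laplace", "agq", "first_order")) {
    nl <- marginal_nll(d, "CR", fx, cov = matrix(0, 2, 2), sigma2 = 0.3,
                       method = m)
    expect_equal(nl, gaussian_nll(r, 0.3), tolerance = 1e-6)
  }
})

test_that("linear sub-case matches the closed-form Gaussian marginal", {
  # CR with shape fixed at 1 and a random asymptote only is linear in the
  # random effect, so the marginal is exactly Gaussian
  d <- sim_small("mixed", "CR", n_trees = 8, seed = 22)
  fx <- c(a0 = 20, a1 = -0.02, a2 = 1)
  v_u <- 16; s2 <- 0.4
  ids <- unique(d$tree_id)
  oracle <- 0
  for (id in ids) {
    di <- d[d$tree_id == id, ]
    x <- 1 - exp(fx[[2]] * (di$bh_age - 0.5))
    r <- di$height - 1.3 - fx[[1]] * x
    V <- v_u * (x %o% x) + diag(s2, length(x))
    ch <- chol(V)
    oracle <- oracle + 0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                              sum(backsolve(ch, r, transpose = TRUE)^2))
  }
  for (m in c("laplace", "agq", "first_order")) {
    nl <- marginal_nll(d, "CR", fx, cov = v_u, sigma2 = s2,
                       random_set = "a0", method = m)
    expect_equal(nl, oracle, tolerance = 1e-6)
  }
})

test_that("adaptive quadrature matches brute-force integration on a toy", {
  # 2 trees, one nonlinear random effect (the CR shape)
  d <- sim_small("mixed", "CR", n_trees = 2, seed = 23)
  fx <- c(a0 = 35, a1 = -0.012, a2 = 1.5)
  v_u <- 0.04; s2 <- 0.3
  brute <- 0
  for (id in unique(d$tree_id)) {
    di <- d[d$tree_id == id, ]
    tt <- di$bh_age - 0.5
    ug <- seq(-8, 8, length.out = 4001) * sqrt(v_u)
    du <- ug[2] - ug[1]
    dens <- vapply(ug, function(u) {
      h <- 1.3 + fx[[1]] * (1 - exp(fx[[2]] * tt))^(fx[[3]] + u)
      exp(sum(stats::dnorm(di$height, h, sqrt(s2), log = TRUE)) +
          stats::dnorm(u, 0, sqrt(v_u), log = TRUE))
    }, numeric(1))
    brute <- brute - log(sum(dens) * du)
  }
  nl <- marginal_nll(d, "CR", fx, cov = v_u, sigma2 = s2,
                     random_set = "a2", method = "agq", agq_order = 25)
  expect_equal(nl, brute, tolerance = 1e-6)
})

test_that("Laplace and adaptive quadrature agree closely on realistic data", {
  d <- sim_small("mixed", "CR", n_trees = 20, seed = 24)
  tr <- attr(d, "truth")$globals
  nl <- marginal_nll(d, "CR", unlist(tr$fixed), tr$vcov, 0.285, method = "laplace")
  na <- marginal_nll(d, "CR", unlist(tr$fixed), tr$vcov, 0.285, method = "agq")
  expect_lt(abs(nl - na) / abs(na), 0.001)
})

test_that("the marginal likelihood is invariant to the covariance factorization", {
  # same D supplied directly and as a rank-revealing eigen reconstruction
  d <- sim_small("mixed", "CR", n_trees = 5, seed = 25)
  fx <- c(a0 = 36, a1 = -0.012, a2 = 1.5)
  D <- matrix(c(90, 0.1, 0.1, 0.14), 2)
  ei <- eigen(D, symmetric = TRUE)
  D2 <- ei$vectors %*% diag(ei$values) %*% t(ei$vectors)
  expect_equal(marginal_nll(d, "CR", fx, D, 0.3),
               marginal_nll(d, "CR", fx, D2, 0.3), tolerance = 1e-6)
})

test_that("mixed fit recovers fixed effects on a small matched simulation", {
  d <- sim_small("mixed", "CR", n_trees = 25, seed = 26, age_range = c(70, 180))
  f <- suppressWarnings(fit_mixed(d, "CR", control = fast_ctrl()))
  tr <- unlist(attr(d, "truth")$globals$fixed)
  expect_true(f$converged)
  expect_lt(max(abs(f$coef - tr[names(f$coef)]) / f$se), 4)
  expect_equal(f$n_params, 7L)
  # empirical-Bayes predictions centre near zero across trees
  expect_lt(max(abs(colMeans(as.matrix(f$ranef[-1])))),
            3 * max(sqrt(diag(f$cov_re)) / sqrt(f$n_trees)))
})

test_that("random effects for a new tree behave like an empirical Bayes posterior", {
  d <- sim_small("mixed", "CR", n_trees = 20, seed = 27)
  f <- suppressWarnings(fit_mixed(d, "CR", control = fast_ctrl()))
  # a tree lying exactly on the population-mean curve has effects near zero
  pop <- do.call(base_params, c(list(family = "CR"), as.list(f$coef)))
  nd <- tibble::tibble(bh_age = seq(10, 100, 10),
                       height = predict_height(pop, bh_age_to_t(seq(10, 100, 10))))
  eb <- predict_random_effects(f, nd)
  expect_lt(max(abs(eb$u) / sqrt(diag(f$cov_re))), 0.05)
  # re-predicting a training tree reproduces its fitted EB values
  id1 <- f$ranef$tree_id[1]
  eb1 <- predict_random_effects(f, d[d$tree_id == id1, c("bh_age", "height")])
  expect_equal(unname(eb1$u), unlist(f$ranef[1, -1], use.names = FALSE),
               tolerance = 1e-4)
  # five observations constrain the posterior more than one
  tr1 <- d[d$tree_id == id1, c("bh_age", "height")]
  e1 <- predict_random_effects(f, tr1[3, ])
  e5 <- predict_random_effects(f, tr1[seq(2, 10, 2), ])
  expect_lt(det(e5$post_vcov), det(e1$post_vcov))
})

test_that("EB effects shrink toward zero as the residual variance grows", {
  d <- sim_small("mixed", "CR", n_trees = 15, seed = 28)
  f <- suppressWarnings(fit_mixed(d, "CR", control = fast_ctrl()))
  nd <- d[d$tree_id == f$ranef$tree_id[2], c("bh_age", "height")]
  sizes <- vapply(c(1, 4, 16, 64), function(mult) {
    fm <- f; fm$sigma2 <- f$sigma2 * mult
    sqrt(sum(predict_random_effects(fm, nd)$u^2))
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("normality diagnostic separates normal from skewed locals", {
  set.seed(31)
  ok <- normality_diagnostic(rnorm(84))
  expect_true(ok$pass)
  bad <- normality_diagnostic(rlnorm(84, sdlog = 1))
  expect_false(bad$pass)
  cst <- normality_diagnostic(rep(1.5, 20))
  expect_false(cst$testable)
  expect_error(normality_diagnostic(rnorm(5)), "8")
})

test_that("HIV mixed fitting defaults to first-order integration", {
  d <- sim_small("mixed", "HIV", n_trees = 12, seed = 32)
  f <- suppressWarnings(fit_mixed(d, "HIV", control = fast_ctrl()))
  expect_identical(f$method, "first_order")
  expect_true(is.finite(f$loglik))
})
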