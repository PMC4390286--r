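# Nonlinear mixed-effects estimation with a self-implemented marginal
# likelihood.
#
# Tree-level random effects enter additively on the local parameters
# (e.g. CR: y = 1.3 + (a0 + u0)(1 - exp(a1 t))^(a2 + u2) + e) and are
# assumed multivariate normal with an unstructured covariance.  The
# per-tree integrals over the random effects are evaluated in standardized
# coordinates z (u = L z with D = L L'), where the integrand is
# exp(-SSE_i(Lz)/(2 sigma2) - z'z/2):
#
# * laplace (default): second-order expansion at the per-tree mode of z,
# * agq: adaptive Gauss-Hermite quadrature at the mode (the test oracle),
# * first_order: linearization of the model at z = 0 (Beal-Sheiner), a
#   lower-fidelity method kept because it is sometimes the only one that
#   converges for the heavy-tailed HIV local parameters.

.default_random_set <- list(CR = c("a0", "a2"), HIV = c("b0", "b2"),
                            SCH = c("c0", "c1"))

.mixed_ctx <- function(dat, family, random_set) {
  all_nm <- .si_par_names[[family]]
  if (!all(random_set %in% all_nm))
    abort(sprintf("`random_set` must be a subset of %s.", paste(all_nm, collapse = ", ")))
  random_set <- all_nm[all_nm %in% random_set]
  q <- length(random_set)
  if (!q %in% 1:2) abort("`random_set` must contain 1 or 2 parameters.")
  ridx <- match(random_set, all_nm)
  par_fun <- function(globals, theta_nat) {
    p <- lapply(1:3, function(k) {
      v <- rep(globals[[all_nm[k]]], dat$n_trees)
      j <- match(k, ridx)
      if (!is.na(j)) v <- v + theta_nat[, j]
      v
    })
    names(p) <- c("p0", "p1", "p2")
    p
  }
  sse <- .sse_factory(dat, family, par_fun, profile_scale = FALSE)
  tree <- dat$tree; t <- dat$t; logt <- log(t)
  jcache <- new_environment(); jcache$key <- NULL

  # analytic Jacobian of the fitted height wrt the random parameters (FD
  # fallback for a random exponent-type parameter a1/b1/c2)
  jac <- function(fx, U, fitted) {
    w <- fitted - BH
    p <- lapply(1:3, function(k) {
      v <- rep(fx[[all_nm[k]]], dat$n_trees)
      j <- match(k, ridx)
      if (!is.na(j)) v <- v + U[, j]
      v
    })
    J <- matrix(0, dat$n_obs, q)
    for (j in seq_len(q)) {
      k <- ridx[j]
      J[, j] <- if (family == "CR" && k == 1) w / p[[1]][tree]
      else if (family == "CR" && k == 3) {
        key <- c(1, p[[2]])
        if (!identical(jcache$key, key)) {
          x <- 1 - exp(p[[2]][tree] * t)
          lx <- rep(NaN, length(x)); pos <- is.finite(x) & x > 0
          lx[pos] <- log(x[pos])
          jcache$basis <- lx; jcache$key <- key
        }
        w * jcache$basis
      }
      else if (family == "HIV" && k == 1) w / (3 * p[[1]][tree])
      else if (family == "HIV" && k == 3) {
        key <- c(2, p[[2]])
        if (!identical(jcache$key, key)) {
          jcache$basis <- exp((p[[2]][tree] - 1) * logt); jcache$key <- key
        }
        -w / (3 * (p[[3]][tree] + jcache$basis))
      }
      else if (family == "SCH" && k == 1) w
      else if (family == "SCH" && k == 2) {
        key <- c(3, p[[3]])
        if (!identical(jcache$key, key)) {
          jcache$basis <- exp(p[[3]][tree] * logt); jcache$key <- key
        }
        w * jcache$basis
      }
      else {  # exponent-type random parameter: central finite differences
        dk <- 1e-5 * (abs(fx[[all_nm[k]]]) + 1e-3)
        Up <- U; Up[, j] <- Up[, j] + dk
        Um <- U; Um[, j] <- Um[, j] - dk
        (sse(fx, Up, want_fitted = TRUE)$fitted -
         sse(fx, Um, want_fitted = TRUE)$fitted) / (2 * dk)
      }
    }
    J
  }

  list(family = family, random_set = random_set, q = q, ridx = ridx,
       sse = sse, jac = jac,
       n_i = diff(c(0, dat$ends)), ends = dat$ends,
       n_trees = dat$n_trees, n_obs = dat$n_obs,
       tree = dat$tree, y = dat$y)
}

# lower Cholesky-like factor of a PSD covariance (tolerates singular D)
.cov_factor <- function(cov, q) {
  if (q == 1L) return(matrix(sqrt(max(as.numeric(cov), 0)), 1, 1))
  cov <- (cov + t(cov)) / 2
  ch <- tryCatch(t(chol(cov)), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ei <- eigen(cov, symmetric = TRUE)
  ei$vectors %*% diag(sqrt(pmax(ei$values, 0)), q) %*% t(ei$vectors)
}

# Per-tree mode finding + curvature, shared by laplace and agq.  The modes
# solve a penalized nonlinear least-squares problem per tree; a vectorized
# Levenberg-Marquardt Gauss-Newton iteration (analytic Jacobians, all trees
# simultaneously) is robust in the long curved valleys these models produce.
.mixed_modes <- function(ctx, fx, L, sigma2, cache, maxit = 60, tol = 1e-9) {
  q <- ctx$q; tree <- ctx$tree
  obj_z <- function(Z) {
    U <- Z %*% t(L)
    ctx$sse(fx, U)$sse / (2 * sigma2) + 0.5 * rowSums(Z^2)
  }
  Z <- cache$Z
  if (is.null(Z)) Z <- matrix(0, ctx$n_trees, q)
  lam <- rep(1e-3, ctx$n_trees)
  f0 <- obj_z(Z)
  for (iter in seq_len(maxit)) {
    U <- Z %*% t(L)
    out <- ctx$sse(fx, U, want_fitted = TRUE)
    r <- ctx$y - out$fitted
    Ju <- ctx$jac(fx, U, out$fitted)
    Jz <- Ju %*% L
    bad <- !is.finite(r) | rowSums(!is.finite(Jz)) > 0
    if (any(bad)) { r[bad] <- 0; Jz[bad, ] <- 0 }
    if (q == 1L) {
      A11 <- .grp_sum(Jz[, 1]^2, ctx$ends) / sigma2
      g1 <- -.grp_sum(Jz[, 1] * r, ctx$ends) / sigma2 + Z[, 1]
      s1 <- -g1 / (A11 + 1 + lam)
      step <- cbind(s1)
      gnorm <- abs(g1)
    } else {
      A11 <- .grp_sum(Jz[, 1]^2, ctx$ends) / sigma2
      A22 <- .grp_sum(Jz[, 2]^2, ctx$ends) / sigma2
      A12 <- .grp_sum(Jz[, 1] * Jz[, 2], ctx$ends) / sigma2
      g1 <- -.grp_sum(Jz[, 1] * r, ctx$ends) / sigma2 + Z[, 1]
      g2 <- -.grp_sum(Jz[, 2] * r, ctx$ends) / sigma2 + Z[, 2]
      d1 <- A11 + 1 + lam; d2 <- A22 + 1 + lam
      det <- d1 * d2 - A12^2
      s1 <- -(d2 * g1 - A12 * g2) / det
      s2 <- -(d1 * g2 - A12 * g1) / det
      step <- cbind(s1, s2)
      gnorm <- pmax(abs(g1), abs(g2))
    }
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -3), 3)
    fn <- obj_z(Z + step)
    ok <- is.finite(fn) & fn <= f0
    Z[ok, ] <- Z[ok, , drop = FALSE] + step[ok, , drop = FALSE]
    f0[ok] <- fn[ok]
    lam[ok] <- pmax(lam[ok] / 3, 1e-5)
    lam[!ok] <- pmin(lam[!ok] * 8, 1e7)
    mstep <- if (any(ok)) max(abs(step[ok, , drop = FALSE])) else 0
    if (mstep < tol && all(gnorm[!ok] < 1e-6 | lam[!ok] >= 1e7)) break
  }
  cache$Z <- Z
  h <- 1e-4 * (abs(Z) + 0.1)
  if (ctx$q == 1L) {
    fp <- obj_z(Z + h); fm <- obj_z(Z - h)
    H11 <- (fp - 2 * f0 + fm) / h[, 1]^2
    list(obj_z = obj_z, Z = Z, g = f0, H = cbind(h11 = H11),
         logdet = log(pmax(H11, 1e-300)), bad = !is.finite(H11) | H11 <= 0)
  } else {
    e1 <- cbind(h[, 1], 0); e2 <- cbind(0, h[, 2])
    fp1 <- obj_z(Z + e1); fm1 <- obj_z(Z - e1)
    fp2 <- obj_z(Z + e2); fm2 <- obj_z(Z - e2)
    fpp <- obj_z(Z + e1 + e2); fpm <- obj_z(Z + e1 - e2)
    fmp <- obj_z(Z - e1 + e2); fmm <- obj_z(Z - e1 - e2)
    H11 <- (fp1 - 2 * f0 + fm1) / h[, 1]^2
    H22 <- (fp2 - 2 * f0 + fm2) / h[, 2]^2
    H12 <- (fpp - fpm - fmp + fmm) / (4 * h[, 1] * h[, 2])
    det <- H11 * H22 - H12^2
    bad <- !is.finite(det) | det <= 0 | H11 <= 0
    list(obj_z = obj_z, Z = Z, g = f0, H = cbind(h11 = H11, h12 = H12, h22 = H22),
         logdet = log(pmax(det, 1e-300)), bad = bad)
  }
}

.mixed_nll_parts <- function(ctx, fx, cov, sigma2, method, agq_order, cache) {
  q <- ctx$q
  L <- .cov_factor(cov, q)
  const <- ctx$n_i / 2 * log(2 * pi * sigma2)
  if (method == "first_order") {
    Z0 <- matrix(0, ctx$n_trees, q)
    f0 <- ctx$sse(fx, Z0, want_fitted = TRUE)
    r <- ctx$y - f0$fitted
    D <- if (q == 1L) matrix(as.numeric(cov), 1, 1) else cov
    fxv <- unlist(fx[.si_par_names[[ctx$family]]])
    nll_i <- numeric(ctx$n_trees)
    Jcols <- lapply(seq_len(q), function(k) {
      dk <- 1e-4 * (sqrt(max(D[k, k], 0)) + 0.01 * abs(fxv[ctx$ridx[k]]) + 1e-3)
      Up <- Z0; Up[, k] <- dk
      Um <- Z0; Um[, k] <- -dk
      (ctx$sse(fx, Up, want_fitted = TRUE)$fitted -
       ctx$sse(fx, Um, want_fitted = TRUE)$fitted) / (2 * dk)
    })
    Jm <- do.call(cbind, Jcols)
    bad_any <- !is.finite(r) | rowSums(!is.finite(Jm)) > 0
    for (i in seq_len(ctx$n_trees)) {
      j <- which(ctx$tree == i)
      if (any(bad_any[j])) { nll_i[i] <- .PENALTY; next }
      Zi <- Jm[j, , drop = FALSE]
      Vi <- Zi %*% D %*% t(Zi) + diag(sigma2, length(j))
      ch <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(ch)) { nll_i[i] <- .PENALTY; next }
      ri <- r[j]
      quad <- sum(backsolve(ch, ri, transpose = TRUE)^2)
      nll_i[i] <- 0.5 * (length(j) * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
    }
    return(list(nll_i = nll_i, Z = NULL, L = L, bad = nll_i >= .PENALTY))
  }

  m <- .mixed_modes(ctx, fx, L, sigma2, cache)
  if (method == "laplace") {
    nll_i <- const + m$g + 0.5 * m$logdet
    nll_i[m$bad] <- .PENALTY
    return(list(nll_i = nll_i, Z = m$Z, L = L, bad = m$bad))
  }
  # adaptive Gauss-Hermite in the mode-centred, curvature-scaled frame; the
  # integrand is evaluated relative to its value at the mode so that trees
  # with large SSE do not underflow
  gh <- pracma::gaussHermite(agq_order)
  if (q == 1L) {
    H <- m$H[, "h11"]
    S <- 0
    for (k in seq_along(gh$x)) {
      Zk <- m$Z + sqrt(2 / H) * gh$x[k]
      S <- S + gh$w[k] * exp(gh$x[k]^2 - (m$obj_z(Zk) - m$g))
    }
    nll_i <- const + 0.5 * log(2 * pi) + m$g - log(sqrt(2 / H) * S)
  } else {
    det <- m$H[, "h11"] * m$H[, "h22"] - m$H[, "h12"]^2
    # lower Cholesky of H^-1 per tree
    a11 <- sqrt(pmax(m$H[, "h22"] / det, 1e-300))
    a21 <- -m$H[, "h12"] / det / a11
    a22 <- sqrt(pmax(m$H[, "h11"] / det - a21^2, 1e-300))
    S <- 0
    for (j in seq_along(gh$x)) for (k in seq_along(gh$x)) {
      z1 <- m$Z[, 1] + sqrt(2) * a11 * gh$x[j]
      z2 <- m$Z[, 2] + sqrt(2) * (a21 * gh$x[j] + a22 * gh$x[k])
      S <- S + gh$w[j] * gh$w[k] *
        exp(gh$x[j]^2 + gh$x[k]^2 - (m$obj_z(cbind(z1, z2)) - m$g))
    }
    nll_i <- const + log(2 * pi) + m$g - log(2 * a11 * a22 * S)
  }
  nll_i[m$bad | !is.finite(nll_i)] <- .PENALTY
  list(nll_i = nll_i, Z = m$Z, L = L, bad = m$bad | !is.finite(nll_i))
}

#' Marginal negative log-likelihood of a nonlinear mixed-effects model
#'
#' Integrates the tree-level random effects out of the likelihood, one tree
#' at a time, and returns the total negative log marginal likelihood.
#'
#' @param data Data frame with columns `tree_id`, `bh_age`, `height`.
#' @param family `"CR"`, `"HIV"` or `"SCH"`.
#' @param fixed Named vector of the three fixed-effect (population)
#'   parameters of the family.
#' @param cov Random-effect covariance: a `q x q` matrix (or a scalar
#'   variance when one parameter is random).
#' @param sigma2 Residual variance (m^2).
#' @param random_set Parameters carrying random effects (default: the
#'   asymptote-like and shape parameters of the family).
#' @param method `"laplace"`, `"agq"` (adaptive Gauss-Hermite) or
#'   `"first_order"` (linearization at zero random effects).
#' @param agq_order Quadrature order per dimension for `"agq"`.
#' @param warn_failures Warn (naming the trees) when a per-tree integral
#'   fails and is replaced by a large penalized contribution.
#' @return The negative log marginal likelihood.
#' @export
marginal_nll <- function(data, family, fixed, cov, sigma2, random_set = NULL,
                         method = c("laplace", "agq", "first_order"),
                         agq_order = 9, warn_failures = TRUE) {
  family <- match_family(family)
  method <- arg_match(method)
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  random_set <- random_set %||% .default_random_set[[family]]
  dat <- .si_data(data, min_obs = 1L)
  ctx <- .mixed_ctx(dat, family, random_set)
  cov <- if (ctx$q == 1L) matrix(as.numeric(cov), 1, 1) else as.matrix(cov)
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) abort("`cov` must be positive semidefinite.")
  parts <- .mixed_nll_parts(ctx, as.list(fixed), cov, sigma2, method,
                            agq_order, cache = new_environment())
  if (warn_failures && any(parts$bad))
    warn(sprintf("per-tree integral failed for tree(s) %s; contribution penalized.",
                 paste(head(dat$tree_levels[parts$bad], 5), collapse = ", ")))
  sum(parts$nll_i)
}

#' Fit a mixed-effects site index model
#'
#' Maximum-likelihood estimation of the fixed effects, the unstructured
#' random-effect covariance and the residual variance, maximizing the
#' marginal likelihood produced by [marginal_nll()].  The covariance is
#' parameterized internally by log standard deviations and an
#' inverse-hyperbolic-tangent correlation, so every proposal is positive
#' semidefinite by construction.
#'
#' The default integration method is the Laplace approximation.  For the
#' HIV family the default is the first-order (Beal-Sheiner) linearization:
#' its local parameters are strongly non-normal in practice and the
#' higher-order methods often fail to converge; predictions from an HIV
#' mixed fit must be admissibility-checked (see
#' [admissible_prediction_check()]), since large negative random effects
#' can make the curve undefined.
#'
#' @inheritParams marginal_nll
#' @param start Optional named list/vector overriding starting values for
#'   the fixed effects.
#' @param control A [si_control()] list (mixed fits default to a single
#'   start from data-driven values).
#' @return An object of class `si_mixed_fit`.
#' @export
fit_mixed <- function(data, family, method = NULL, random_set = NULL,
                      start = NULL, control = si_control(n_starts = 1),
                      agq_order = 9) {
  family <- match_family(family)
  random_set <- random_set %||% .default_random_set[[family]]
  method <- method %||% if (family == "HIV") "first_order" else "laplace"
  method <- arg_match(method, c("laplace", "agq", "first_order"))
  dat <- .si_data(data, min_obs = 1L)
  if (dat$n_trees < 10)
    warn("fewer than 10 trees: mixed-effects variance components will be poorly determined.")
  ctx <- .mixed_ctx(dat, family, random_set)
  q <- ctx$q
  all_nm <- .si_par_names[[family]]
  trans <- .par_trans[[family]]

  # data-driven starts from rough per-tree locals
  rough <- tryCatch(.rough_locals(dat, family), error = function(e) NULL)
  fx0 <- .default_par_start[[family]]
  s0 <- abs(fx0[ctx$random_set]) * 0.2 + 1e-3
  r0 <- 0
  sg0 <- 0.3
  if (!is.null(rough)) {
    lc <- as.matrix(rough[, ctx$random_set, drop = FALSE])
    ok <- rowSums(!is.finite(lc)) == 0
    if (sum(ok) > 3) {
      lc <- lc[ok, , drop = FALSE]
      fx0[ctx$random_set] <- apply(lc, 2, median)
      s0 <- pmax(apply(lc, 2, sd), abs(fx0[ctx$random_set]) * 1e-3 + 1e-4)
      if (q == 2L) r0 <- min(max(cor(lc[, 1], lc[, 2]), -0.95), 0.95)
    }
    sg0 <- attr(rough, "sigma2") %||% 0.3
  }
  if (!is.null(start)) fx0[names(start)] <- unlist(start)

  # parameter vector: transformed fixed effects, log sds, atanh correlation,
  # log sigma2
  pack_names <- c(all_nm, paste0("lsd_", ctx$random_set),
                  if (q == 2L) "atanh_r", "lsig2")
  unpack <- function(par) {
    par <- unname(par)
    fx <- setNames(vector("list", 3), all_nm)
    for (k in 1:3) fx[[k]] <- .tf_inv(par[k], trans[[all_nm[k]]])
    s <- exp(par[3 + seq_len(q)])
    r <- if (q == 2L) tanh(par[3 + q + 1]) else NULL
    cov <- if (q == 1L) matrix(s^2, 1, 1)
           else matrix(c(s[1]^2, r * s[1] * s[2], r * s[1] * s[2], s[2]^2), 2)
    sigma2 <- exp(par[length(par)])
    list(fx = fx, cov = cov, sigma2 = sigma2)
  }
  par0 <- c(vapply(all_nm, function(nm) .tf_fwd(fx0[[nm]], trans[[nm]]), numeric(1)),
            log(s0), if (q == 2L) atanh(r0), log(sg0))

  cache <- new_environment(); cache$Z <- NULL
  nll_fun <- function(par) {
    if (any(!is.finite(par))) return(1e12)
    u <- unpack(par)
    if (u$sigma2 <= 0 || !is.finite(u$sigma2)) return(1e12)
    parts <- tryCatch(
      .mixed_nll_parts(ctx, u$fx, u$cov, u$sigma2, method, agq_order, cache),
      error = function(e) NULL)
    if (is.null(parts)) return(1e12)
    v <- sum(parts$nll_i)
    if (!is.finite(v)) 1e12 else v
  }

  best <- nlminb(par0, nll_fun,
                 control = list(iter.max = control$outer_iter,
                                eval.max = 4 * control$outer_iter,
                                rel.tol = control$outer_rel_tol))
  if (control$n_starts > 1) {
    jit <- .with_local_seed(control$seed, {
      matrix(rnorm((control$n_starts - 1) * length(par0), sd = control$jitter_sd),
             ncol = length(par0))
    })
    for (s in seq_len(control$n_starts - 1)) {
      cache$Z <- NULL
      cand <- nlminb(par0 + jit[s, ] * (abs(par0) + 0.5), nll_fun,
                     control = list(iter.max = control$screen_iter,
                                    rel.tol = control$outer_rel_tol))
      if (is.finite(cand$objective) && cand$objective < best$objective - 1e-7) {
        cand <- nlminb(cand$par, nll_fun,
                       control = list(iter.max = control$outer_iter,
                                      rel.tol = control$outer_rel_tol))
        if (cand$objective < best$objective) best <- cand
      }
    }
  }

  # Newton polishing with our own finite-difference gradient and Hessian:
  # quasi-Newton optimizers tend to report "false convergence" on this
  # surface while a measurable Newton decrement remains
  np <- length(par0)
  fd_grad <- function(par) {
    vapply(seq_len(np), function(i) {
      h <- max(1e-4 * abs(par[i]), 1e-4)
      ei <- replace(numeric(np), i, h)
      (nll_fun(par + ei) - nll_fun(par - ei)) / (2 * h)
    }, numeric(1))
  }
  H <- tryCatch(.hessian_fd(nll_fun, best$par), error = function(e) NULL)
  Vt <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  gr <- fd_grad(best$par)
  if (!is.null(Vt) && all(is.finite(Vt))) {
    for (it in 1:6) {
      decr <- abs(drop(t(gr) %*% Vt %*% gr))
      if (!is.finite(decr) || decr < 1e-4) break
      step <- -drop(Vt %*% gr)
      improved <- FALSE
      for (hv in c(1, 0.5, 0.25, 0.1)) {
        cand <- best$par + hv * step
        fv <- nll_fun(cand)
        if (is.finite(fv) && fv < best$objective) {
          best$par <- cand; best$objective <- fv; improved <- TRUE; break
        }
      }
      if (!improved) break
      gr <- fd_grad(best$par)
    }
  }

  u <- unpack(best$par)
  parts <- .mixed_nll_parts(ctx, u$fx, u$cov, u$sigma2, method, agq_order, cache)
  nll <- sum(parts$nll_i)
  if (any(parts$bad))
    warn(sprintf("per-tree integral penalized for tree(s) %s at the optimum.",
                 paste(head(dat$tree_levels[parts$bad], 5), collapse = ", ")))

  # report scale: fixed effects, Var/Cov of the random effects, sigma2
  rep_fun <- function(par) {
    v <- unpack(par)
    c(unlist(v$fx),
      setNames(v$cov[lower.tri(v$cov, diag = TRUE)],
               if (q == 1L) paste0("var_", ctx$random_set)
               else c(paste0("var_", ctx$random_set[1]), "cov",
                      paste0("var_", ctx$random_set[2]))),
      sigma2 = v$sigma2)
  }
  est <- rep_fun(best$par)
  se <- setNames(rep(NA_real_, length(est)), names(est))
  vcov_rep <- matrix(NA_real_, length(est), length(est),
                     dimnames = list(names(est), names(est)))
  H <- tryCatch(.hessian_fd(nll_fun, best$par), error = function(e) NULL)
  Vt <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  grad_ok <- FALSE
  if (!is.null(Vt) && all(is.finite(Vt))) {
    J <- matrix(NA_real_, length(est), np)
    for (j in seq_len(np)) {
      h <- 1e-6 * (abs(best$par[j]) + 1e-3)
      ej <- replace(numeric(np), j, h)
      J[, j] <- (rep_fun(best$par + ej) - rep_fun(best$par - ej)) / (2 * h)
    }
    V <- J %*% Vt %*% t(J)
    if (all(is.finite(diag(V))) && all(diag(V) >= 0)) {
      vcov_rep[, ] <- V
      se <- setNames(sqrt(diag(V)), names(est))
    }
    decrement <- abs(drop(t(gr) %*% Vt %*% gr))
    grad_ok <- all(is.finite(gr)) && decrement < 1e-3
  } else {
    decrement <- NA_real_
    grad_ok <- all(is.finite(gr)) && max(abs(gr)) < 1e-2
  }

  # empirical-Bayes predictions and conditional fitted values
  if (is.null(parts$Z)) {           # first_order: compute modes for EB anyway
    m <- .mixed_modes(ctx, u$fx, .cov_factor(u$cov, q), u$sigma2, cache)
    Zhat <- m$Z
  } else Zhat <- parts$Z
  U <- Zhat %*% t(.cov_factor(u$cov, q))
  colnames(U) <- paste0("u_", ctx$random_set)
  fin <- ctx$sse(u$fx, U, want_fitted = TRUE)
  fitted <- rep(NA_real_, dat$n_obs)
  fitted[dat$order] <- fin$fitted
  data_tbl <- as_tibble(data[c("tree_id", "bh_age", "height")])
  data_tbl$.fitted <- fitted
  data_tbl$.resid <- data_tbl$height - fitted

  k <- 3L + (q * (q + 1L)) %/% 2L + 1L
  fit <- structure(list(
    family = family, parameterization = "mixed", method = method,
    random_set = ctx$random_set,
    coef = setNames(unlist(u$fx), all_nm),
    se = se[all_nm],
    cov_re = u$cov, sigma2 = u$sigma2,
    estimates = est, estimate_se = se, vcov = vcov_rep,
    loglik = -nll, n_params = k, n_obs = dat$n_obs, n_trees = dat$n_trees,
    aicc = aicc(-nll, k, dat$n_obs),
    converged = grad_ok && !any(parts$bad),
    ranef = as_tibble(cbind(tibble(tree_id = dat$tree_levels), as.data.frame(U))),
    data = data_tbl,
    demotions = character(),
    diagnostics = list(gradient = gr, decrement = decrement,
                       optim_message = best$message)
  ), class = c("si_mixed_fit"))
  if (!fit$converged) warn("mixed-effects fit did not converge cleanly.")
  fit
}

#' @export
print.si_mixed_fit <- function(x, ...) {
  cat(sprintf("<si_mixed_fit> %s site index model, mixed effects (%s), random: %s\n",
              x$family, x$method, paste(x$random_set, collapse = ", ")))
  cat(sprintf("  %d trees, %d observations%s\n", x$n_trees, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- sprintf("%s = %.6g (SE %.3g)", names(x$estimates), x$estimates, x$estimate_se)
  cat("  estimates:", paste(est, collapse = ",\n             "), "\n")
  cat(sprintf("  logLik = %.2f, k = %d, AICc = %.0f\n", x$loglik, x$n_params, x$aicc))
  invisible(x)
}

#' Empirical-Bayes random-effect prediction for a new tree
#'
#' Returns the posterior mode of the random effects for a tree not in the
#' fitting data, given its observed height-age pair(s) and the fitted
#' population parameters.  Usable with a single observation, though the
#' posterior spread (also returned) shrinks as observations accumulate.
#'
#' @param fit An `si_mixed_fit` object.
#' @param newdata Data frame with columns `bh_age` and `height` for one
#'   tree.
#' @param check_admissible Abort if the calibrated parameters are
#'   inadmissible over the observed age range.
#' @return A list with `u` (named random effects), `params` (the calibrated
#'   [base_params()]), `post_vcov` (posterior covariance of `u`), and
#'   `n_obs`.
#' @export
predict_random_effects <- function(fit, newdata, check_admissible = TRUE) {
  stopifnot(inherits(fit, "si_mixed_fit"))
  if (!all(c("bh_age", "height") %in% names(newdata)))
    abort("`newdata` needs columns `bh_age` and `height`.")
  if (nrow(newdata) < 1L) abort("at least one observation is required.")
  nd <- tibble(tree_id = "new", bh_age = newdata$bh_age, height = newdata$height)
  dat1 <- .si_data(nd, min_obs = 1L)
  ctx1 <- .mixed_ctx(dat1, fit$family, fit$random_set)
  q <- ctx1$q
  L <- .cov_factor(fit$cov_re, q)
  fx <- as.list(fit$coef)
  cache <- new_environment()
  m <- .mixed_modes(ctx1, fx, L, fit$sigma2, cache, maxit = 60, tol = 1e-10)
  u <- drop(m$Z %*% t(L))
  names(u) <- paste0("u_", fit$random_set)
  # posterior covariance of z is H^-1; map to u scale
  Hz <- if (q == 1L) matrix(m$H[, "h11"], 1, 1)
        else matrix(c(m$H[1, "h11"], m$H[1, "h12"], m$H[1, "h12"], m$H[1, "h22"]), 2)
  post <- L %*% solve(Hz) %*% t(L)
  all_nm <- .si_par_names[[fit$family]]
  pv <- fit$coef
  pv[fit$random_set] <- pv[fit$random_set] + u
  params <- do.call(base_params, c(list(family = fit$family), as.list(pv)))
  if (check_admissible) {
    tr <- range(bh_age_to_t(newdata$bh_age))
    chk <- admissible_prediction_check(params, c(max(0.5, tr[1] - 0.5), tr[2] + 0.5))
    if (!chk$pass)
      abort(paste("calibrated parameters are inadmissible:",
                  paste(chk$reasons, collapse = "; ")))
  }
  list(u = u, params = params, post_vcov = post, n_obs = nrow(newdata))
}

#' Normality diagnostic for per-tree local parameter estimates
#'
#' The mixed-effects parameterization assumes the tree-level parameters are
#' normally distributed; skewed locals (typical for the HIV asymptote-like
#' parameters) violate it.  This runs a Shapiro-Wilk test on a vector of
#' local parameter estimates.
#'
#' @param values Numeric vector of local parameter values (>= 8).
#' @param alpha Significance level.
#' @return A list with `statistic`, `p_value`, `pass` (TRUE when normality
#'   is not rejected at `alpha`) and `testable` (FALSE for degenerate,
#'   constant input, in which case the other fields are `NA`).
#' @export
normality_diagnostic <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 8) abort("need at least 8 finite values.")
  if (max(values) - min(values) < 1e-12)
    return(list(statistic = NA_real_, p_value = NA_real_, pass = NA,
                testable = FALSE))
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       pass = sw$p.value > alpha, testable = TRUE)
}
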