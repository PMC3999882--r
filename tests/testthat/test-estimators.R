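test_that("linear fit reproduces closed forms and the lm() oracle", {
  d <- two_sample_data(c(0.2, 0.4, 0.5, 0.7), c(0, 0, 1, 1))
  f <- fit_linear(d)
  expect_equal(f$coef[["beta1"]], 0.3)
  expect_equal(f$coef[["beta0"]], 0.3)

  set.seed(21)
  for (i in 1:5) {
    d <- draw_two_sample(beta_scenario(0.3, 8, 0.45, 4, n0 = 17, n1 = 23))
    f <- fit_linear(d)
    o <- lm(y ~ x, data = data.frame(y = d$y, x = d$x))
    expect_equal(unname(f$coef[1:2]), unname(coef(o)), tolerance = 1e-12)
    expect_equal(f$coef[["sigma2"]], summary(o)$sigma^2, tolerance = 1e-12)
    expect_equal(unname(f$cov[1:2, 1:2]), unname(vcov(o)), tolerance = 1e-12)
    # permuting observations within groups changes nothing
    perm <- order(d$x, runif(length(d$x)))
    f2 <- fit_linear(two_sample_data(d$y[perm], d$x[perm]))
    expect_equal(f$coef, f2$coef)
  }
})

test_that("fractional logit matches group means and the linear delta exactly", {
  set.seed(31)
  for (i in 1:5) {
    d <- draw_two_sample(beta_scenario(0.1, 5, 0.2, 30, n0 = 12, n1 = 19))
    f <- fit_fraclogit(d)
    expect_true(f$converged)
    m0 <- plogis(f$coef[["beta0"]])
    m1 <- plogis(f$coef[["beta0"]] + f$coef[["beta1"]])
    expect_equal(m0, mean(d$y[d$x == 0]), tolerance = 1e-10)
    expect_equal(m1, mean(d$y[d$x == 1]), tolerance = 1e-10)
    expect_identical(effect_from_fit(f)$delta_hat,
                     m1 - m0)
    expect_equal(effect_from_fit(f)$delta_hat,
                 effect_from_fit(fit_linear(d))$delta_hat, tolerance = 1e-12)
  }
})

test_that("fractional logit sandwich equals a brute-force A^-1 M A^-1", {
  d <- tiny_data()
  f <- fit_fraclogit(d)
  X <- cbind(1, d$x)
  mu <- plogis(X %*% f$coef)
  A <- matrix(0, 2, 2); M <- matrix(0, 2, 2)
  for (i in seq_along(d$y)) {
    xi <- X[i, ]
    A <- A + (mu[i] * (1 - mu[i])) * tcrossprod(xi)
    si <- (d$y[i] - mu[i]) * xi
    M <- M + tcrossprod(si)
  }
  expect_equal(unname(f$cov), solve(A) %*% M %*% solve(A), tolerance = 1e-10)
})

test_that("constant-dispersion beta ML beats a coarse grid-search oracle", {
  set.seed(7)
  d <- draw_two_sample(beta_scenario(0.4, 6, 0.5, 6, n0 = 4, n1 = 4))
  f <- fit_beta_const(d)
  expect_true(f$converged)
  grid <- expand.grid(b0 = seq(-2, 2, by = 0.1),
                      b1 = seq(-2, 2, by = 0.1),
                      lphi = seq(-1, 4, by = 0.1))
  ll <- mapply(function(b0, b1, lphi)
    oracle_ll_const(c(b0, b1, exp(lphi)), d$y, d$x),
    grid$b0, grid$b1, grid$lphi)
  expect_gte(f$objective, max(ll) - 1e-9)
  # and the attained optimum is within one grid cell of the grid argmax
  best <- grid[which.max(ll), ]
  expect_lt(abs(f$coef[["beta0"]] - best$b0), 0.1)
  expect_lt(abs(f$coef[["beta1"]] - best$b1), 0.1)
  expect_lt(abs(log(f$coef[["phi"]]) - best$lphi), 0.1)
})

test_that("numerical score vanishes at both beta-regression optima", {
  set.seed(8)
  for (i in 1:4) {
    d <- draw_two_sample(beta_scenario(0.25, 5, 0.25, 10, n0 = 40, n1 = 40))
    fc <- fit_beta_const(d)
    gc <- fd_grad(function(p) oracle_ll_const(p, d$y, d$x), fc$coef)
    expect_lt(max(abs(gc)), 1e-6 * max(1, abs(fc$objective)))
    fv <- fit_beta_vardisp(d)
    gv <- fd_grad(function(p) oracle_ll_vardisp(p, d$y, d$x), fv$coef)
    expect_lt(max(abs(gv)), 1e-6 * max(1, abs(fv$objective)))
  }
})

test_that("intercept-only dispersion sub-model reproduces the constant fit", {
  set.seed(9)
  for (i in 1:3) {
    d <- draw_two_sample(beta_scenario(0.3, 7, 0.35, 7, n0 = 30, n1 = 30))
    fc <- fit_beta_const(d)
    f0 <- fit_beta_vardisp(d, dispersion_covariate = FALSE)
    expect_lt(abs(f0$coef[["beta0"]] - fc$coef[["beta0"]]), 1e-6)
    expect_lt(abs(f0$coef[["beta1"]] - fc$coef[["beta1"]]), 1e-6)
    expect_lt(abs(exp(f0$coef[["gamma0"]]) - fc$coef[["phi"]]), 1e-4)
    expect_equal(f0$objective, fc$objective, tolerance = 1e-9)
  }
})

test_that("variable-dispersion fit recovers group-specific dispersions", {
  sc <- beta_scenario(0.3, 5, 0.3, 10, n0 = 10000)
  d <- draw_two_sample(sc, seed = 44)
  f <- fit_beta_vardisp(d)
  expect_true(f$converged)
  expect_equal(exp(f$coef[["gamma0"]]), 5, tolerance = 0.1)
  expect_equal(exp(f$coef[["gamma0"]] + f$coef[["gamma1"]]), 10,
               tolerance = 0.1)
  # mean parameters recovered within 4 model-based se
  se <- sqrt(diag(f$cov))
  expect_lt(abs(f$coef[["beta0"]] - qlogis(0.3)), 4 * se[1])
  expect_lt(abs(plogis(f$coef[["beta0"]] + f$coef[["beta1"]]) - 0.3), 0.01)
})

test_that("misspecified constant-dispersion model displaces the effect estimate", {
  # Unequal dispersions with a common mean near the boundary: the constant-phi
  # model's delta is systematically non-zero while the correctly specified
  # variable-dispersion model stays on target.
  sc <- beta_scenario(0.05, 5, 0.05, 10, n0 = 10000)
  d <- draw_two_sample(sc, seed = 55)
  ec <- effect_from_fit(fit_beta_const(d))
  expect_gt(abs(ec$delta_hat) / ec$se, 4)
  ev <- effect_from_fit(fit_beta_vardisp(d))
  expect_lt(abs(ev$delta_hat) / ev$se, 4)
})

test_that("delta-method effect matches closed forms and a gradient oracle", {
  mk_fit <- function(coef, cov, tag = "beta_const") {
    propdiffsim:::new_fit_result(tag, coef, cov, 0, TRUE, 1L)
  }
  f0 <- mk_fit(c(beta0 = 0, beta1 = 0, phi = 5), diag(3))
  e0 <- effect_from_fit(f0)
  expect_equal(e0$delta_hat, 0)
  expect_false(e0$reject)

  f1 <- mk_fit(c(beta0 = 0, beta1 = log(3), phi = 5), diag(3))
  e1 <- effect_from_fit(f1)
  expect_equal(e1$delta_hat, 0.25)
  expect_equal(e1$se^2, (-0.0625)^2 + 0.1875^2, tolerance = 1e-12)

  # arbitrary covariance: compare against a finite-difference gradient oracle
  set.seed(12)
  A <- matrix(rnorm(16), 4)
  cov <- crossprod(A) / 10
  coef <- c(beta0 = -0.7, beta1 = 0.4, gamma0 = 1.2, gamma1 = -0.3)
  f <- mk_fit(coef, cov, tag = "beta_vardisp")
  e <- effect_from_fit(f)
  gfun <- function(p) plogis(p[1] + p[2]) - plogis(p[1])
  g <- fd_grad(gfun, coef)
  expect_equal(e$se^2, as.numeric(t(g) %*% cov %*% g), tolerance = 1e-8)
  expect_equal(e$delta_hat, unname(gfun(coef)))

  f_bad <- mk_fit(coef, cov)
  f_bad$converged <- FALSE
  expect_error(effect_from_fit(f_bad), "non-converged")
})

test_that("relabeling groups negates delta and wald for every model", {
  set.seed(13)
  for (i in 1:3) {
    d <- draw_two_sample(beta_scenario(0.2, 6, 0.35, 9, n0 = 35, n1 = 35))
    d_flip <- two_sample_data(d$y, 1 - d$x)
    for (m in model_tags()) {
      e <- effect_from_fit(fit_model(d, m))
      ef <- effect_from_fit(fit_model(d_flip, m))
      expect_equal(ef$delta_hat, -e$delta_hat, tolerance = 1e-5)
      expect_equal(abs(ef$wald), abs(e$wald), tolerance = 1e-4)
      expect_identical(ef$reject, e$reject)
    }
  }
})
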