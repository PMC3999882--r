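#' Fitted-model record
#'
#' All four fitters return a `fit_result`: the estimator tag, the ordered
#' coefficient vector, its covariance matrix, the attained
#' log-(quasi-)likelihood, and convergence bookkeeping. Coefficient order is
#' mean coefficients first (`beta0`, `beta1`), then dispersion parameters
#' (`phi` for the constant-dispersion beta model, `gamma0`/`gamma1` for the
#' variable-dispersion model, `sigma2` for the linear model).
#'
#' @param model_tag one of `"linear"`, `"beta_const"`, `"beta_vardisp"`,
#'   `"fraclogit"`.
#' @param coef named coefficient vector.
#' @param cov covariance matrix of `coef`.
#' @param objective maximized log-(quasi-)likelihood.
#' @param converged logical.
#' @param n_iter iterations used.
#' @param degenerate logical; boundary or zero-variance solution.
#' @return an object of class `fit_result`.
#' @keywords internal
new_fit_result <- function(model_tag, coef, cov, objective, converged,
                           n_iter, degenerate = FALSE) {
  dimnames(cov) <- list(names(coef), names(coef))
  structure(
    list(model_tag = model_tag, coef = coef, cov = cov,
         objective = objective, converged = converged,
         n_iter = n_iter, degenerate = degenerate),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s%s>\n", x$model_tag,
              if (!x$converged) " (NOT converged)" else ""))
  print(round(x$coef, 6))
  invisible(x)
}

model_tags <- function() c("linear", "beta_const", "beta_vardisp", "fraclogit")

as_design <- function(data) cbind(`(Intercept)` = 1, x = data$x)

#' Linear regression of a (0,1) response on the group indicator
#'
#' Ordinary least squares for the two-sample design `y = b0 + b1 x + e`.
#' The estimates are available in closed form: `b0` is the group-0 sample
#' mean and `b1` the difference of group sample means. The error variance
#' `sigma2` is the residual mean square on `n - 2` degrees of freedom and the
#' coefficient covariance is the usual OLS `sigma2 (X'X)^{-1}`.
#'
#' @param data a [two_sample_data()] object.
#' @return a `fit_result` with coefficients `(beta0, beta1, sigma2)`.
#' @export
fit_linear <- function(data) {
  stopifnot(inherits(data, "two_sample_data"))
  y0 <- data$y[data$x == 0]
  y1 <- data$y[data$x == 1]
  n0 <- data$n0; n1 <- data$n1; n <- n0 + n1
  b0 <- mean(y0)
  b1 <- mean(y1) - mean(y0)
  rss <- sum((y0 - mean(y0))^2) + sum((y1 - mean(y1))^2)
  sigma2 <- rss / (n - 2)
  cov <- matrix(0, 3, 3)
  cov[1, 1] <- sigma2 / n0
  cov[1, 2] <- cov[2, 1] <- -sigma2 / n0
  cov[2, 2] <- sigma2 * (1 / n0 + 1 / n1)
  cov[3, 3] <- 2 * sigma2^2 / (n - 2) # exact under normal errors
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1) # Gaussian profile log-likelihood
  new_fit_result("linear",
                 c(beta0 = b0, beta1 = b1, sigma2 = sigma2), cov, ll,
                 converged = TRUE, n_iter = 0L,
                 degenerate = sigma2 <= 0)
}

# --- beta regression log-likelihoods -------------------------------------
#
# Mean-dispersion beta log-likelihood with logit mean link. `phi` may be a
# scalar (constant dispersion) or a per-observation vector (variable
# dispersion with a log-linked sub-model).

beta_loglik <- function(y, mu, phi) {
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

# Score contributions shared by both beta fitters.
# d LL / d mu_i  = phi_i * (ystar_i - mustar_i)
# d LL / d phi_i = digamma(phi_i) - mu digamma(mu phi_i)
#                  - (1-mu) digamma((1-mu) phi_i) + mu log y + (1-mu) log(1-y)
beta_score_parts <- function(y, mu, phi) {
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dmu <- phi * (ystar - mustar)
  dphi <- digamma(phi) - mu * digamma(mu * phi) -
    (1 - mu) * digamma((1 - mu) * phi) +
    mu * log(y) + (1 - mu) * log1p(-y)
  list(dmu = dmu, dphi = dphi)
}

# Method-of-moments dispersion from pooled within-group moments,
# phi = mu(1-mu)/s^2 - 1, floored away from zero.
phi_moment_start <- function(data) {
  y0 <- data$y[data$x == 0]; y1 <- data$y[data$x == 1]
  s2 <- (sum((y0 - mean(y0))^2) + sum((y1 - mean(y1))^2)) /
    max(length(y0) + length(y1) - 2, 1)
  mu <- mean(data$y)
  max(mu * (1 - mu) / max(s2, 1e-10) - 1, 0.1)
}

logit_ls_start <- function(data) {
  y0 <- data$y[data$x == 0]; y1 <- data$y[data$x == 1]
  eta0 <- stats::qlogis(mean(y0))
  eta1 <- stats::qlogis(mean(y1))
  c(eta0, eta1 - eta0)
}

# Inverse observed information at the optimum via a numerical Hessian of the
# log-likelihood (finite differences of the analytic gradient). Returns NULL
# when the information matrix is not positive definite.
observed_info_cov <- function(par, negll, neggr) {
  H <- try(stats::optimHess(par, fn = negll, gr = neggr), silent = TRUE)
  if (inherits(H, "try-error")) return(NULL)
  H <- (H + t(H)) / 2
  cov <- try(solve(H), silent = TRUE)
  if (inherits(cov, "try-error")) return(NULL)
  if (any(!is.finite(cov)) || any(diag(cov) <= 0)) return(NULL)
  (cov + t(cov)) / 2
}

maximize_with_restarts <- function(start, negll, neggr, lower = NULL,
                                   n_restarts = 3L, seed_jitter = 1L) {
  method <- if (is.null(lower)) "BFGS" else "L-BFGS-B"
  best <- NULL
  par <- start
  for (attempt in 0:n_restarts) {
    if (attempt > 0) {
      # deterministic jitter so refits are reproducible
      jit <- sin(seq_along(start) * 7.3 + attempt * 2.1 + seed_jitter) * 0.5
      par <- start + jit
      if (!is.null(lower)) par <- pmax(par, lower + 0.05)
    }
    fit <- try(
      if (is.null(lower)) {
        stats::optim(par, fn = negll, gr = neggr, method = method,
                     control = list(maxit = 500, reltol = 1e-12))
      } else {
        stats::optim(par, fn = negll, gr = neggr, method = method,
                     lower = lower,
                     control = list(maxit = 500, factr = 1e4))
      },
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ok <- fit$convergence == 0 && all(is.finite(fit$par))
    if (ok && (is.null(best) || fit$value < best$value)) {
      best <- fit
      break
    }
    if (is.null(best) && all(is.finite(fit$par))) best <- fit
  }
  best
}

#' Constant-dispersion beta regression
#'
#' Maximum likelihood for the beta regression model with logit mean link,
#' `logit(mu_i) = b0 + b1 x_i`, and a single dispersion parameter `phi`
#' common to all observations, kept on the identity scale with a positivity
#' bound. The covariance matrix is the inverse observed information
#' (numerical Hessian of the log-likelihood at the optimum).
#'
#' @param data a [two_sample_data()] object; all responses strictly in (0,1).
#' @param start optional numeric start `(beta0, beta1, phi)`; defaults to
#'   least squares on the logit scale plus a method-of-moments `phi`.
#' @return a `fit_result` with coefficients `(beta0, beta1, phi)`.
#' @export
fit_beta_const <- function(data, start = NULL) {
  stopifnot(inherits(data, "two_sample_data"))
  y <- data$y
  X <- as_design(data)
  phi_min <- 1e-4
  if (is.null(start)) start <- c(logit_ls_start(data), phi_moment_start(data))

  negll <- function(par) {
    mu <- stats::plogis(X %*% par[1:2])
    -beta_loglik(y, mu, par[3])
  }
  neggr <- function(par) {
    mu <- as.vector(stats::plogis(X %*% par[1:2]))
    sp <- beta_score_parts(y, mu, par[3])
    gb <- crossprod(X, sp$dmu * mu * (1 - mu))
    -c(gb, sum(sp$dphi))
  }

  opt <- maximize_with_restarts(start, negll, neggr,
                                lower = c(-Inf, -Inf, phi_min))
  if (is.null(opt)) {
    return(new_fit_result("beta_const",
                          c(beta0 = NA_real_, beta1 = NA_real_, phi = NA_real_),
                          matrix(NA_real_, 3, 3), NA_real_,
                          converged = FALSE, n_iter = 0L))
  }
  coef <- c(beta0 = opt$par[1], beta1 = opt$par[2], phi = opt$par[3])
  cov <- observed_info_cov(opt$par, negll, neggr)
  converged <- opt$convergence == 0 && !is.null(cov)
  if (is.null(cov)) cov <- matrix(NA_real_, 3, 3)
  new_fit_result("beta_const", coef, cov, -opt$value,
                 converged = converged,
                 n_iter = opt$counts[["function"]],
                 degenerate = coef[["phi"]] <= phi_min * 2)
}

#' Variable-dispersion beta regression
#'
#' Maximum likelihood for the double-index beta regression model: the mean
#' follows `logit(mu_i) = b0 + b1 x_i` and the dispersion its own sub-model
#' `log(phi_i) = g0 + g1 x_i`. The covariance matrix is the inverse observed
#' information of the full four-parameter likelihood (including the
#' mean-dispersion cross blocks).
#'
#' @inheritParams fit_beta_const
#' @param start optional start `(beta0, beta1, gamma0, gamma1)` (or
#'   `(beta0, beta1, gamma0)` when `dispersion_covariate = FALSE`).
#' @param dispersion_covariate include the group indicator in the dispersion
#'   sub-model? `FALSE` restricts it to an intercept, which reproduces the
#'   constant-dispersion fit with `phi = exp(gamma0)`.
#' @return a `fit_result` with coefficients `(beta0, beta1, gamma0, gamma1)`.
#' @export
fit_beta_vardisp <- function(data, start = NULL, dispersion_covariate = TRUE) {
  stopifnot(inherits(data, "two_sample_data"))
  y <- data$y
  X <- as_design(data)
  Z <- if (dispersion_covariate) X else X[, 1, drop = FALSE]
  k <- 2L + ncol(Z)
  zi <- 3:k
  if (is.null(start)) {
    start <- c(logit_ls_start(data), log(phi_moment_start(data)),
               if (dispersion_covariate) 0)
  }

  negll <- function(par) {
    mu <- stats::plogis(X %*% par[1:2])
    phi <- exp(Z %*% par[zi])
    -beta_loglik(y, mu, phi)
  }
  neggr <- function(par) {
    mu <- as.vector(stats::plogis(X %*% par[1:2]))
    phi <- as.vector(exp(Z %*% par[zi]))
    sp <- beta_score_parts(y, mu, phi)
    gb <- crossprod(X, sp$dmu * mu * (1 - mu))
    gg <- crossprod(Z, sp$dphi * phi) # log link: d phi / d zeta = phi
    -c(gb, gg)
  }

  opt <- maximize_with_restarts(start, negll, neggr)
  nm <- c("beta0", "beta1", "gamma0", if (dispersion_covariate) "gamma1")
  if (is.null(opt)) {
    coef <- stats::setNames(rep(NA_real_, k), nm)
    return(new_fit_result("beta_vardisp", coef, matrix(NA_real_, k, k),
                          NA_real_, converged = FALSE, n_iter = 0L))
  }
  coef <- stats::setNames(opt$par, nm)
  cov <- observed_info_cov(opt$par, negll, neggr)
  converged <- opt$convergence == 0 && !is.null(cov)
  if (is.null(cov)) cov <- matrix(NA_real_, k, k)
  new_fit_result("beta_vardisp", coef, cov, -opt$value,
                 converged = converged,
                 n_iter = opt$counts[["function"]])
}

#' Fractional logit regression with sandwich covariance
#'
#' Quasi-parametric estimator for (0,1) responses assuming only a logistic
#' conditional mean, `E(Y|x) = expit(b0 + b1 x)`. Coefficients maximize the
#' Bernoulli quasi-log-likelihood `sum(y log(mu) + (1-y) log(1-mu))` by
#' Newton iteration (for the logit link the observed and expected Hessians
#' coincide, `-X' diag(mu(1-mu)) X`). The covariance is the robust sandwich
#' `A^{-1} M A^{-1}` with `A` the negative expected Hessian and `M` the sum
#' of outer products of per-observation scores, both at the estimate.
#'
#' @inheritParams fit_beta_const
#' @return a `fit_result` with coefficients `(beta0, beta1)`.
#' @export
fit_fraclogit <- function(data) {
  stopifnot(inherits(data, "two_sample_data"))
  y <- data$y
  X <- as_design(data)
  b <- c(0, 0)
  n_iter <- 0L
  converged <- FALSE
  for (it in 1:50) {
    mu <- as.vector(stats::plogis(X %*% b))
    score <- crossprod(X, y - mu)
    A <- crossprod(X, X * (mu * (1 - mu)))
    step <- solve(A, score)
    b <- b + as.vector(step)
    n_iter <- it
    if (max(abs(score)) < 1e-10 || max(abs(step)) < 1e-12) {
      converged <- TRUE
      break
    }
  }
  mu <- as.vector(stats::plogis(X %*% b))
  A <- crossprod(X, X * (mu * (1 - mu)))
  resid <- y - mu
  M <- crossprod(X, X * resid^2)
  Ainv <- solve(A)
  cov <- Ainv %*% M %*% Ainv
  cov <- (cov + t(cov)) / 2
  qll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  new_fit_result("fraclogit", c(beta0 = b[1], beta1 = b[2]), cov, qll,
                 converged = converged, n_iter = n_iter)
}

#' Fit one of the four models by tag
#'
#' @param data a [two_sample_data()].
#' @param model one of [model_tags()].
#' @return a `fit_result`.
#' @export
fit_model <- function(data, model = model_tags()) {
  model <- match.arg(model)
  switch(model,
         linear = fit_linear(data),
         beta_const = fit_beta_const(data),
         beta_vardisp = fit_beta_vardisp(data),
         fraclogit = fit_fraclogit(data))
}
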