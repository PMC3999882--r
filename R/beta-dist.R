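#' Beta distribution in the mean-dispersion parameterization
#'
#' A beta random variable is usually written in terms of its two shape
#' parameters \eqn{(p, q)}. For regression modelling it is more convenient to
#' index the distribution by its mean \eqn{\mu = p/(p+q)} and a precision-like
#' dispersion parameter \eqn{\phi = p + q}, so that
#' \eqn{p = \mu\phi} and \eqn{q = (1-\mu)\phi}, with
#' \eqn{E(Y) = \mu} and \eqn{Var(Y) = \mu(1-\mu)/(1+\phi)}.
#' At fixed mean, larger \eqn{\phi} means smaller variance.
#'
#' @param mu mean, in (0, 1).
#' @param phi dispersion (precision), strictly positive.
#' @return `beta_shapes()` returns a named numeric vector `c(p, q)`;
#'   `beta_mean_disp()` the inverse map `c(mu, phi)`;
#'   `beta_moments()` a named numeric vector `c(mean, variance)`.
#' @examples
#' beta_shapes(0.25, 5)    # p = 1.25, q = 3.75
#' beta_moments(0.5, 5)    # variance = 0.25/6
#' @export
beta_shapes <- function(mu, phi) {
  stopifnot(is.numeric(mu), is.numeric(phi))
  if (any(mu <= 0 | mu >= 1)) {
    stop("`mu` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(phi <= 0)) {
    stop("`phi` must be strictly positive", call. = FALSE)
  }
  c(p = mu * phi, q = (1 - mu) * phi)
}

#' @param p,q beta shape parameters, strictly positive.
#' @rdname beta_shapes
#' @export
beta_mean_disp <- function(p, q) {
  if (any(p <= 0) || any(q <= 0)) {
    stop("shape parameters must be strictly positive", call. = FALSE)
  }
  c(mu = p / (p + q), phi = p + q)
}

#' @rdname beta_shapes
#' @export
beta_moments <- function(mu, phi) {
  beta_shapes(mu, phi) # validates
  c(mean = mu, variance = mu * (1 - mu) / (1 + phi))
}

#' Beta density indexed by mean and dispersion
#'
#' Density of the beta distribution with mean `mu` and dispersion `phi`,
#' i.e. shapes `mu * phi` and `(1 - mu) * phi`. Evaluates to zero nowhere on
#' its support; values of `y` outside the open interval (0,1) are an error
#' because every likelihood in this package requires interior responses.
#'
#' @param y evaluation points, each in (0, 1).
#' @inheritParams beta_shapes
#' @param log logical; return log-density?
#' @return numeric vector of (log-)density values.
#' @export
dbeta_mu_phi <- function(y, mu, phi, log = FALSE) {
  if (any(y <= 0 | y >= 1)) {
    stop("`y` must lie strictly inside (0, 1)", call. = FALSE)
  }
  s <- beta_shapes(mu, phi)
  stats::dbeta(y, shape1 = s[["p"]], shape2 = s[["q"]], log = log)
}
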