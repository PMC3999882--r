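#' Derive a per-replication substream seed
#'
#' Each replication of an experiment draws its data from an independent
#' substream so that any single replication is reproducible in isolation.
#' The substream seed is a deterministic 31-bit mix of the master seed and
#' the replication index (a Lehmer-style multiplicative mix; not
#' cryptographic, but collision-free across the replication counts used
#' here for any fixed master seed).
#'
#' @param seed master seed (integer).
#' @param index replication index (positive integer); `0` addresses the
#'   experiment-level stream itself.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.double(seed)) %% m)
  s <- (s * 48271 + as.double(index) * 16807 + 1) %% m
  # one more mixing round so adjacent (seed, index) pairs decorrelate
  s <- (s * 69621) %% m
  as.integer(s + (s == 0))
}

clamp_open_unit <- function(y) {
  eps <- .Machine$double.eps
  n_clamped <- sum(y <= 0 | y >= 1)
  if (n_clamped > 0) {
    y <- pmin(pmax(y, eps), 1 - eps)
  }
  attr(y, "n_clamped") <- n_clamped
  y
}

#' Draw one two-sample dataset from a scenario
#'
#' `draw_two_sample()` dispatches on the scenario class;
#' `draw_beta_two_sample()` and `draw_multinomial_two_sample()` are the
#' explicit entry points. Group 0 observations come first, then group 1.
#' A seed always produces the identical dataset.
#'
#' Beta draws that underflow to exactly 0 or 1 in double precision (possible
#' only for extreme shape parameters) are clamped into the open interval at
#' one machine epsilon from the boundary, because every likelihood here
#' requires interior responses; the number of clamped values is recorded in
#' the `"n_clamped"` attribute of the returned object.
#'
#' @param scenario a [beta_scenario()] or [multinomial_scenario()].
#' @param seed integer seed for this draw (use [substream_seed()] to derive
#'   per-replication seeds from a master seed). `NULL` uses the current RNG
#'   state.
#' @return a [two_sample_data()] object.
#' @export
draw_two_sample <- function(scenario, seed = NULL) {
  UseMethod("draw_two_sample")
}

#' @rdname draw_two_sample
#' @export
draw_two_sample.beta_scenario <- function(scenario, seed = NULL) {
  draw_beta_two_sample(scenario, seed)
}

#' @rdname draw_two_sample
#' @export
draw_two_sample.multinomial_scenario <- function(scenario, seed = NULL) {
  draw_multinomial_two_sample(scenario, seed)
}

#' @rdname draw_two_sample
#' @export
draw_beta_two_sample <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "beta_scenario"))
  if (!is.null(seed)) set.seed(seed)
  s0 <- beta_shapes(scenario$mu0, scenario$phi0)
  s1 <- beta_shapes(scenario$mu1, scenario$phi1)
  y0 <- stats::rbeta(scenario$n0, s0[["p"]], s0[["q"]])
  y1 <- stats::rbeta(scenario$n1, s1[["p"]], s1[["q"]])
  y <- clamp_open_unit(c(y0, y1))
  out <- two_sample_data(y, rep(c(0, 1), c(scenario$n0, scenario$n1)))
  attr(out, "n_clamped") <- attr(y, "n_clamped")
  out
}

#' @rdname draw_two_sample
#' @export
draw_multinomial_two_sample <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "multinomial_scenario"))
  if (!is.null(seed)) set.seed(seed)
  y0 <- sample(scenario$support, scenario$n0, replace = TRUE,
               prob = scenario$probs0)
  y1 <- sample(scenario$support, scenario$n1, replace = TRUE,
               prob = scenario$probs1)
  out <- two_sample_data(c(y0, y1),
                         rep(c(0, 1), c(scenario$n0, scenario$n1)))
  attr(out, "n_clamped") <- 0L
  out
}
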