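# Shared fixtures built in code at test time.

# Tiny fixed dataset: 3 observations per group, all interior.
tiny_data <- function() {
  two_sample_data(y = c(0.2, 0.4, 0.35, 0.5, 0.7, 0.55),
                  x = c(0, 0, 0, 1, 1, 1))
}

# The two Table-2-style probability vectors used throughout.
sym_probs <- function() c(0, 0.025, 0.025, 0.15, 0.30, 0.30, 0.15, 0.025, 0.025, 0)
asym_probs <- function() c(0.40, 0.20, 0.10, 0.10, 0.10, 0.05, 0.05, 0, 0, 0)

# Central-difference gradient of f at x.
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Log-likelihood functions written independently of the package internals
# (straight from dbeta), used as oracles for the fitters.
oracle_ll_const <- function(par, y, x) {
  mu <- plogis(par[1] + par[2] * x)
  sum(dbeta(y, mu * par[3], (1 - mu) * par[3], log = TRUE))
}
oracle_ll_vardisp <- function(par, y, x) {
  mu <- plogis(par[1] + par[2] * x)
  phi <- exp(par[3] + par[4] * x)
  sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}
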