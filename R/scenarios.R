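#' Two-sample response data on the open unit interval
#'
#' Container for a single simulated (or observed) dataset: a response vector
#' `y` with every element strictly inside (0,1) and an aligned binary group
#' indicator `x` (0 = reference group, 1 = comparison group).
#'
#' @param y numeric responses, each in (0, 1).
#' @param x integer/numeric group indicator of the same length, values 0/1.
#' @return an object of class `two_sample_data`: a list with elements `y`,
#'   `x`, `n0`, `n1`.
#' @export
two_sample_data <- function(y, x) {
  if (length(y) != length(x)) {
    stop("`y` and `x` must have the same length", call. = FALSE)
  }
  if (any(y <= 0 | y >= 1)) {
    stop("all responses must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!all(x %in% c(0, 1))) {
    stop("`x` must be a 0/1 group indicator", call. = FALSE)
  }
  n0 <- sum(x == 0)
  n1 <- sum(x == 1)
  if (n0 == 0L || n1 == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  structure(list(y = as.numeric(y), x = as.numeric(x), n0 = n0, n1 = n1),
            class = "two_sample_data")
}

#' @export
print.two_sample_data <- function(x, ...) {
  cat(sprintf("<two_sample_data: n0 = %d, n1 = %d>\n", x$n0, x$n1))
  invisible(x)
}

#' Two-sample beta sampling scenario
#'
#' Describes one cell of the beta-response simulation design: group-specific
#' means and dispersions plus per-group sample sizes. The true average
#' proportion difference is `mu1 - mu0` and is derived, never stored
#' independently.
#'
#' @param mu0,phi0 mean and dispersion in group 0.
#' @param mu1,phi1 mean and dispersion in group 1.
#' @param n0,n1 per-group sample sizes (positive integers).
#' @return an object of class `c("beta_scenario", "sampling_scenario")`.
#' @export
beta_scenario <- function(mu0, phi0, mu1, phi1, n0, n1 = n0) {
  beta_shapes(mu0, phi0) # validates the (mu, phi) pairs
  beta_shapes(mu1, phi1)
  n0 <- check_count(n0, "n0")
  n1 <- check_count(n1, "n1")
  structure(
    list(mu0 = mu0, phi0 = phi0, mu1 = mu1, phi1 = phi1,
         n0 = n0, n1 = n1, true_delta = mu1 - mu0),
    class = c("beta_scenario", "sampling_scenario")
  )
}

#' Two-sample discrete multinomial sampling scenario
#'
#' Responses take values on a fixed grid of support points inside (0,1)
#' (default `{0.05, 0.15, ..., 0.95}`), with a separate probability vector in
#' each group. The true effect is the difference of the group means
#' `sum(support * probs1) - sum(support * probs0)`.
#'
#' @param probs0,probs1 per-group probability vectors over `support`; each
#'   must be non-negative and sum to 1 (tolerance 1e-8).
#' @param n0,n1 per-group sample sizes.
#' @param support strictly increasing points in (0,1).
#' @return an object of class `c("multinomial_scenario", "sampling_scenario")`.
#' @export
multinomial_scenario <- function(probs0, probs1, n0, n1 = n0,
                                 support = seq(0.05, 0.95, by = 0.10)) {
  if (any(support <= 0 | support >= 1) || is.unsorted(support, strictly = TRUE)) {
    stop("`support` must be strictly increasing points inside (0, 1)",
         call. = FALSE)
  }
  for (pr in list(probs0, probs1)) {
    if (length(pr) != length(support) || any(pr < 0)) {
      stop("probability vectors must be non-negative and match the support",
           call. = FALSE)
    }
    if (abs(sum(pr) - 1) > 1e-8) {
      stop("probability vectors must sum to 1", call. = FALSE)
    }
  }
  n0 <- check_count(n0, "n0")
  n1 <- check_count(n1, "n1")
  structure(
    list(support = support, probs0 = probs0, probs1 = probs1,
         n0 = n0, n1 = n1,
         mean0 = sum(support * probs0), mean1 = sum(support * probs1),
         true_delta = sum(support * (probs1 - probs0))),
    class = c("multinomial_scenario", "sampling_scenario")
  )
}

check_count <- function(n, name) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  as.integer(n)
}

#' @export
print.beta_scenario <- function(x, ...) {
  cat(sprintf(
    "<beta_scenario: mu0 = %g, phi0 = %g | mu1 = %g, phi1 = %g; n = (%d, %d); delta = %g>\n",
    x$mu0, x$phi0, x$mu1, x$phi1, x$n0, x$n1, x$true_delta))
  invisible(x)
}

#' @export
print.multinomial_scenario <- function(x, ...) {
  cat(sprintf(
    "<multinomial_scenario: E(Y0) = %g, E(Y1) = %g; n = (%d, %d); delta = %g>\n",
    x$mean0, x$mean1, x$n0, x$n1, x$true_delta))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Built-in scenario registries
#
# The shipped simulation design has two registries. Registry 1 holds 24
# beta-response rows: 12 null rows (equal group means; the second half of
# each block doubles the dispersion in group 1) and 12 power rows where the
# group-1 mean is shifted by +0.025. Registry 2 holds 4 multinomial rows:
# a symmetric and an asymmetric null vector, and their power counterparts
# where the group-1 vector is the group-0 vector shifted one support point
# upward (a mean shift of +0.10).

beta_grid_rows <- function() {
  null <- expand.grid(phi_pair = 1:2, phi_base = c(5, 100), mu = c(0.50, 0.25, 0.05))
  rows <- lapply(seq_len(nrow(null)), function(i) {
    mu <- null$mu[i]; phi0 <- null$phi_base[i]
    phi1 <- if (null$phi_pair[i] == 1) phi0 else 2 * phi0
    list(mu0 = mu, phi0 = phi0, mu1 = mu, phi1 = phi1)
  })
  power <- lapply(rows, function(r) {
    r$mu1 <- r$mu0 + 0.025
    r
  })
  c(rows, power)
}

multinomial_grid_rows <- function() {
  sym <- c(0, 0.025, 0.025, 0.15, 0.30, 0.30, 0.15, 0.025, 0.025, 0)
  asym <- c(0.40, 0.20, 0.10, 0.10, 0.10, 0.05, 0.05, 0, 0, 0)
  shift1 <- function(p) c(0, p[-length(p)]) # move all mass one support point up
  list(
    list(probs0 = sym,  probs1 = sym),
    list(probs0 = asym, probs1 = asym),
    list(probs0 = sym,  probs1 = shift1(sym)),
    list(probs0 = asym, probs1 = shift1(asym))
  )
}

#' Look up one row of the built-in scenario registries
#'
#' @param table 1 for the beta-response design (24 rows: 1-12 null, 13-24
#'   power), 2 for the multinomial design (4 rows: 1-2 null, 3-4 power).
#' @param row row index within the table.
#' @param n per-group sample size; the shipped designs use
#'   `c(25, 100, 250, 750)` but any positive integer is accepted.
#' @return a `sampling_scenario`.
#' @export
registry_scenario <- function(table, row, n) {
  if (table == 1) {
    rows <- beta_grid_rows()
    if (row < 1 || row > length(rows)) {
      stop(sprintf("table 1 has rows 1..%d", length(rows)), call. = FALSE)
    }
    r <- rows[[row]]
    beta_scenario(r$mu0, r$phi0, r$mu1, r$phi1, n0 = n)
  } else if (table == 2) {
    rows <- multinomial_grid_rows()
    if (row < 1 || row > length(rows)) {
      stop(sprintf("table 2 has rows 1..%d", length(rows)), call. = FALSE)
    }
    r <- rows[[row]]
    multinomial_scenario(r$probs0, r$probs1, n0 = n)
  } else {
    stop("`table` must be 1 (beta design) or 2 (multinomial design)",
         call. = FALSE)
  }
}

#' Number of rows in a scenario registry
#' @inheritParams registry_scenario
#' @export
registry_size <- function(table) {
  switch(as.character(table),
         "1" = length(beta_grid_rows()),
         "2" = length(multinomial_grid_rows()),
         stop("`table` must be 1 or 2", call. = FALSE))
}

#' Default per-group sample sizes of the shipped designs
#' @export
default_sample_sizes <- function() c(25L, 100L, 250L, 750L)
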