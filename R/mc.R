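#' Configure a Monte Carlo experiment
#'
#' One experiment is a scenario replicated `reps` times; each replication
#' draws a fresh dataset from its own substream (see [substream_seed()]),
#' fits the requested models, and records the delta-method inference.
#'
#' @param scenario a [beta_scenario()] or [multinomial_scenario()].
#' @param reps number of replications (>= 2; the shipped experiments use
#'   20000).
#' @param seed master seed for the experiment.
#' @param models character subset of [model_tags()].
#' @param alpha two-sided significance level (default 0.05, tested with the
#'   fixed 1.96 critical value).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(scenario, reps = 20000L, seed = 1L,
                              models = model_tags(), alpha = 0.05) {
  stopifnot(inherits(scenario, "sampling_scenario"))
  reps <- check_count(reps, "reps")
  if (reps < 2L) stop("`reps` must be at least 2", call. = FALSE)
  models <- match.arg(models, model_tags(), several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  structure(
    list(scenario = scenario, reps = reps, seed = as.integer(seed),
         models = models, alpha = alpha),
    class = "experiment_config"
  )
}

#' Run a single replication of an experiment
#'
#' Deterministic given `(config$seed, index)`: the replication draws its
#' dataset from substream `index` and fits every requested model. Fit
#' failures are recorded (`converged = FALSE`) with `NA` inference fields
#' rather than raised.
#'
#' @param config an [experiment_config()].
#' @param index replication index (1-based).
#' @return a data.frame with one row per model: `model`, `delta_hat`,
#'   `var_model` (delta-method variance), `reject`, `converged`.
#' @export
run_replication <- function(config, index) {
  stopifnot(inherits(config, "experiment_config"))
  data <- draw_two_sample(config$scenario,
                          seed = substream_seed(config$seed, index))
  rows <- lapply(config$models, function(m) {
    fit <- try(fit_model(data, m), silent = TRUE)
    if (!inherits(fit, "try-error") && isTRUE(fit$converged)) {
      eff <- effect_from_fit(fit, alpha = config$alpha)
      data.frame(model = m, delta_hat = eff$delta_hat,
                 var_model = eff$se^2, reject = eff$reject,
                 converged = TRUE)
    } else {
      data.frame(model = m, delta_hat = NA_real_, var_model = NA_real_,
                 reject = NA, converged = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$replication <- index
  out
}

#' Monte Carlo errors of bias, variance and rejection-rate estimates
#'
#' Standard simulation-study error formulas: the MC error of the bias is
#' `sd(delta_hat)/sqrt(R)`; the MC error of the empirical variance `s^2` is
#' `s^2 * sqrt(2/(R-1))` (exact under normality of the estimator); the MC
#' error of a rejection rate `r` is the binomial `sqrt(r(1-r)/R)`.
#'
#' @param estimates numeric vector of per-replication effect estimates.
#' @param rejections logical vector of per-replication rejections.
#' @param reps number of replications contributing (defaults to
#'   `length(estimates)`).
#' @return named numeric vector `c(mce_bias, mce_variance, mce_rejection)`.
#' @export
mc_errors <- function(estimates, rejections, reps = length(estimates)) {
  if (reps < 2) stop("at least 2 replications are required", call. = FALSE)
  s2 <- stats::var(estimates)
  r <- mean(rejections)
  c(mce_bias = sqrt(s2 / reps),
    mce_variance = s2 * sqrt(2 / (reps - 1)),
    mce_rejection = sqrt(r * (1 - r) / reps))
}

scenario_id_fields <- function(scenario, n_label = NULL) {
  if (inherits(scenario, "beta_scenario")) {
    data.frame(n = scenario$n0, mu0 = scenario$mu0, phi0 = scenario$phi0,
               mu1 = scenario$mu1, phi1 = scenario$phi1,
               true_delta = scenario$true_delta)
  } else {
    data.frame(n = scenario$n0, ey0 = scenario$mean0, ey1 = scenario$mean1,
               true_delta = scenario$true_delta)
  }
}

#' Run a full Monte Carlo experiment and summarize it
#'
#' Executes all replications of `config` and aggregates, per model:
#' bias (`mean(delta_hat) - true_delta`), the empirical variance of
#' `delta_hat` across replications, the rejection rate, the corresponding
#' Monte Carlo errors (see [mc_errors()]), the mean delta-method
#' (model-based) variance as a diagnostic, and the number of excluded
#' (non-converged) replications. Aggregates use converged replications only.
#'
#' @param config an [experiment_config()].
#' @return a data.frame (class `mc_summary`) with one row per model;
#'   scenario identifier columns are repeated on every row.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  recs <- lapply(seq_len(config$reps), function(r) run_replication(config, r))
  recs <- do.call(rbind, recs)
  summarize_replications(recs, config)
}

#' @rdname run_experiment
#' @param records stacked [run_replication()] output for all replications.
#' @export
summarize_replications <- function(records, config) {
  scen <- config$scenario
  id <- scenario_id_fields(scen)
  rows <- lapply(config$models, function(m) {
    rec <- records[records$model == m, ]
    ok <- rec[rec$converged, ]
    n_excluded <- nrow(rec) - nrow(ok)
    if (nrow(ok) < 2) {
      out <- data.frame(model = m, reps_used = nrow(ok),
                        n_excluded = n_excluded,
                        bias = NA_real_, mce_bias = NA_real_,
                        variance = NA_real_, mce_variance = NA_real_,
                        rejection_rate = NA_real_, mce_rejection = NA_real_,
                        mean_model_variance = NA_real_)
      return(cbind(id, out))
    }
    mce <- mc_errors(ok$delta_hat, ok$reject, reps = nrow(ok))
    out <- data.frame(
      model = m, reps_used = nrow(ok), n_excluded = n_excluded,
      bias = mean(ok$delta_hat) - scen$true_delta,
      mce_bias = mce[["mce_bias"]],
      variance = stats::var(ok$delta_hat),
      mce_variance = mce[["mce_variance"]],
      rejection_rate = mean(ok$reject),
      mce_rejection = mce[["mce_rejection"]],
      mean_model_variance = mean(ok$var_model))
    cbind(id, out)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mc_summary", class(out))
  out
}

#' Enumerate the shipped experiment grids
#'
#' Expands a scenario registry into one [experiment_config()] per
#' (row, sample size) combination: registry 1 gives 24 scenarios x 4 sizes =
#' 96 configs, registry 2 gives 4 x 4 = 16.
#'
#' @param table_id 1 (beta design) or 2 (multinomial design).
#' @param reps replications per experiment.
#' @param seed master seed; each config gets its own experiment-level
#'   substream derived from `(seed, row, n)` so experiments are independent.
#' @param sizes per-group sample sizes (default the shipped
#'   `c(25, 100, 250, 750)`).
#' @param models,alpha passed through to [experiment_config()].
#' @return a list of `experiment_config` objects, with attributes `table`
#'   and `row`/`n` stored on each element.
#' @export
scenario_grid <- function(table_id, reps = 20000L, seed = 1L,
                          sizes = default_sample_sizes(),
                          models = model_tags(), alpha = 0.05) {
  n_rows <- registry_size(table_id) # validates table_id
  configs <- list()
  for (row in seq_len(n_rows)) {
    for (n in sizes) {
      cfg <- experiment_config(
        registry_scenario(table_id, row, n),
        reps = reps,
        seed = substream_seed(seed, row * 10000L + as.integer(n)),
        models = models, alpha = alpha)
      cfg$table <- as.integer(table_id)
      cfg$row <- as.integer(row)
      configs[[length(configs) + 1L]] <- cfg
    }
  }
  configs
}
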