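#' Load and write experiment configurations
#'
#' Declarative YAML configurations with sections `neuron`, `pool`,
#' `synchrony`, `estimator` and top-level `seed`/`horizon_ms`.  The
#' synchrony section carries a `kind` tag (`asynchronous`, `beta_binomial`,
#' `shared_inputs`, `cross_mixture`) plus kind-specific parameters; units
#' are ms, mV and Hz throughout.  `load_config()` validates the schema and
#' materializes the package objects.
#'
#' @param path Path to a YAML configuration.
#' @return `load_config()`: a list with elements `neuron`
#'   ([neuron_params()]), `pool` ([input_pool()]), `model`
#'   (`synchrony_model`), `estimator` ([estimator_config()]), `horizon_ms`,
#'   `seed`, `extra` (unrecognized sections such as jitter settings).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- function(sec, keys) {
    if (is.null(raw[[sec]])) stop(sprintf("config: missing section '%s'", sec))
    miss <- setdiff(keys, names(raw[[sec]]))
    if (length(miss))
      stop(sprintf("config: section '%s' is missing key(s) %s",
                   sec, paste(miss, collapse = ", ")))
    raw[[sec]]
  }
  nrn <- need("neuron", c("tau", "v_exc", "v_inh"))
  neuron <- neuron_params(tau = nrn$tau, v_exc = nrn$v_exc, v_inh = nrn$v_inh,
                          i_ext_over_g = nrn$i_ext_over_g %||% 0,
                          epsilon = nrn$epsilon %||% 0)
  pl <- need("pool", c("n_exc"))
  pool <- input_pool(n_exc = pl$n_exc, n_inh = pl$n_inh %||% 0,
                     rate_exc = pl$rate_exc %||% 0,
                     rate_inh = pl$rate_inh %||% 0,
                     w_exc = pl$w_exc %||% 0, w_inh = pl$w_inh %||% 0)
  sy <- need("synchrony", "kind")
  model <- switch(sy$kind,
    asynchronous = sync_asynchronous(pool),
    beta_binomial = sync_beta_binomial(pool, rho_e = sy$rho_e %||% 0,
                                       rho_i = sy$rho_i %||% 0,
                                       rho_ei = sy$rho_ei %||% 0),
    shared_inputs = sync_shared_inputs(pool, f_e = sy$f_e %||% 0,
                                       f_i = sy$f_i %||% 0),
    cross_mixture = calibrate_cross_neuron(pool, rho = sy$rho,
                                           rho_cross = sy$rho_cross,
                                           structure = sy$structure %||% "within_pool"),
    stop(sprintf("config: unknown synchrony kind '%s'", sy$kind)))
  if (!is.null(sy$failure_p) && sy$failure_p < 1)
    model <- apply_synaptic_failure(model, sy$failure_p)
  es <- raw$estimator %||% list()
  estimator <- estimator_config(burn_in_ms = es$burn_in_ms %||% (20 * neuron$tau),
                                batches = es$batches %||% 50L,
                                bootstrap = es$bootstrap %||% 1000L)
  known <- c("neuron", "pool", "synchrony", "estimator", "seed", "horizon_ms")
  list(neuron = neuron, pool = pool, model = model, estimator = estimator,
       horizon_ms = raw$horizon_ms %||% 10000,
       seed = raw$seed %||% 1L,
       synchrony_raw = sy,
       extra = raw[setdiff(names(raw), known)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config A named list (as read or assembled) to serialize.
#' @return `write_config()` returns `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a moment report as JSON
#'
#' @param report A [moment_report()] (or any named list).
#' @param path Output path.
#' @param meta Optional provenance list (seed, config hash, ...) stored
#'   under `provenance`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, meta = NULL) {
  x <- unclass(report)
  x$provenance <- c(list(package = "syncshot",
                         version = as.character(utils::packageVersion("syncshot")),
                         r_version = R.version.string),
                    meta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Named fixture configurations
#'
#' Regenerates the small deterministic experiment configurations used for
#' validation, keyed by the scenario they reproduce:
#' `fig5_moderate` (single neuron, moderate weights, within-pool synchrony),
#' `fig6_shared` (asynchronous pair sharing 85% / 40% of strong inputs),
#' `fig7_synchronous` (synchronous pair, rho = 0.02, rho' = 0.013),
#' `fig8_skewness` (skewness under weak synchrony at low drive), and
#' `fig10_jitter` (instantaneous rho_e = 0.25 jittered with sigma_J = 50 ms,
#' read out in 25 ms windows).
#'
#' @param name Fixture name (see above).
#' @param dir Output directory.
#' @param seed Seed recorded in the configuration.
#' @return The path of the written YAML file, invisibly.
#' @export
make_fixture <- function(name = c("fig5_moderate", "fig6_shared",
                                  "fig7_synchronous", "fig8_skewness",
                                  "fig10_jitter"),
                         dir = ".", seed = 1L) {
  name <- match.arg(name)
  neuron <- list(tau = 15, v_exc = 60, v_inh = -10, i_ext_over_g = 0,
                 epsilon = 0)
  cfg <- switch(name,
    fig5_moderate = list(
      seed = seed, horizon_ms = 20000, neuron = neuron,
      pool = list(n_exc = 1000L, n_inh = 250L, rate_exc = 10, rate_inh = 10,
                  w_exc = 0.001, w_inh = 0.004),
      synchrony = list(kind = "beta_binomial", rho_e = 0.03, rho_i = 0.03,
                       rho_ei = 0)),
    fig6_shared = list(
      seed = seed, horizon_ms = 20000, neuron = neuron,
      pool = list(n_exc = 200L, n_inh = 50L, rate_exc = 10, rate_inh = 10,
                  w_exc = 0.01, w_inh = 0.04),
      synchrony = list(kind = "shared_inputs", f_e = 0.85, f_i = 0.4)),
    fig7_synchronous = list(
      seed = seed, horizon_ms = 20000, neuron = neuron,
      pool = list(n_exc = 1000L, n_inh = 250L, rate_exc = 1, rate_inh = 1,
                  w_exc = 0.001, w_inh = 0.004),
      synchrony = list(kind = "cross_mixture", rho = 0.02, rho_cross = 0.013,
                       structure = "uniform")),
    fig8_skewness = list(
      seed = seed, horizon_ms = 20000, neuron = neuron,
      pool = list(n_exc = 1000L, n_inh = 250L, rate_exc = 1, rate_inh = 1,
                  w_exc = 0.001, w_inh = 0.004),
      synchrony = list(kind = "beta_binomial", rho_e = 0.03, rho_i = 0.03,
                       rho_ei = 0)),
    fig10_jitter = list(
      seed = seed, horizon_ms = 500000, neuron = neuron,
      pool = list(n_exc = 1000L, n_inh = 0L, rate_exc = 10, rate_inh = 0,
                  w_exc = 0.001, w_inh = 0),
      synchrony = list(kind = "beta_binomial", rho_e = 0.25, rho_i = 0,
                       rho_ei = 0),
      jitter = list(sigma_j_ms = 50, window_ms = 25)))
  path <- file.path(dir, paste0(name, ".yaml"))
  write_config(cfg, path)
  invisible(path)
}

#' Cross-check analytic moments against a simulation
#'
#' Runs the full pipeline on a configuration: builds the exact jump law,
#' simulates a Marcus event train over the configured horizon, estimates
#' time-weighted moments, and compares them with the analytic values within
#' `n_se` standard errors.
#'
#' @param config A list from [load_config()].
#' @param n_se Tolerance in standard errors (default 4; the analytic value
#'   must lie within `n_se` s.e. of the estimate).
#' @return A data frame of checks (`statistic`, `analytic`, `estimate`,
#'   `se`, `pass`), with attribute `ok` (all passed).
#' @export
validate_experiment <- function(config, n_se = 4) {
  jd <- jump_distribution(config$model)
  pl <- as_params_list(config$neuron, config$model$n_neurons)
  train <- sample_event_train(config$model, config$horizon_ms,
                              seed = config$seed)
  trace <- simulate_marcus(train, pl)
  est <- time_weighted_moments(trace, config$estimator, seed = config$seed)
  rows <- list()
  for (a in seq_len(config$model$n_neurons)) {
    m <- stationary_mean(jd, pl[[a]], a)
    v <- stationary_variance(jd, pl[[a]], a)
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = sprintf("mean_%d", a), analytic = m,
      estimate = est$mean[a], se = est$se$mean[a])
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = sprintf("variance_%d", a), analytic = v,
      estimate = est$variance[a], se = est$se$variance[a])
  }
  if (config$model$n_neurons == 2L) {
    cv <- stationary_covariance(jd, pl[[1]], pl[[2]])
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = "covariance", analytic = cv,
      estimate = est$covariance, se = est$se$covariance)
  } else {
    t3 <- third_central_moment(jd, pl[[1]])
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = "third_central", analytic = t3,
      estimate = est$third_central[1],
      se = max(est$se$skewness[1] * est$variance[1]^1.5,
               .Machine$double.eps))
  }
  out <- do.call(rbind, rows)
  out$pass <- abs(out$analytic - out$estimate) <= n_se * out$se
  attr(out, "ok") <- all(out$pass)
  out
}
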