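test_that("time-weighted moments are exact on degenerate and single segments", {
  p <- default_params(i_ext_over_g = 6)
  cfg <- estimator_config(burn_in_ms = 0, batches = 10, bootstrap = 50)
  ## constant trace at equilibrium: mean = constant, variance 0
  tr0 <- event_train(numeric(0), matrix(0, 0, 1), matrix(0, 0, 1),
                     horizon = c(0, 1000))
  vt0 <- simulate_marcus(tr0, p, v0 = 6)
  est0 <- time_weighted_moments(vt0, cfg)
  expect_equal(est0$mean, 6, tolerance = 1e-12)
  expect_equal(est0$variance, 0, tolerance = 1e-12)
  ## pure decay from V0 over one segment: mean = V0 (tau/D)(1 - e^(-D/tau))
  p0 <- default_params()
  D <- 45
  tr1 <- event_train(numeric(0), matrix(0, 0, 1), matrix(0, 0, 1),
                     horizon = c(0, D))
  vt1 <- simulate_marcus(tr1, p0, v0 = 12)
  est1 <- time_weighted_moments(vt1, estimator_config(burn_in_ms = 0,
                                                      batches = 2,
                                                      bootstrap = 50))
  expect_equal(est1$mean, 12 * (p0$tau / D) * (1 - exp(-D / p0$tau)),
               tolerance = 1e-10)
})

test_that("long-run estimates match analytic moments within 3 s.e.", {
  p <- default_params()
  mod <- small_bb_model(rate = 10)
  jd <- jump_distribution(mod)
  tr <- sample_event_train(mod, 120000, seed = 41)
  vt <- simulate_marcus(tr, p)
  est <- time_weighted_moments(vt, seed = 41)
  expect_lt(abs(est$mean - stationary_mean(jd, p)), 3 * est$se$mean)
  expect_lt(abs(est$variance - stationary_variance(jd, p)),
            3 * est$se$variance)
  t3_th <- third_central_moment(jd, p)
  se_t3 <- 3 * est$se$skewness * est$variance^1.5 + 1e-9
  expect_lt(abs(est$third_central - t3_th), 3 * se_t3)
  ## skewness is invariant under affine rescaling of the trajectory
  vt_sc <- vt
  vt_sc$v_post <- 2 * vt$v_post + 5
  vt_sc$v0 <- 2 * vt$v0 + 5
  vt_sc$params <- list(neuron_params(i_ext_over_g = 5,
                                     v_exc = 2 * 60 + 5, v_inh = 2 * -10 + 5))
  est_sc <- time_weighted_moments(vt_sc, seed = 41)
  expect_equal(est_sc$skewness, est$skewness, tolerance = 1e-10)
})

test_that("palm and time-weighted moments agree on a pair simulation", {
  p <- default_params()
  mod <- calibrate_cross_neuron(input_pool(40, 10, 10, 10, 0.01, 0.04),
                                rho = 0.1, rho_cross = 0.05,
                                structure = "within_pool")
  tr <- sample_event_train(mod, 60000, seed = 43)
  vt <- simulate_marcus(tr, list(p, p))
  tw <- time_weighted_moments(vt, seed = 43)
  pm <- palm_moments(vt)
  se2 <- function(a, b) sqrt(a^2 + b^2)
  for (a in 1:2) {
    expect_lt(abs(pm$mean[a] - tw$mean[a]),
              3 * se2(pm$se$mean[a], tw$se$mean[a]))
    expect_lt(abs(pm$variance[a] - tw$variance[a]),
              3 * se2(pm$se$variance[a], tw$se$variance[a]))
  }
  ## palm joint second moment against the exact covariance
  jd <- jump_distribution(mod)
  cv_th <- stationary_covariance(jd, p, p)
  expect_lt(abs(pm$covariance - cv_th), 3 * pm$se$covariance)
  ## empirical voltage correlation against the exact one
  rho_th <- cv_th / stationary_variance(jd_marginal(jd, 1), p)
  ec <- empirical_voltage_correlation(vt, seed = 43)
  expect_lt(abs(ec$estimate - rho_th), 3 * ec$se)
  expect_lte(abs(ec$estimate), 1)
})

test_that("identical and independent drives give correlations 1 and 0", {
  p <- default_params()
  ## fully shared pair: identical traces, correlation exactly 1
  mod1 <- sync_shared_inputs(input_pool(20, 5, 10, 10, 0.01, 0.04), 1, 1)
  vt1 <- simulate_marcus(sample_event_train(mod1, 30000, seed = 47),
                         list(p, p))
  ec1 <- empirical_voltage_correlation(vt1, seed = 1)
  expect_equal(ec1$estimate, 1, tolerance = 1e-9)
  ## unshared pair: correlation near 0
  mod0 <- sync_shared_inputs(input_pool(20, 5, 10, 10, 0.01, 0.04), 0, 0)
  vt0 <- simulate_marcus(sample_event_train(mod0, 60000, seed = 48),
                         list(p, p))
  ec0 <- empirical_voltage_correlation(vt0, seed = 1)
  expect_lt(abs(ec0$estimate), 3 * ec0$se + 0.02)
})

test_that("mirror-symmetric drive has zero empirical skewness", {
  pm <- neuron_params(v_exc = 30, v_inh = -30)
  jd_sym <- jump_dist(c(0.5, 0.5), c(0.2, 0), c(0, 0.2), rate_hz = 500)
  mod <- structure(list(kind = "atoms", n_neurons = 1L,
                        components = list(list(flavor = "atoms", rate_hz = 500,
                                               prob = c(0.5, 0.5),
                                               w_e = matrix(c(0.2, 0)),
                                               w_i = matrix(c(0, 0.2))))),
                   class = "synchrony_model")
  tr <- sample_event_train(mod, 60000, seed = 53)
  vt <- simulate_marcus(tr, pm)
  sk <- empirical_skewness(vt, seed = 53)
  expect_lt(abs(sk$estimate), 3 * sk$se)
})

test_that("windowed spike correlation: identical, independent, synchronous", {
  set.seed(61)
  t1 <- sort(runif(3000, 0, 300000))
  ## identical trains: correlation 1
  w_id <- windowed_spike_correlation(t1, t1, window_ms = 25,
                                     t_range = c(0, 300000))
  expect_equal(w_id$estimate, 1, tolerance = 1e-12)
  ## independent Poisson trains: 0 within 3 s.e.
  t2 <- sort(runif(3000, 0, 300000))
  w_ind <- windowed_spike_correlation(t1, t2, window_ms = 25,
                                      t_range = c(0, 300000))
  expect_lt(abs(w_ind$estimate), 3 * w_ind$se + 0.01)
  ## beta-binomial synchronous trains: ~ 1/(1+beta) at any window
  mod <- sync_beta_binomial(input_pool(30, 0, 10, 0, 0.01, 0), rho_e = 0.2)
  sl <- sample_spike_list(mod, 200000,
                          inputs = data.frame(neuron = 1, type = "e",
                                              index = 1:2), seed = 62)
  for (dt in c(10, 40)) {
    w <- windowed_spike_correlation(sl, window_ms = dt,
                                    t_range = c(0, 200000),
                                    ids = c("n1:e1", "n1:e2"))
    expect_lt(abs(w$estimate - 0.2), 3 * w$se)
  }
  expect_error(windowed_spike_correlation(t1, numeric(0), window_ms = 25,
                                          t_range = c(0, 300000)))
})

test_that("standard errors shrink like 1/sqrt(horizon)", {
  p <- default_params()
  mod <- small_bb_model(rate = 10)
  horizons <- c(15000, 30000, 60000, 120000)
  ses <- vapply(horizons, function(h) {
    tr <- sample_event_train(mod, h, seed = 71)
    time_weighted_moments(simulate_marcus(tr, p), seed = 71)$se$mean
  }, 0)
  fit <- stats::lm(log(ses) ~ log(horizons))
  expect_lt(abs(stats::coef(fit)[2] + 0.5), 0.2)
})
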