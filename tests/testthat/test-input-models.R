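test_that("beta-binomial correlation algebra matches its closed forms", {
  expect_equal(pairwise_rho_from_beta(1), 0.5)
  expect_equal(pairwise_rho_from_beta(1e9), 0, tolerance = 1e-8)
  expect_equal(beta_from_rho(0.03), 97 / 3, tolerance = 1e-12)
  expect_equal(pairwise_rho_from_beta(beta_from_rho(0.2)), 0.2)
  ## higher-order coefficients: empty product, pairwise consistency, and the
  ## single-coefficient identity rho_3 = 2 rho^2 / (1 + rho)
  b <- 97 / 3
  expect_equal(higher_order_rho(1, b), 1)
  expect_equal(higher_order_rho(2, b), pairwise_rho_from_beta(b))
  expect_equal(higher_order_rho(3, b), 2 * 0.03^2 / 1.03, tolerance = 1e-12)
  ## nonincreasing in n, power-law decay exponent beta
  rho_n <- higher_order_rho(1:50, 2.5)
  expect_true(all(diff(rho_n) < 0))
  expect_true(all(rho_n >= 0 & rho_n <= 1))
})

test_that("collective event rate is the digamma form, sublinear in K", {
  expect_equal(collective_rate(1, 3, 7.7), 3)                 # psi recurrence
  expect_equal(collective_rate(2, 1, 1), digamma(3) - digamma(1))  # 1.5 Hz
  expect_equal(collective_rate(2, 1, 1), 1.5)
  r_k <- collective_rate(c(10, 100, 1000), 1, 97 / 3)
  expect_true(all(diff(r_k) > 0))
  expect_lt(r_k[3], 1000 * 1)                                 # sublinear
  ## asynchronous and fully synchronous limits
  expect_equal(collective_rate(50, 2, Inf), 100)
  expect_equal(collective_rate(50, 2, 0), 2)
})

test_that("event-count law is normalized and consistent with rate and rho", {
  expect_equal(event_count_pmf(1, 5), 1)                       # point mass
  for (case in list(c(K = 7, beta = 0.8), c(K = 40, beta = 12),
                    c(K = 1000, beta = 97 / 3))) {
    pmf <- event_count_pmf(case["K"], case["beta"])
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    n <- seq_along(pmf)
    En <- sum(pmf * n); En2 <- sum(pmf * n * (n - 1))
    K <- case[["K"]]
    ## K / E[count] equals the collective-rate factor
    expect_equal(K / En,
                 case[["beta"]] * (digamma(case[["beta"]] + K) -
                                     digamma(case[["beta"]])),
                 tolerance = 1e-10)
    ## implied pairwise coactivation equals 1/(1+beta)
    if (K > 1)
      expect_equal((En2 / (K * (K - 1))) / (En / K),
                   1 / (1 + case[["beta"]]), tolerance = 1e-10)
  }
  ## Monte-Carlo activation vectors reproduce the pairwise correlation
  set.seed(42)
  K <- 12; beta <- 3
  pmf <- event_count_pmf(K, beta)
  nev <- 20000
  cnt <- sample.int(K, nev, replace = TRUE, prob = pmf)
  x1 <- stats::rhyper(nev, 2, K - 2, cnt)   # actives among a tracked pair
  both <- mean(x1 == 2L); one <- mean(x1 >= 1L)
  p1 <- sum(pmf * seq_len(K)) / K
  rho_hat <- both / p1
  se <- sd((x1 == 2L)) / sqrt(nev) / p1
  expect_lt(abs(rho_hat - 1 / (1 + beta)), 3 * se)
})

test_that("per-input rates are recovered from the event rate", {
  ## asynchronous: identity on the configured rates
  pool <- input_pool(4, 2, c(1, 2, 3, 4), c(5, 6), 0.01, 0.04)
  m <- sync_asynchronous(pool)
  expect_equal(input_rate_from_event_rate(m, type = "e", index = 3), 3)
  expect_equal(input_rate_from_event_rate(m, type = "i", index = 2), 6)
  ## beta-binomial: b * E[count]/K inverts the calibration
  mb <- sync_beta_binomial(input_pool(80, 20, 7, 7, 0.01, 0.04), 0.05, 0.02)
  expect_equal(input_rate_from_event_rate(mb, type = "e"), 7,
               tolerance = 1e-10)
  expect_equal(input_rate_from_event_rate(mb, type = "i"), 7,
               tolerance = 1e-10)
  ## fully synchronous pool: every input active at every event -> r = b
  mf <- sync_beta_binomial(input_pool(30, 0, 4, 0, 0.01, 0), rho_e = 1)
  expect_equal(input_rate_from_event_rate(mf, type = "e"),
               model_event_rate(mf), tolerance = 1e-10)
})

test_that("pair event rate obeys the overlap relation and its bounds", {
  expect_equal(pair_event_rate(10, 20, 0), 30)
  expect_equal(pair_event_rate(10, 10, 1), 10)   # optimally synchronous
  expect_equal(pair_event_rate(10, 30, 1 / 3), 30)
  expect_error(pair_event_rate(10, 30, 0.9))     # infeasible overlap
  for (q in c(0, 0.1, 1 / 3)) {
    b12 <- pair_event_rate(10, 30, q)
    expect_gte(b12, 30); expect_lte(b12, 40)
  }
})

test_that("jump laws have correct supports and subsampling consistency", {
  p <- default_params()
  ## asynchronous uniform pool: two atoms with rate-proportional weights
  pool <- input_pool(10, 5, 2, 4, 0.01, 0.04)
  jd <- jump_distribution(sync_asynchronous(pool))
  expect_equal(length(jd$prob), 2L)
  expect_equal(jd$rate_hz, 10 * 2 + 5 * 4)
  i_exc <- which(jd$w_e[, 1] > 0)
  expect_equal(jd$prob[i_exc], 20 / 40)
  ## beta-binomial excitatory-only: support {n w_e} with the count pmf
  K <- 15; rho <- 0.1
  jd_b <- jump_distribution(sync_beta_binomial(
    input_pool(K, 0, 3, 0, 0.01, 0), rho_e = rho))
  pmf <- event_count_pmf(K, beta_from_rho(rho))
  o <- order(jd_b$w_e[, 1])
  expect_equal(jd_b$w_e[o, 1], (1:K) * 0.01, tolerance = 1e-12)
  expect_equal(jd_b$prob[o], pmf, tolerance = 1e-10)
  ## subsampling (nested neuron sets): b_A = b_B * P(sum_A W > 0), and the
  ## pair marginal reproduces the single-neuron law
  mod2 <- calibrate_cross_neuron(small_pair_pool(), rho = 0.1,
                                 rho_cross = 0.04)
  jd2 <- jump_distribution(mod2)
  jd1 <- jd_marginal(jd2, 1L)
  tot1 <- rowSums(jd2$w_e[, 1, drop = FALSE]) + rowSums(jd2$w_i[, 1, drop = FALSE])
  p_pos <- sum(jd2$prob[tot1 > 0])
  expect_equal(jd1$rate_hz, jd2$rate_hz * p_pos, tolerance = 1e-12)
  m_pair <- stationary_mean(jd2, p, neuron = 1L)
  m_single <- stationary_mean(jd1, p)
  expect_equal(m_pair, m_single, tolerance = 1e-12)
})

test_that("cross-neuron calibration hits its correlation targets", {
  pool <- small_pair_pool()
  ## generic targets, both structures: implied coefficients match exactly
  for (st in c("within_pool", "uniform")) {
    mod <- calibrate_cross_neuron(pool, rho = 0.1, rho_cross = 0.04,
                                  structure = st)
    expect_equal(implied_rho(mod, 1, "e", 1, "e"), 0.1, tolerance = 1e-10)
    expect_equal(implied_rho(mod, 1, "e", 2, "e"), 0.04, tolerance = 1e-10)
    expect_equal(input_rate_from_event_rate(mod, 1, "e"), 5,
                 tolerance = 1e-10)
    ei <- implied_rho(mod, 1, "e", 1, "i")
    expect_equal(ei, if (st == "uniform") 0.1 else 0, tolerance = 1e-10)
  }
  ## rho_cross = 0: independent neurons (no joint component)
  m0 <- calibrate_cross_neuron(pool, rho = 0.1, rho_cross = 0)
  jd0 <- jump_distribution(m0)
  expect_equal(stationary_covariance(jd0, default_params()), 0,
               tolerance = 1e-12)
  ## rho_cross = rho: single merged exchangeable pool across the neurons
  m1 <- calibrate_cross_neuron(pool, rho = 0.1, rho_cross = 0.1)
  expect_equal(length(m1$components), 2L)  # one joint component per type
  expect_error(calibrate_cross_neuron(pool, rho = 0.05, rho_cross = 0.2))
})

test_that("sampled events reproduce the calibrated coefficients empirically", {
  ## moderate-size pools, windowed (vanishing-window) spiking correlation
  pool <- input_pool(40, 0, 20, 0, 0.01, 0)
  mod <- calibrate_cross_neuron(pool, rho = 0.1, rho_cross = 0.05,
                                structure = "within_pool")
  sl <- sample_spike_list(mod, 200000,
                          inputs = data.frame(neuron = c(1, 1, 2),
                                              type = "e", index = c(1, 2, 1)),
                          seed = 91)
  w_in <- windowed_spike_correlation(sl, window_ms = 1,
                                     ids = c("n1:e1", "n1:e2"))
  expect_lt(abs(w_in$estimate - 0.1), 3 * w_in$se)
  w_x <- windowed_spike_correlation(sl, window_ms = 1,
                                    ids = c("n1:e1", "n2:e1"))
  expect_lt(abs(w_x$estimate - 0.05), 3 * w_x$se)
})

test_that("synaptic failure thins rates and correlations as sqrt(p_a p_b)", {
  ## identity at p = 1
  m <- sync_beta_binomial(input_pool(50, 0, 5, 0, 0.01, 0), 0.04)
  expect_identical(apply_synaptic_failure(m, 1), m)
  ## p = 0.5: rho 0.04 -> 0.02; rates halve
  mf <- apply_synaptic_failure(m, 0.5)
  expect_equal(implied_rho(mf), 0.02, tolerance = 1e-10)
  expect_equal(input_rate_from_event_rate(mf, type = "e"), 2.5,
               tolerance = 1e-10)
  ## K -> K/p compensation preserves small-weight second and third moments
  p <- default_params()
  m0 <- sync_beta_binomial(input_pool(100, 0, 10, 0, 0.005, 0), 0.03)
  mc <- apply_synaptic_failure(
    sync_beta_binomial(input_pool(1000, 0, 10, 0, 0.005, 0), 0.03), 0.1)
  jd0 <- jump_distribution(m0); jdc <- jump_distribution(mc)
  v0 <- stationary_variance(jd0, p); vc <- stationary_variance(jdc, p)
  t0 <- third_central_moment(jd0, p); tc <- third_central_moment(jdc, p)
  expect_equal(input_rate_from_event_rate(mc, type = "e"), 1,
               tolerance = 1e-10)
  expect_lt(abs(vc - v0) / v0, 0.02)
  expect_lt(abs(tc - t0) / abs(t0), 0.05)
})

test_that("infeasible correlation structures are rejected", {
  expect_error(correlation_structure(rho_ee = 0.01, rho_ii = 0.01,
                                     rho_ei = 0.5))
  expect_error(correlation_structure(rho_ee = 0.02, rho_ee_cross = 0.03))
  expect_error(correlation_structure(rho_ee = 1.5))
  expect_error(sync_beta_binomial(input_pool(10, 5, 1, 2, 0.01, 0.04),
                                  0.03, 0.03, 0.03))  # unequal rates with ei
})
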