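test_that("stationary mean: limits, deterministic jumps, efficacy forms", {
  p <- default_params(i_ext_over_g = 3)
  ## vanishing input rate: mean at the resting offset I/G
  jd <- jump_dist(1, 0.1, 0, rate_hz = 1e-12)
  expect_equal(stationary_mean(jd, p), 3, tolerance = 1e-9)
  ## deterministic pure-excitatory jump: m = b u Ve / (1/tau + b u)
  p0 <- default_params()
  b_hz <- 100; w <- 0.1
  jd1 <- jump_dist(1, w, 0, rate_hz = b_hz)
  u <- 1 - exp(-w); b <- b_hz / 1000
  expect_equal(stationary_mean(jd1, p0), b * u * 60 / (1 / 15 + b * u),
               tolerance = 1e-12)
  ## asynchronous pools: efficacies reduce to sum_k r_k (1 - exp(-w_k))
  pool <- input_pool(3, 2, c(2, 4, 6), c(3, 5), c(0.1, 0.2, 0.3), c(0.4, 0.5))
  jd_a <- jump_distribution(sync_asynchronous(pool))
  c_e <- sum(hz_to_per_ms <- pool$rate_exc / 1000 * (1 - exp(-pool$w_exc)))
  c_i <- sum(pool$rate_inh / 1000 * (1 - exp(-pool$w_inh)))
  expect_equal(stationary_mean(jd_a, p0),
               (c_e * 60 - c_i * 10) / (1 / 15 + c_e + c_i),
               tolerance = 1e-12)
  ## the mean stays inside (v_inh, v_exc)
  for (jd_x in example_jump_laws()) {
    m <- stationary_mean(jd_x, p0)
    expect_gt(m, p0$v_inh); expect_lt(m, p0$v_exc)
  }
})

test_that("stationary covariance: independence, variance recovery, full sync", {
  p <- default_params()
  ## never-coactive pair laws give zero covariance
  jd_ind <- jump_dist(c(0.5, 0.5),
                      w_e = cbind(c(0.1, 0), c(0, 0.1)),
                      w_i = cbind(c(0, 0), c(0, 0)), rate_hz = 2000)
  expect_equal(stationary_covariance(jd_ind, p), 0, tolerance = 1e-14)
  ## identical neurons with identical jumps: covariance equals variance
  mod <- small_bb_model()
  jd1 <- jump_distribution(mod)
  jd_dup <- jump_dist(jd1$prob, cbind(jd1$w_e[, 1], jd1$w_e[, 1]),
                      cbind(jd1$w_i[, 1], jd1$w_i[, 1]), jd1$rate_hz)
  expect_equal(stationary_covariance(jd_dup, p),
               stationary_variance(jd1, p), tolerance = 1e-12)
  ## fully synchronous pair: M^{rho'=1}_{V1,V2} = M^{rho=1}_{V1,V1}
  pool <- small_pair_pool()
  m_pair <- calibrate_cross_neuron(pool, rho = 1, rho_cross = 1,
                                   structure = "uniform")
  m_one <- sync_beta_binomial(pool, rho_e = 1, rho_i = 1, rho_ei = 1)
  cv <- stationary_covariance(jump_distribution(m_pair), p)
  vv <- stationary_variance(jump_distribution(m_one), p)
  expect_equal(cv, vv, tolerance = 1e-10)
})

test_that("asynchronous exact variance agrees with the jump-law route", {
  p <- default_params()
  pool <- input_pool(30, 10, 7, 7, c(rep(0.01, 15), rep(0.03, 15)), 0.05)
  v1 <- variance_asynchronous_exact(pool, p)
  v2 <- stationary_variance(jump_distribution(sync_asynchronous(pool)), p)
  expect_equal(v1, v2, tolerance = 1e-12)
  ## all-zero weights: zero variance
  expect_error(variance_asynchronous_exact(input_pool(5, 0, 1, 0, 0, 0), p))
  ## small-weight limit: relative deviation from the quadratic form is O(w)
  scales <- c(1, 1 / 4, 1 / 16)
  devs <- vapply(scales, function(s) {
    pl <- input_pool(30, 10, 7, 7, 0.04 * s, 0.16 * s)
    ex <- variance_asynchronous_exact(pl, p)
    sw <- variance_small_weight(pl, correlation_structure(), p)
    abs(ex - sw) / ex
  }, 0)
  ratios <- devs[-length(devs)] / devs[-1]
  expect_true(all(ratios > 3))   # first-order vanishing (factor ~4 per 1/4)
})

test_that("small-weight variance carries the synchrony gain and E-I cancellation", {
  p <- default_params()
  pool <- input_pool(100, 25, 5, 5, 0.01, 0.04)
  v0 <- variance_small_weight(pool, correlation_structure(), p)
  ## uniform within-pool rho multiplies the pool term by 1 + (K-1) rho
  rho <- 0.01
  v_r <- variance_small_weight(pool,
                               correlation_structure(rho_ee = rho), p)
  m <- syncshot:::small_weight_mean(pool, p)
  num_e0 <- (60 - m)^2 * 100 * (5 / 1000) * 0.01^2
  expect_equal(v_r - v0, num_e0 * (100 - 1) * rho /
                 (2 * (1 / 15 + 100 * 5 / 1000 * 0.01 + 25 * 5 / 1000 * 0.04)),
               tolerance = 1e-10)
  ## K = 100 at rho = 0.01: synchrony factor 1 + (K-1) rho = 1.99
  expect_equal(1 + (100 - 1) * rho, 1.99)
  ## positive rho_ei reduces the variance at equal other parameters
  v_ei <- variance_small_weight(pool,
    correlation_structure(rho_ee = 0.03, rho_ii = 0.03, rho_ei = 0.03), p)
  v_no <- variance_small_weight(pool,
    correlation_structure(rho_ee = 0.03, rho_ii = 0.03, rho_ei = 0), p)
  expect_lt(v_ei, v_no)
  ## nondecreasing in each within-pool coefficient
  for (fld in c("rho_ee", "rho_ii")) {
    args1 <- list(rho_ee = 0.01, rho_ii = 0.01); args2 <- args1
    args2[[fld]] <- 0.02
    va <- variance_small_weight(pool, do.call(correlation_structure, args1), p)
    vb <- variance_small_weight(pool, do.call(correlation_structure, args2), p)
    expect_gte(vb, va)
  }
  ## decomposition: M = (1 - rho) M^{rho=0} + rho M^{rho=1} (uniform case);
  ## rho = 1 is outside the approximation regime (warning suppressed), the
  ## identity holds for the quadratic form itself
  v_rho <- function(r) suppressWarnings(variance_small_weight(pool,
    correlation_structure(rho_ee = r, rho_ii = r), p))
  expect_equal(v_rho(0.3), 0.7 * v_rho(0) + 0.3 * v_rho(1), tolerance = 1e-12)
})

test_that("small-weight covariance is linear in the cross coefficients", {
  p <- default_params()
  pool <- input_pool(100, 25, 5, 5, 0.01, 0.04)
  cs <- function(ee, ii, ei) correlation_structure(
    rho_ee = 0.04, rho_ii = 0.04, rho_ei = 0.04,
    rho_ee_cross = ee, rho_ii_cross = ii, rho_ei_cross = ei)
  expect_equal(covariance_small_weight(pool, cs(0, 0, 0), p), 0)
  ## pure E-I cross correlation yields negative covariance
  expect_lt(covariance_small_weight(pool, cs(0, 0, 0.02), p), 0)
  ## doubling all cross coefficients doubles the covariance
  c1 <- covariance_small_weight(pool, cs(0.01, 0.01, 0.01), p)
  c2 <- covariance_small_weight(pool, cs(0.02, 0.02, 0.02), p)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("excitatory share q matches its closed form and printed values", {
  p <- default_params()
  ## no inhibition: q = 1
  expect_equal(excitatory_share_q(input_pool(10, 0, 1, 0, 0.1, 0), p, m = 0), 1)
  ## Ke we = Ki wi = 1, wi = 4 we, re = ri: q(0) = 0.90, q(15) ~ 0.4475
  pool <- input_pool(1000, 250, 1, 1, 0.001, 0.004)
  expect_equal(excitatory_share_q(pool, p, m = 0), 0.90, tolerance = 1e-12)
  expect_equal(excitatory_share_q(pool, p, m = 15), 0.4475, tolerance = 1e-3)
  ## decreasing in m over the physiological range
  qs <- vapply(seq(-10, 20, by = 5),
               function(m) excitatory_share_q(pool, p, m = m), 0)
  expect_true(all(diff(qs) < 0))
  expect_error(excitatory_share_q(input_pool(5, 0, 0, 0, 0, 0), p, m = 0))
})

test_that("kappa: excitation-only limit and inhibitory reduction", {
  p <- default_params()
  pool <- input_pool(1000, 250, 1, 1, 0.001, 0.004)
  ## q = 1 reduces both cases to Ke
  pe <- input_pool(1000, 0, 1, 0, 0.001, 0)
  expect_equal(kappa_ratio(pe, p, m = 0, case = "i"), 1000)
  expect_equal(kappa_ratio(pe, p, m = 0, case = "ii"), 1000, tolerance = 1e-9)
  ## case (ii) equals (sqrt(Ke q) - sqrt(Ki(1-q)))^2 (equal rates)
  for (m in c(0, 7, 15)) {
    q <- excitatory_share_q(pool, p, m = m)
    expect_equal(kappa_ratio(pool, p, m = m, case = "ii"),
                 (sqrt(1000 * q) - sqrt(250 * (1 - q)))^2, tolerance = 1e-9)
  }
  ## printed reductions: ~0.6 Ke at rest, ~0.08 Ke at 15 mV
  expect_equal(kappa_ratio(pool, p, m = 0, case = "ii") / 1000, 0.625,
               tolerance = 1e-9)
  expect_equal(kappa_ratio(pool, p, m = 15, case = "ii") / 1000, 0.0884,
               tolerance = 1e-3)
  ## case (i) is the q-weighted mean of the pool sizes
  q0 <- excitatory_share_q(pool, p, m = 0)
  expect_equal(kappa_ratio(pool, p, m = 0, case = "i"),
               1000 * q0 + 250 * (1 - q0), tolerance = 1e-12)
})

test_that("voltage-correlation formulas: shared inputs and synchrony", {
  ## shared inputs: rho_V = fe q + fi (1 - q)
  expect_equal(shared_input_correlation(0.85, 0.40, 0.90), 0.805)
  expect_equal(shared_input_correlation(0.3, 0.3, 0.77), 0.3)  # fe = fi
  expect_equal(shared_input_correlation(0.85, 0.40, 1), 0.85)  # q = 1
  ## synchrony: rho_V = rho' / ((1-rho)/kappa + rho)
  expect_equal(synchronous_voltage_correlation(0.02, 0, 500), 0)
  ## saturation at rho'/rho for large kappa
  expect_equal(synchronous_voltage_correlation(0.02, 0.013, 1e12),
               0.013 / 0.02, tolerance = 1e-6)
  ## linear regime: rho_V ~ rho' kappa for small kappa rho
  expect_equal(synchronous_voltage_correlation(0.02, 0.001, 5),
               0.001 * 5, tolerance = 0.12)
  ## always bounded by rho'/rho
  for (k in c(1, 100, 1e4))
    expect_lte(synchronous_voltage_correlation(0.02, 0.013, k), 0.013 / 0.02)
})

test_that("third central moment: symmetry, small-weight form, skewness", {
  p <- default_params()
  ## mirror-symmetric configuration: exchangeable jumps toward +/- V*
  pm <- neuron_params(v_exc = 30, v_inh = -30)
  jd_sym <- jump_dist(c(0.5, 0.5), c(0.2, 0), c(0, 0.2), rate_hz = 1000)
  expect_equal(third_central_moment(jd_sym, pm), 0, tolerance = 1e-12)
  ## excitation-only small-weight reduction in terms of rho and rho_3:
  ## the exact moments converge to the quadratic/cubic correlation forms at
  ## first order as weights shrink
  K <- 200; rho <- 0.05; r_hz <- 8
  rel_dev <- vapply(c(0.002, 0.001, 0.0005), function(w) {
    jd_e <- jump_distribution(sync_beta_binomial(
      input_pool(K, 0, r_hz, 0, w, 0), rho_e = rho))
    m <- stationary_mean(jd_e, p)
    M2 <- stationary_variance(jd_e, p)
    M3 <- third_central_moment(jd_e, p)
    r <- r_hz / 1000
    rho3 <- 2 * rho^2 / (1 + rho)
    den1 <- 1 / p$tau + K * r * w
    M2_sw <- (60 - m)^2 * K * r * w^2 * (1 + (K - 1) * rho) / (2 * den1)
    M3_sw <- ((60 - m)^3 * K * r * w^3 *
                (1 + 3 * (K - 1) * rho + (K - 1) * (K - 2) * rho3) -
              6 * (60 - m) * K * r * w^2 * (1 + (K - 1) * rho) * M2_sw) /
      (3 * den1)
    c(abs(M2 - M2_sw) / M2, abs(M3 - M3_sw) / abs(M3))
  }, numeric(2))
  expect_lt(rel_dev[1, 3], 0.015)          # M2 within ~1% at w = 5e-4
  expect_lt(rel_dev[2, 3], 0.03)           # M3 within ~2%
  ratios <- rel_dev[, -3] / rel_dev[, -1]  # halving w halves the deviation
  expect_true(all(ratios > 1.7 & ratios < 2.3))
  ## skewness definition
  jd_s <- jump_distribution(sync_beta_binomial(
    input_pool(K, 0, r_hz, 0, 0.001, 0), rho_e = rho))
  expect_equal(stationary_skewness(jd_s, p),
               third_central_moment(jd_s, p) /
                 stationary_variance(jd_s, p)^1.5, tolerance = 1e-12)
})

test_that("skewness closed forms give the expected magnitudes", {
  ## current-based reference: 0.24 at 1 Hz, 0.049 at 25 Hz (Ke = 1000)
  expect_equal(skewness_current_based(1000, 1, 15), (2 * sqrt(2) / 3) / sqrt(15),
               tolerance = 1e-12)
  expect_equal(skewness_current_based(1000, 1, 15), 0.2434, tolerance = 1e-3)
  expect_equal(skewness_current_based(1000, 25, 15), 0.0487, tolerance = 1e-3)
  ## quadrupling the drive halves the skewness
  expect_equal(skewness_current_based(1000, 4, 15),
               skewness_current_based(1000, 1, 15) / 2, tolerance = 1e-12)
  ## conductance-based approximation: ~0.2 asynchronous, ~1.3 at rho = 0.03
  expect_equal(skewness_conductance_approx(1000, 1, 15, 0), 0.233,
               tolerance = 2e-2)
  expect_equal(skewness_conductance_approx(1000, 1, 15, 0.03), 1.295,
               tolerance = 1e-2)
  ## sign change at r = 1/(2 tau) and increase with rho
  r_c <- 1000 / (2 * 15)   # Hz
  expect_equal(skewness_conductance_approx(1000, r_c, 15, 0.03), 0,
               tolerance = 1e-12)
  expect_lt(skewness_conductance_approx(1000, 50, 15, 0.03), 0)
  expect_gt(skewness_conductance_approx(1000, 1, 15, 0.03),
            skewness_conductance_approx(1000, 1, 15, 0.01))
})

test_that("full analytic reports satisfy moment inequalities", {
  p <- default_params()
  mod <- calibrate_cross_neuron(small_pair_pool(), rho = 0.1,
                                rho_cross = 0.05, structure = "uniform")
  rep <- moment_report_analytic(mod, p)
  expect_true(all(rep$variance > 0))
  expect_lte(abs(rep$correlation), 1)
  expect_lte(rep$covariance^2, prod(rep$variance) * (1 + 1e-12))
  expect_equal(rep$mean[1], rep$mean[2], tolerance = 1e-12)  # symmetric pair
})
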