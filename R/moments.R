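#' Stationary moment report
#'
#' Container for stationary voltage statistics with provenance: analytic
#' exact, small-weight approximation, or Monte-Carlo with standard errors.
#'
#' @param mean Per-neuron stationary means, mV.
#' @param variance Per-neuron variances, mV^2.
#' @param covariance Pair covariance, mV^2 (NA for single neurons).
#' @param third_central Per-neuron third central moments, mV^3.
#' @param skewness Per-neuron skewness (dimensionless).
#' @param correlation Pair voltage correlation (dimensionless).
#' @param method One of `"exact"`, `"small_weight"`, `"monte_carlo"`.
#' @param se Optional named list of standard errors (Monte-Carlo methods).
#' @return An object of class `moment_report`.
#' @export
moment_report <- function(mean, variance, covariance = NA_real_,
                          third_central = NA_real_, skewness = NA_real_,
                          correlation = NA_real_,
                          method = c("exact", "small_weight", "monte_carlo"),
                          se = NULL) {
  method <- match.arg(method)
  stopifnot(all(variance >= -1e-12 | is.na(variance)))
  if (!is.na(correlation) && abs(correlation) > 1 + 1e-9)
    stop("correlation outside [-1, 1]")
  structure(list(mean = mean, variance = variance, covariance = covariance,
                 third_central = third_central, skewness = skewness,
                 correlation = correlation, method = method, se = se),
            class = "moment_report")
}

#' @export
print.moment_report <- function(x, ...) {
  cat(sprintf("Stationary moments (%s)\n", x$method))
  cat(sprintf("  mean      : %s mV\n", paste(signif(x$mean, 5), collapse = ", ")))
  cat(sprintf("  variance  : %s mV^2\n", paste(signif(x$variance, 5), collapse = ", ")))
  if (!all(is.na(x$covariance)))
    cat(sprintf("  covariance: %s mV^2\n", signif(x$covariance, 5)))
  if (!all(is.na(x$third_central)))
    cat(sprintf("  third     : %s mV^3\n", paste(signif(x$third_central, 5), collapse = ", ")))
  if (!all(is.na(x$skewness)))
    cat(sprintf("  skewness  : %s\n", paste(signif(x$skewness, 5), collapse = ", ")))
  if (!all(is.na(x$correlation)))
    cat(sprintf("  rho_V     : %s\n", signif(x$correlation, 5)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Exact moments from the jump law (PASTA fixed point, closed forms)
## ---------------------------------------------------------------------------

#' Exact stationary mean voltage
#'
#' Evaluates the PASTA fixed-point mean
#' `m = (c_e V_e + c_i V_i + (I/G)/tau) / (1/tau + c_e + c_i)` with the
#' synchrony-aware synaptic efficacies
#' `c_a = b * E[ (W_a / (W_e + W_i)) * (1 - exp(-(W_e+W_i))) ]` evaluated
#' exactly over the finite-support jump law.  Without synchrony the
#' efficacies reduce to the shot-noise form `sum_k r_k (1 - exp(-w_k))`,
#' and for small weights to the classical `sum_k r_k w_k`.
#'
#' @param jd A [jump_dist()] (multi-neuron laws are marginalized).
#' @param params A [neuron_params()].
#' @param neuron Neuron index within `jd`.
#' @return The stationary mean, mV (always inside `(v_inh, v_exc)`).
#' @export
stationary_mean <- function(jd, params, neuron = 1L) {
  if (n_neurons(jd) > 1L) jd <- jd_marginal(jd, neuron)
  b <- hz_to_per_ms(jd$rate_hz)
  if (b == 0) return(params$i_ext_over_g)
  w <- jd$w_e[, 1] + jd$w_i[, 1]
  omy <- 1 - exp(-w)
  frac_e <- ifelse(w > 0, jd$w_e[, 1] / pmax(w, .Machine$double.xmin), 0)
  c_e <- b * sum(jd$prob * frac_e * omy)
  c_i <- b * sum(jd$prob * (1 - frac_e) * omy * (w > 0))
  (c_e * params$v_exc + c_i * params$v_inh + params$i_ext_over_g / params$tau) /
    (1 / params$tau + c_e + c_i)
}

#' Exact stationary covariance (and variance)
#'
#' Evaluates the PASTA fixed-point covariance
#' \deqn{M_{12} = b_{12} E[(R_1 - m_1)(1-Y_1)(R_2 - m_2)(1-Y_2)] /
#'   (1/\tau_1 + 1/\tau_2 + b_{12} E[1 - Y_1 Y_2])}
#' over the joint jump law of the pair, with `Y_a = exp(-(W_e,a + W_i,a))`
#' and jump targets `R_a`; neurons with zero jump at an atom contribute
#' `Y_a = 1`.  With the two neurons identified (`neuron2 = neuron1`) this is
#' the exact stationary variance.
#'
#' @param jd A [jump_dist()] over the pair (or a single neuron).
#' @param params1,params2 [neuron_params()] of each neuron.
#' @param neuron1,neuron2 Columns of `jd` to use.
#' @return Covariance in mV^2.
#' @export
stationary_covariance <- function(jd, params1, params2 = params1,
                                  neuron1 = 1L, neuron2 = 2L) {
  if (n_neurons(jd) == 1L) neuron2 <- 1L
  m1 <- stationary_mean(jd, params1, neuron1)
  m2 <- stationary_mean(jd, params2, neuron2)
  b <- hz_to_per_ms(jd$rate_hz)
  a1 <- jd_aux(jd, neuron1, params1)
  a2 <- jd_aux(jd, neuron2, params2)
  num <- b * sum(jd$prob * (a1$r - m1) * a1$one_m_y * (a2$r - m2) * a2$one_m_y)
  den <- 1 / params1$tau + 1 / params2$tau + b * sum(jd$prob * (1 - a1$y * a2$y))
  num / den
}

#' @rdname stationary_covariance
#' @param jd A single-neuron [jump_dist()].
#' @param params A [neuron_params()].
#' @param neuron Column of `jd`.
#' @export
stationary_variance <- function(jd, params, neuron = 1L) {
  if (n_neurons(jd) > 1L) jd <- jd_marginal(jd, neuron)
  stationary_covariance(jd, params, params, 1L, 1L)
}

#' Exact stationary third central moment
#'
#' Compact PASTA fixed-point form of the third centered voltage moment:
#' \deqn{M_3 = \frac{E[(R-m)^3 (1-Y)^3] + 3 M_2 E[(R-m)(Y^2-1)(1-Y)]}
#'   {3/(b\tau) + E[1-Y^3]}}
#' with `Y = exp(-(W_e+W_i))`, jump target `R`, stationary mean `m` and
#' variance `M_2`.  The expression is exact for any constant tonic current.
#'
#' @param jd A single-neuron [jump_dist()].
#' @param params A [neuron_params()].
#' @param neuron Column of `jd`.
#' @param mean,variance Optional precomputed mean/variance (must come from
#'   the same law; computed if omitted).
#' @return Third central moment in mV^3.
#' @export
third_central_moment <- function(jd, params, neuron = 1L,
                                 mean = NULL, variance = NULL) {
  if (n_neurons(jd) > 1L) jd <- jd_marginal(jd, neuron)
  m  <- if (is.null(mean)) stationary_mean(jd, params) else mean
  M2 <- if (is.null(variance)) stationary_variance(jd, params) else variance
  b <- hz_to_per_ms(jd$rate_hz)
  a <- jd_aux(jd, 1L, params)
  rc <- a$r - m
  num <- sum(jd$prob * rc^3 * a$one_m_y^3) +
    3 * M2 * sum(jd$prob * rc * (a$y^2 - 1) * a$one_m_y)
  den <- 3 / (b * params$tau) + sum(jd$prob * (1 - a$y^3))
  num / den
}

#' Exact stationary skewness
#'
#' `S[V] = M3 / M2^(3/2)` from the exact third moment and variance.
#'
#' @inheritParams third_central_moment
#' @return Dimensionless skewness.
#' @export
stationary_skewness <- function(jd, params, neuron = 1L) {
  if (n_neurons(jd) > 1L) jd <- jd_marginal(jd, neuron)
  m  <- stationary_mean(jd, params)
  M2 <- stationary_variance(jd, params)
  M3 <- third_central_moment(jd, params, mean = m, variance = M2)
  M3 / M2^1.5
}

## ---------------------------------------------------------------------------
## Asynchronous and small-weight reductions
## ---------------------------------------------------------------------------

## self-consistent small-weight mean (classical efficacies c_a = sum r w)
small_weight_mean <- function(pool, params) {
  c_e <- sum(hz_to_per_ms(pool$rate_exc) * pool$w_exc)
  c_i <- sum(hz_to_per_ms(pool$rate_inh) * pool$w_inh)
  (c_e * params$v_exc + c_i * params$v_inh + params$i_ext_over_g / params$tau) /
    (1 / params$tau + c_e + c_i)
}

#' Exact stationary variance for asynchronous inputs
#'
#' Shot-noise variance without synchrony, with exponential synaptic
#' efficacies:
#' \deqn{M_V = \frac{\sum_k r_k (1-e^{-w_k})^2 (V_\alpha - m)^2}
#'   {2/\tau + \sum_k r_k (1 - e^{-2 w_k})}}
#' summed over both pools; `m` is the exact asynchronous stationary mean.
#' This coincides with the effective-time-constant result except for the
#' exponential form of the efficacies, and reduces to the classical
#' quadratic small-weight expression as weights shrink.
#'
#' @param pool An [input_pool()].
#' @param params A [neuron_params()].
#' @return Variance in mV^2.
#' @export
variance_asynchronous_exact <- function(pool, params) {
  re <- hz_to_per_ms(pool$rate_exc); ri <- hz_to_per_ms(pool$rate_inh)
  we <- pool$w_exc; wi <- pool$w_inh
  m <- stationary_mean(jump_distribution(sync_asynchronous(pool)), params)
  num <- sum(re * (1 - exp(-we))^2) * (params$v_exc - m)^2 +
         sum(ri * (1 - exp(-wi))^2) * (params$v_inh - m)^2
  den <- 2 / params$tau + sum(re * (1 - exp(-2 * we))) +
         sum(ri * (1 - exp(-2 * wi)))
  num / den
}

#' Small-weight stationary variance with synchrony
#'
#' Quadratic-form approximation of the variance in terms of pairwise
#' spiking correlations, valid when per-event jumps are small:
#' \deqn{M_V \simeq \frac{\sum_{\alpha\beta} (V_\alpha - m)(V_\beta - m)
#'   \sum_{kl} \rho_{\alpha\beta,kl} \sqrt{r_k r_l} w_k w_l}
#'   {2 (1/\tau + \sum_k r_k w_k)}}
#' Diagonal coefficients are 1, so with uniform pools the within-pool sums
#' carry the synchrony gain `K r w^2 (1 + (K-1) rho)`; positive
#' excitation-inhibition correlation `rho_ei` contributes the (negative)
#' cross term and can only reduce variability.
#'
#' @param pool An [input_pool()].
#' @param correlation A [correlation_structure()] (within-neuron entries).
#' @param params A [neuron_params()].
#' @param m Mean voltage; defaults to the self-consistent small-weight mean.
#' @return Variance in mV^2 (a warning is issued outside the small-weight
#'   regime, when a typical total jump exceeds 0.2).
#' @export
variance_small_weight <- function(pool, correlation, params, m = NULL) {
  if (is.null(m)) m <- small_weight_mean(pool, params)
  re <- hz_to_per_ms(pool$rate_exc); ri <- hz_to_per_ms(pool$rate_inh)
  we <- pool$w_exc; wi <- pool$w_inh
  ## typical per-event jump: weight times mean coactive-cluster size
  jump_scale <- max(c(0, we * (1 + (length(we) - 1) * correlation$rho_ee),
                      wi * (1 + (length(wi) - 1) * correlation$rho_ii)))
  if (is.finite(jump_scale) && jump_scale > 0.2)
    warning("typical per-event jump exceeds 0.2; small-weight approximation is strained")
  s_e <- sum(sqrt(re) * we); d_e <- sum(re * we^2)
  s_i <- sum(sqrt(ri) * wi); d_i <- sum(ri * wi^2)
  de <- params$v_exc - m; di <- params$v_inh - m
  num <- de^2 * (d_e + correlation$rho_ee * (s_e^2 - d_e)) +
         di^2 * (d_i + correlation$rho_ii * (s_i^2 - d_i)) +
         2 * de * di * correlation$rho_ei * s_e * s_i
  den <- 2 * (1 / params$tau + sum(re * we) + sum(ri * wi))
  num / den
}

#' Small-weight cross-neuron covariance
#'
#' \deqn{M_{12} \simeq \frac{\sum_{\alpha\beta} (V_\alpha - m_1)
#'   (V_\beta - m_2) \rho'_{\alpha\beta} \sum_k \sqrt{r_k} w_{1,k}
#'   \sum_l \sqrt{r_l} w_{2,l}}{1/\tau_1 + 1/\tau_2 +
#'   \sum_k r_k (w_{1,k} + w_{2,k})}}
#' Linear in each cross-neuron coefficient; zero when all vanish, and
#' negative when only the excitation-inhibition cross coefficients are
#' positive.
#'
#' @param pool1,pool2 [input_pool()]s of the two neurons.
#' @param correlation A [correlation_structure()] (cross-neuron entries).
#' @param params1,params2 [neuron_params()] per neuron.
#' @param m1,m2 Mean voltages (self-consistent small-weight defaults).
#' @return Covariance in mV^2.
#' @export
covariance_small_weight <- function(pool1, correlation, params1,
                                    pool2 = pool1, params2 = params1,
                                    m1 = NULL, m2 = NULL) {
  if (is.null(m1)) m1 <- small_weight_mean(pool1, params1)
  if (is.null(m2)) m2 <- small_weight_mean(pool2, params2)
  s <- function(pool) list(
    e = sum(sqrt(hz_to_per_ms(pool$rate_exc)) * pool$w_exc),
    i = sum(sqrt(hz_to_per_ms(pool$rate_inh)) * pool$w_inh))
  s1 <- s(pool1); s2 <- s(pool2)
  de1 <- params1$v_exc - m1; di1 <- params1$v_inh - m1
  de2 <- params2$v_exc - m2; di2 <- params2$v_inh - m2
  num <- correlation$rho_ee_cross * de1 * de2 * s1$e * s2$e +
         correlation$rho_ii_cross * di1 * di2 * s1$i * s2$i +
         correlation$rho_ei_cross * (de1 * di2 * s1$e * s2$i +
                                     di1 * de2 * s1$i * s2$e)
  den <- 1 / params1$tau + 1 / params2$tau +
    sum(hz_to_per_ms(pool1$rate_exc) * (pool1$w_exc + pool2$w_exc)) +
    sum(hz_to_per_ms(pool1$rate_inh) * (pool1$w_inh + pool2$w_inh))
  num / den
}

## ---------------------------------------------------------------------------
## Interpretable reductions: q, kappa, rho_V, skewness approximations
## ---------------------------------------------------------------------------

#' Excitatory share of voltage variability
#'
#' The fraction of the small-weight voltage variance contributed by
#' excitation:
#' \deqn{q = \frac{\sum_k r_{e,k} w_{e,k}^2 (V_e - m)^2}
#'   {\sum_k r_{e,k} w_{e,k}^2 (V_e-m)^2 + \sum_l r_{i,l} w_{i,l}^2 (V_i-m)^2}}
#' Decreasing in the mean depolarization `m`: at rest the excitatory
#' driving force dominates, while depolarization shifts weight toward
#' inhibition.
#'
#' @param pool An [input_pool()].
#' @param params A [neuron_params()].
#' @param m Mean voltage, mV (defaults to the small-weight mean).
#' @return `q` in \[0, 1\] (1 without inhibition).
#' @export
excitatory_share_q <- function(pool, params, m = NULL) {
  if (is.null(m)) m <- small_weight_mean(pool, params)
  d_e <- sum(pool$rate_exc * pool$w_exc^2) * (params$v_exc - m)^2
  d_i <- sum(pool$rate_inh * pool$w_inh^2) * (params$v_inh - m)^2
  if (d_e + d_i <= 0) stop("all-zero drive: q is undefined")
  d_e / (d_e + d_i)
}

#' Voltage correlation from shared asynchronous inputs
#'
#' For two identical neurons sharing fractions `f_e` and `f_i` of their
#' asynchronous inputs, `rho_V = f_e q + f_i (1 - q)` where `q` is the
#' excitatory share of variability.
#'
#' @param f_e,f_i Shared fractions in \[0, 1\].
#' @param q Excitatory share, from [excitatory_share_q()].
#' @return The voltage correlation, in \[0, 1\].
#' @export
shared_input_correlation <- function(f_e, f_i, q) {
  stopifnot(f_e >= 0, f_e <= 1, f_i >= 0, f_i <= 1, q >= 0, q <= 1)
  f_e * q + f_i * (1 - q)
}

#' Synchrony gain kappa
#'
#' Ratio of the fully synchronous to the asynchronous small-weight variance,
#' `kappa = M^(rho=1) / M^(rho=0)`.  Case `"i"` (independent excitatory and
#' inhibitory synchrony): `kappa = Ke q + Ki (1 - q)`.  Case `"ii"`
#' (uniformly correlated excitation and inhibition, equal rates): from the
#' variance-ratio definition,
#' `kappa = (Ke we (Ve-m) + Ki wi (Vi-m))^2 / (Ke we^2 (Ve-m)^2 +
#'  Ki wi^2 (Vi-m)^2)`, equal to `(sqrt(Ke q) - sqrt(Ki (1-q)))^2`; the
#' partial cancellation by synchronous inhibition lowers kappa increasingly
#' with depolarization.  With excitation alone both cases give `kappa = Ke`.
#'
#' @param pool An [input_pool()] (uniform weights per pool).
#' @param params A [neuron_params()].
#' @param m Mean voltage, mV (small-weight default).
#' @param case `"i"` or `"ii"`.
#' @return The dimensionless gain kappa.
#' @export
kappa_ratio <- function(pool, params, m = NULL, case = c("ii", "i")) {
  case <- match.arg(case)
  if (is.null(m)) m <- small_weight_mean(pool, params)
  q <- excitatory_share_q(pool, params, m)
  if (case == "i") return(pool$n_exc * q + pool$n_inh * (1 - q))
  w_e <- uniform_or_stop(pool$w_exc, "excitatory weights")
  w_i <- uniform_or_stop(pool$w_inh, "inhibitory weights")
  r_e <- uniform_or_stop(pool$rate_exc, "excitatory rates")
  r_i <- uniform_or_stop(pool$rate_inh, "inhibitory rates")
  de <- params$v_exc - m; di <- params$v_inh - m
  num <- (pool$n_exc * sqrt(r_e) * w_e * de +
          pool$n_inh * sqrt(r_i) * w_i * di)^2
  den <- pool$n_exc * r_e * w_e^2 * de^2 + pool$n_inh * r_i * w_i^2 * di^2
  num / den
}

#' Voltage correlation under cross-neuron synchrony
#'
#' For two identical neurons with within-neuron spiking correlation `rho`,
#' cross-neuron correlation `rho_cross` and synchrony gain `kappa`:
#' \deqn{\rho_V = \frac{\rho'}{(1-\rho)/\kappa + \rho} \le \rho'/\rho}
#' Linear in `kappa` for small `kappa rho` (excitation alone:
#' `rho_V ~ rho' Ke`), saturating at `rho'/rho` for large `kappa`.
#'
#' @param rho Within-neuron pairwise spiking correlation, in (0, 1\].
#' @param rho_cross Cross-neuron coefficient, `<= rho`.
#' @param kappa Synchrony gain from [kappa_ratio()].
#' @return The voltage correlation.
#' @export
synchronous_voltage_correlation <- function(rho, rho_cross, kappa) {
  stopifnot(rho_cross >= 0, rho_cross <= rho + 1e-12, rho <= 1, kappa > 0)
  if (rho == 0) stop("degenerate: rho = 0 (use the shared-input route)")
  rho_cross / ((1 - rho) / kappa + rho)
}

#' Skewness of the asynchronous current-based reference model
#'
#' `s[V] = (2 sqrt(2) / 3) / sqrt(Ke re tau)`: the voltage skewness of the
#' current-based analogue (constant driving force) under asynchronous
#' excitatory drive, inherited from the Poissonian input-count fluctuations
#' over the membrane timescale.
#'
#' @param k_e Number of excitatory inputs.
#' @param rate_hz Per-input rate, Hz.
#' @param tau Membrane time constant, ms.
#' @return Dimensionless skewness.
#' @export
skewness_current_based <- function(k_e, rate_hz, tau) {
  x <- k_e * hz_to_per_ms(rate_hz) * tau
  if (x <= 0) stop("zero drive: skewness undefined")
  (2 * sqrt(2) / 3) / sqrt(x)
}

#' Approximate skewness of the conductance-based neuron with synchrony
#'
#' Excitation-only approximation valid for `Ke we ~ 1` under the
#' beta-binomial synchrony model (third-order coefficient
#' `rho_e3 = 2 rho_e^2 / (1 + rho_e)`):
#' \deqn{S[V] \simeq s[V] \frac{1 - 2 r_e \tau}{1 + r_e \tau}
#'   \sqrt{1 + \rho_e K_e}}
#' with `s[V]` the current-based reference ([skewness_current_based()]).
#' Positive below `r_e = 1/(2 tau)` and mildly negative beyond; synchrony
#' amplifies the spontaneous-regime skew by `sqrt(1 + rho_e Ke)`.
#'
#' @param k_e Number of excitatory inputs.
#' @param rate_hz Per-input rate, Hz.
#' @param tau Membrane time constant, ms.
#' @param rho_e Pairwise spiking correlation of the excitatory pool.
#' @return Dimensionless skewness.
#' @export
skewness_conductance_approx <- function(k_e, rate_hz, tau, rho_e = 0) {
  stopifnot(rho_e >= 0, rho_e <= 1)
  r <- hz_to_per_ms(rate_hz)
  skewness_current_based(k_e, rate_hz, tau) *
    (1 - 2 * r * tau) / (1 + r * tau) * sqrt(1 + rho_e * k_e)
}

#' Analytic voltage-correlation pipeline
#'
#' Convenience chain for the synchronous two-neuron case: small-weight mean
#' `m`, excitatory share `q`, synchrony gain `kappa` (case ii by default),
#' then `rho_V` via [synchronous_voltage_correlation()].
#'
#' @param pool An [input_pool()].
#' @param params A [neuron_params()].
#' @param rho,rho_cross Within- and cross-neuron spiking correlations.
#' @param case `kappa` case, `"ii"` (uniformly correlated E/I) or `"i"`.
#' @return A list with `m`, `q`, `kappa`, `rho_v`.
#' @export
voltage_correlation_pipeline <- function(pool, params, rho, rho_cross,
                                         case = c("ii", "i")) {
  case <- match.arg(case)
  m <- small_weight_mean(pool, params)
  q <- excitatory_share_q(pool, params, m)
  kap <- kappa_ratio(pool, params, m, case)
  list(m = m, q = q, kappa = kap,
       rho_v = synchronous_voltage_correlation(rho, rho_cross, kap))
}

#' Full analytic moment report for a synchrony model
#'
#' Assembles mean, variance, covariance/correlation (two-neuron models),
#' third moment and skewness from the exact closed forms over the model's
#' jump law.
#'
#' @param model A `synchrony_model`.
#' @param params [neuron_params()] (recycled over neurons).
#' @param ... Passed to [jump_distribution()].
#' @return A [moment_report()] with method `"exact"`.
#' @export
moment_report_analytic <- function(model, params, ...) {
  jd <- jump_distribution(model, ...)
  nn <- n_neurons(jd)
  pl <- as_params_list(params, nn)
  means <- vars <- thirds <- skews <- numeric(nn)
  for (a in seq_len(nn)) {
    jda <- if (nn > 1L) jd_marginal(jd, a) else jd
    means[a] <- stationary_mean(jda, pl[[a]])
    vars[a] <- stationary_variance(jda, pl[[a]])
    thirds[a] <- third_central_moment(jda, pl[[a]], mean = means[a],
                                      variance = vars[a])
    skews[a] <- thirds[a] / vars[a]^1.5
  }
  covv <- NA_real_; corr <- NA_real_
  if (nn == 2L) {
    covv <- stationary_covariance(jd, pl[[1]], pl[[2]])
    corr <- covv / sqrt(vars[1] * vars[2])
  }
  moment_report(means, vars, covv, thirds, skews, corr, method = "exact")
}
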