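#' Pool of synaptic inputs to one neuron
#'
#' Describes the excitatory and inhibitory synapses impinging on a neuron:
#' counts, per-input spiking rates (Hz) and dimensionless synaptic weights.
#' Rates and weights may be scalars (uniform pools) or per-input vectors.
#'
#' @param n_exc,n_inh Input counts Ke, Ki.
#' @param rate_exc,rate_inh Per-input spiking rates, Hz.
#' @param w_exc,w_inh Dimensionless synaptic weights (w = g * tau_s / C).
#' @return An object of class `input_pool`.
#' @export
input_pool <- function(n_exc, n_inh = 0, rate_exc = 0, rate_inh = 0,
                       w_exc = 0, w_inh = 0) {
  n_exc <- as.integer(n_exc); n_inh <- as.integer(n_inh)
  stopifnot(n_exc >= 0, n_inh >= 0)
  chk <- function(v, n, what) {
    if (!length(v) %in% c(1L, max(n, 1L)))
      stop(sprintf("%s must be scalar or length %d", what, n))
    if (any(v < 0) || any(!is.finite(v))) stop(sprintf("%s must be finite and >= 0", what))
    if (n == 0L) return(numeric(0))
    rep_len(as.numeric(v), n)
  }
  structure(list(
    n_exc = n_exc, n_inh = n_inh,
    rate_exc = chk(rate_exc, n_exc, "rate_exc"),
    rate_inh = chk(rate_inh, n_inh, "rate_inh"),
    w_exc = chk(w_exc, n_exc, "w_exc"),
    w_inh = chk(w_inh, n_inh, "w_inh")), class = "input_pool")
}

#' @export
print.input_pool <- function(x, ...) {
  cat(sprintf("Input pool: Ke = %d (r ~ %.3g Hz, w ~ %.3g), Ki = %d (r ~ %.3g Hz, w ~ %.3g)\n",
              x$n_exc, mean(x$rate_exc), mean(x$w_exc),
              x$n_inh, if (x$n_inh) mean(x$rate_inh) else 0,
              if (x$n_inh) mean(x$w_inh) else 0))
  invisible(x)
}

uniform_or_stop <- function(v, what) {
  if (length(v) == 0L) return(0)
  if (diff(range(v)) > 0)
    stop(sprintf("exchangeable synchrony models require uniform %s", what))
  v[1L]
}

#' Pairwise spiking correlation structure
#'
#' Uniform pairwise spiking correlation coefficients between inputs to the
#' same neuron (`rho_*`) and to distinct neurons (`rho_*_cross`), by pool
#' pair: `ee`, `ii` and the excitation-inhibition cross term `ei`.  All
#' coefficients lie in \[0, 1\]; feasibility requires
#' `rho_ei <= sqrt(rho_ee * rho_ii)` and cross coefficients no larger than
#' their within counterparts.
#'
#' @param rho_ee,rho_ii,rho_ei Within-neuron coefficients.
#' @param rho_ee_cross,rho_ii_cross,rho_ei_cross Cross-neuron coefficients.
#' @return An object of class `correlation_structure`.
#' @export
correlation_structure <- function(rho_ee = 0, rho_ii = 0, rho_ei = 0,
                                  rho_ee_cross = 0, rho_ii_cross = 0,
                                  rho_ei_cross = 0) {
  v <- c(rho_ee, rho_ii, rho_ei, rho_ee_cross, rho_ii_cross, rho_ei_cross)
  if (any(v < 0) || any(v > 1))
    stop("correlation coefficients must lie in [0, 1]")
  if (rho_ei > sqrt(rho_ee * rho_ii) + 1e-12)
    stop("infeasible structure: rho_ei must satisfy rho_ei <= sqrt(rho_ee * rho_ii)")
  if (rho_ee_cross > rho_ee + 1e-12 || rho_ii_cross > rho_ii + 1e-12 ||
      rho_ei_cross > max(rho_ei, sqrt(rho_ee * rho_ii)) + 1e-12)
    stop("cross-neuron coefficients cannot exceed their within-neuron counterparts")
  structure(list(rho_ee = rho_ee, rho_ii = rho_ii, rho_ei = rho_ei,
                 rho_ee_cross = rho_ee_cross, rho_ii_cross = rho_ii_cross,
                 rho_ei_cross = rho_ei_cross),
            class = "correlation_structure")
}

## ---------------------------------------------------------------------------
## Beta-binomial synchrony algebra
## ---------------------------------------------------------------------------

#' Pairwise spiking correlation of the beta-binomial synchrony model
#'
#' In the exchangeable beta-binomial model, synchrony is governed by a single
#' parameter `beta > 0` and the pairwise spiking correlation between any two
#' inputs is `rho = 1/(1 + beta)`; `beta -> Inf` recovers asynchrony.
#'
#' @param beta Positive synchrony parameter (may be `Inf`).
#' @return The pairwise correlation coefficient.
#' @export
pairwise_rho_from_beta <- function(beta) {
  stopifnot(is.numeric(beta), all(beta >= 0))
  1 / (1 + beta)
}

#' @rdname pairwise_rho_from_beta
#' @param rho Pairwise correlation in (0, 1\]; `rho = 0` maps to `beta = Inf`.
#' @export
beta_from_rho <- function(rho) {
  stopifnot(is.numeric(rho), all(rho >= 0), all(rho <= 1))
  ifelse(rho == 0, Inf, 1 / rho - 1)
}

#' Higher-order spiking correlation of the beta-binomial model
#'
#' The n-input coactivation coefficient of the exchangeable beta-binomial
#' model is `rho_{1..n} = prod_{k=1}^{n-1} k/(beta + k)
#' = Gamma(1+beta) Gamma(n) / Gamma(n+beta)`, evaluated in log-gamma space;
#' it decreases with `n` and decays like `n^-beta`.
#'
#' @param n Number of inputs considered (n >= 1).
#' @param beta Positive synchrony parameter.
#' @return The coefficient, in \[0, 1\] (1 for `n = 1`).
#' @export
higher_order_rho <- function(n, beta) {
  stopifnot(all(n >= 1), all(beta >= 0))
  ln <- max(length(n), length(beta))
  n <- rep_len(n, ln); beta <- rep_len(beta, ln)
  out <- numeric(ln)
  inf <- is.infinite(beta)
  out[inf] <- as.numeric(n[inf] == 1)
  out[!inf] <- exp(lgamma(1 + beta[!inf]) + lgamma(n[!inf]) -
                     lgamma(n[!inf] + beta[!inf]))
  out[n == 1] <- 1
  out
}

#' Collective event rate of a synchronous input pool
#'
#' Rate (Hz) of synaptic events in which at least one of `n_inputs`
#' exchangeable beta-binomial inputs with individual rate `rate_hz`
#' activates: `rate_hz * beta * (digamma(beta + K) - digamma(beta))`.  Sublinear
#' (logarithmic) in K for finite beta, reducing to `K * r` as `beta -> Inf`.
#'
#' @param n_inputs Number of inputs K (>= 1).
#' @param rate_hz Per-input spiking rate, Hz.
#' @param beta Positive synchrony parameter (may be `Inf`).
#' @return Collective event rate, Hz.
#' @export
collective_rate <- function(n_inputs, rate_hz, beta) {
  stopifnot(all(n_inputs >= 1), all(rate_hz >= 0), all(beta >= 0))
  ln <- max(length(n_inputs), length(rate_hz), length(beta))
  n_inputs <- rep_len(n_inputs, ln); rate_hz <- rep_len(rate_hz, ln)
  beta <- rep_len(beta, ln)
  out <- numeric(ln)
  inf <- is.infinite(beta)
  out[inf] <- (n_inputs * rate_hz)[inf]
  out[beta == 0] <- rate_hz[beta == 0]   # full synchrony: one shared volley
  fin <- !inf & beta > 0
  out[fin] <- rate_hz[fin] * beta[fin] *
    (digamma(beta[fin] + n_inputs[fin]) - digamma(beta[fin]))
  out
}

#' Per-event coactivation count law of the beta-binomial model
#'
#' Distribution of the number of coactive inputs per synaptic event for K
#' exchangeable inputs in the alpha -> 0+ beta-binomial limit, conditioned
#' on at least one active input:
#' `P(n) proportional to choose(K, n) * Beta(n, beta + K - n)`, `1 <= n <= K`,
#' computed in log space.  This is the "rich-gets-richer" cluster-size law
#' whose mean satisfies `K / E[n] = beta * (digamma(beta+K) - digamma(beta))`.
#'
#' @param n_inputs Number of inputs K (>= 1).
#' @param beta Positive synchrony parameter (`Inf` gives a point mass at 1).
#' @return Numeric vector of probabilities over counts `1:K`.
#' @export
event_count_pmf <- function(n_inputs, beta) {
  K <- as.integer(n_inputs)
  stopifnot(K >= 1, beta >= 0)
  if (is.infinite(beta)) return(c(1, rep(0, K - 1L)))
  if (beta == 0) return(c(rep(0, K - 1L), 1))  # full synchrony: all coactive
  n <- seq_len(K)
  lp <- lchoose(K, n) + lbeta(n, beta + K - n)
  p <- exp(lp - max(lp))
  p / sum(p)
}

## count factorial moments E[n], E[n(n-1)], E[n(n-1)(n-2)] of a count pmf
count_fmoments <- function(pmf) {
  n <- seq_along(pmf)
  c(sum(pmf * n), sum(pmf * n * (n - 1)), sum(pmf * n * (n - 1) * (n - 2)))
}

## ---------------------------------------------------------------------------
## Event components: every synchrony model is a superposition of independent
## compound-Poisson components.  Two flavors:
##   - atoms: explicit finite jump support (asynchronous and shared inputs);
##   - bb:    an exchangeable beta-binomial count law over a union of input
##            groups; the active inputs are a uniform random subset, so the
##            per-group counts follow a multivariate hypergeometric split.
## ---------------------------------------------------------------------------

comp_atoms <- function(rate_hz, prob, w_e, w_i, n_neurons) {
  list(flavor = "atoms", rate_hz = rate_hz, prob = prob / sum(prob),
       w_e = matrix(w_e, ncol = n_neurons),
       w_i = matrix(w_i, ncol = n_neurons))
}

## groups: data.frame(neuron, type ("e"/"i"), K, w); pmf over counts 1..sum(K)
comp_bb <- function(rate_hz, pmf, groups) {
  stopifnot(sum(groups$K) == length(pmf))
  list(flavor = "bb", rate_hz = rate_hz, pmf = pmf, groups = groups)
}

model_components <- function(model) model$components

#' Synchrony models
#'
#' A synchrony model pairs [input_pool()]s with a parametric law for which
#' inputs coactivate at each synaptic event.  Constructors:
#'
#' * `sync_asynchronous(pool)`: every input spikes independently; each event
#'   carries a single active input.
#' * `sync_beta_binomial(pool, rho_e, rho_i, rho_ei)`: one neuron whose
#'   excitatory and inhibitory pools are exchangeable beta-binomial with
#'   pairwise correlations `rho_e`, `rho_i`.  `rho_ei = 0` makes the pools
#'   independent; `rho_ei = rho_e = rho_i` merges them into one exchangeable
#'   pool (uniformly correlated excitation and inhibition).  Intermediate
#'   `rho_ei` is realized as a mixture of a merged-pool component and
#'   pool-private components, calibrated in closed form.
#' * `sync_shared_inputs(pool, f_e, f_i)`: two identical neurons receiving
#'   asynchronous inputs and sharing a fraction `f_e` of excitatory and
#'   `f_i` of inhibitory inputs (shared counts rounded half up).
#' * `sync_cross_neuron(pool, rho, rho_cross, structure)`: two identical
#'   neurons with uniform within-neuron correlation `rho` and cross-neuron
#'   correlation `rho_cross <= rho`; see [calibrate_cross_neuron()].
#'
#' @param pool An [input_pool()] (applies to each neuron).
#' @param rho_e,rho_i,rho_ei Within-neuron pairwise spiking correlations.
#' @param f_e,f_i Shared input fractions in \[0, 1\].
#' @return An object of class `synchrony_model` with fields `kind`, `pool`,
#'   `n_neurons`, `components` and kind-specific parameters.
#' @name synchrony_model
NULL

new_sync_model <- function(kind, pool, n_neurons, components, ...) {
  structure(list(kind = kind, pool = pool, n_neurons = n_neurons,
                 components = components, ...),
            class = "synchrony_model")
}

#' @export
print.synchrony_model <- function(x, ...) {
  cat(sprintf("Synchrony model '%s' over %d neuron(s); event rate %.4g Hz, %d component(s)\n",
              x$kind, x$n_neurons, model_event_rate(x), length(x$components)))
  invisible(x)
}

#' @rdname synchrony_model
#' @export
sync_asynchronous <- function(pool) {
  atoms <- async_atoms(pool)
  comp <- comp_atoms(atoms$rate_hz, atoms$prob, atoms$w_e, atoms$w_i, 1L)
  new_sync_model("asynchronous", pool, 1L, list(comp))
}

## asynchronous single-neuron atoms: one active input per event; inputs with
## zero weight never generate events (they are invisible to the neuron).
async_atoms <- function(pool) {
  re <- pool$rate_exc * (pool$w_exc > 0)
  ri <- pool$rate_inh * (pool$w_inh > 0)
  b <- sum(re) + sum(ri)
  if (b <= 0) stop("asynchronous model needs at least one input with positive rate and weight")
  ke <- which(re > 0); ki <- which(ri > 0)
  w_e <- c(pool$w_exc[ke], rep(0, length(ki)))
  w_i <- c(rep(0, length(ke)), pool$w_inh[ki])
  list(rate_hz = b, prob = c(re[ke], ri[ki]) / b, w_e = w_e, w_i = w_i)
}

#' @rdname synchrony_model
#' @export
sync_beta_binomial <- function(pool, rho_e = 0, rho_i = 0, rho_ei = 0) {
  correlation_structure(rho_ee = rho_e, rho_ii = rho_i, rho_ei = rho_ei)
  comps <- list()
  r_e <- uniform_or_stop(pool$rate_exc, "excitatory rates")
  r_i <- uniform_or_stop(pool$rate_inh, "inhibitory rates")
  w_e <- uniform_or_stop(pool$w_exc, "excitatory weights")
  w_i <- uniform_or_stop(pool$w_inh, "inhibitory weights")
  ge <- data.frame(neuron = 1L, type = "e", K = pool$n_exc, w = w_e)
  gi <- data.frame(neuron = 1L, type = "i", K = pool$n_inh, w = w_i)
  if (rho_ei == 0) {
    if (pool$n_exc > 0 && r_e > 0)
      comps <- c(comps, list(comp_bb(collective_rate(pool$n_exc, r_e, beta_from_rho(rho_e)),
                                     event_count_pmf(pool$n_exc, beta_from_rho(rho_e)), ge)))
    if (pool$n_inh > 0 && r_i > 0)
      comps <- c(comps, list(comp_bb(collective_rate(pool$n_inh, r_i, beta_from_rho(rho_i)),
                                     event_count_pmf(pool$n_inh, beta_from_rho(rho_i)), gi)))
  } else {
    if (abs(rho_e - rho_i) > 1e-12)
      stop("rho_ei > 0 requires rho_e == rho_i (exchangeable mixture construction)")
    if (abs(r_e - r_i) > 1e-12)
      stop("rho_ei > 0 requires equal excitatory and inhibitory rates")
    rho <- rho_e
    if (rho_ei > rho + 1e-12) stop("rho_ei cannot exceed the within-pool correlation")
    beta <- beta_from_rho(rho)
    N <- pool$n_exc + pool$n_inh
    ## mixture of a merged-pool component (carrying the e-i coactivation)
    ## and pool-private components.  All components share beta, so every
    ## within-pool coefficient is exactly 1/(1+beta) = rho for any split,
    ## and rho_ei = t * rho where t is the merged component's share of each
    ## input's activation rate.  Component rates follow in closed form from
    ## the per-input marginal r = b * P(X_k = 1).
    t <- rho_ei / rho
    pc_J <- count_fmoments(event_count_pmf(N, beta))[1] / N
    pc_e <- count_fmoments(event_count_pmf(pool$n_exc, beta))[1] / pool$n_exc
    pc_i <- count_fmoments(event_count_pmf(pool$n_inh, beta))[1] / pool$n_inh
    if (t > 0)
      comps <- c(comps, list(comp_bb(t * r_e / pc_J, event_count_pmf(N, beta),
                                     rbind(ge, gi))))
    if (t < 1)
      comps <- c(comps, list(
        comp_bb((1 - t) * r_e / pc_e, event_count_pmf(pool$n_exc, beta), ge),
        comp_bb((1 - t) * r_i / pc_i, event_count_pmf(pool$n_inh, beta), gi)))
  }
  if (!length(comps)) stop("model has no active inputs")
  new_sync_model("beta_binomial", pool, 1L, comps,
                 rho_e = rho_e, rho_i = rho_i, rho_ei = rho_ei)
}

#' @rdname synchrony_model
#' @export
sync_shared_inputs <- function(pool, f_e, f_i = f_e) {
  stopifnot(f_e >= 0, f_e <= 1, f_i >= 0, f_i <= 1)
  w_e <- uniform_or_stop(pool$w_exc, "excitatory weights")
  w_i <- uniform_or_stop(pool$w_inh, "inhibitory weights")
  r_e <- uniform_or_stop(pool$rate_exc, "excitatory rates")
  r_i <- uniform_or_stop(pool$rate_inh, "inhibitory rates")
  s_e <- floor(f_e * pool$n_exc + 0.5)  # round half up, documented
  s_i <- floor(f_i * pool$n_inh + 0.5)
  p_e <- pool$n_exc - s_e; p_i <- pool$n_inh - s_i
  rates <- c(shared_e = s_e * r_e, priv_e1 = p_e * r_e, priv_e2 = p_e * r_e,
             shared_i = s_i * r_i, priv_i1 = p_i * r_i, priv_i2 = p_i * r_i)
  keep <- rates > 0
  if (!any(keep)) stop("shared-input model has no active inputs")
  w_e_atoms <- rbind(c(w_e, w_e), c(w_e, 0), c(0, w_e), c(0, 0), c(0, 0), c(0, 0))
  w_i_atoms <- rbind(c(0, 0), c(0, 0), c(0, 0), c(w_i, w_i), c(w_i, 0), c(0, w_i))
  b <- sum(rates)
  comp <- comp_atoms(b, rates[keep],
                     w_e_atoms[keep, , drop = FALSE],
                     w_i_atoms[keep, , drop = FALSE], 2L)
  new_sync_model("shared_inputs", pool, 2L, list(comp),
                 f_e = f_e, f_i = f_i, n_shared_e = s_e, n_shared_i = s_i)
}

#' Calibrate a cross-neuron synchrony mixture
#'
#' Builds a generative model for two identical neurons whose inputs have
#' uniform within-neuron pairwise spiking correlation `rho` and a weaker
#' cross-neuron correlation `rho_cross`.  The construction superposes, per
#' input type, a *joint* beta-binomial component over the union of both
#' neurons' inputs and *private* per-neuron components, all sharing the
#' synchrony parameter `beta = 1/rho - 1`.  Because every component has the
#' same beta, the within-neuron correlation is exactly `rho` for any mixture
#' split, and the share of joint events that achieves the cross-neuron
#' target follows in closed form; implied coefficients match the targets to
#' machine precision (see [implied_rho()]).
#'
#' Two correlation structures are supported, mirroring the two physiological
#' cases: `"within_pool"` keeps excitation and inhibition independent
#' (rho_ei = 0, per-type joint/private mixtures) while `"uniform"` merges
#' excitatory and inhibitory pools so that all within-neuron pairs, including
#' excitation-inhibition pairs, share the correlation `rho` (this requires
#' equal excitatory and inhibitory rates).
#'
#' @param pool [input_pool()] received by each neuron.
#' @param rho Within-neuron pairwise correlation, in (0, 1\].
#' @param rho_cross Cross-neuron pairwise correlation, `0 <= rho_cross <= rho`.
#' @param structure `"within_pool"` (case i) or `"uniform"` (case ii).
#' @return A two-neuron `synchrony_model` of kind `"cross_mixture"`.
#' @export
calibrate_cross_neuron <- function(pool, rho, rho_cross,
                                   structure = c("within_pool", "uniform")) {
  structure <- match.arg(structure)
  stopifnot(rho > 0, rho <= 1, rho_cross >= 0)
  if (rho_cross > rho + 1e-12)
    stop("infeasible targets: rho_cross must not exceed rho")
  beta <- beta_from_rho(rho)
  t <- rho_cross / rho
  r_e <- uniform_or_stop(pool$rate_exc, "excitatory rates")
  r_i <- uniform_or_stop(pool$rate_inh, "inhibitory rates")
  w_e <- uniform_or_stop(pool$w_exc, "excitatory weights")
  w_i <- uniform_or_stop(pool$w_inh, "inhibitory weights")

  ## All components share beta, so within-neuron coefficients are exactly
  ## rho = 1/(1+beta) for any split.  The joint (shared across neurons)
  ## component carries a fraction t = rho_cross/rho of each input's
  ## activation rate, giving rho_cross = t * rho exactly; component event
  ## rates then follow from the per-input marginal r = b_c * E[count]/N_c.
  mixture <- function(g1, g2, r) {
    N <- sum(g1$K)
    pmf_j <- event_count_pmf(2L * N, beta)
    pmf_p <- event_count_pmf(N, beta)
    pc_j <- count_fmoments(pmf_j)[1] / (2 * N)
    pc_p <- count_fmoments(pmf_p)[1] / N
    out <- list()
    if (t > 0) out <- c(out, list(comp_bb(t * r / pc_j, pmf_j, rbind(g1, g2))))
    if (t < 1) out <- c(out, list(comp_bb((1 - t) * r / pc_p, pmf_p, g1),
                                  comp_bb((1 - t) * r / pc_p, pmf_p, g2)))
    out
  }

  if (structure == "within_pool") {
    comps <- list()
    if (pool$n_exc > 0 && r_e > 0) {
      g1 <- data.frame(neuron = 1L, type = "e", K = pool$n_exc, w = w_e)
      g2 <- g1; g2$neuron <- 2L
      comps <- c(comps, mixture(g1, g2, r_e))
    }
    if (pool$n_inh > 0 && r_i > 0) {
      g1 <- data.frame(neuron = 1L, type = "i", K = pool$n_inh, w = w_i)
      g2 <- g1; g2$neuron <- 2L
      comps <- c(comps, mixture(g1, g2, r_i))
    }
  } else {
    if (pool$n_inh > 0 && abs(r_e - r_i) > 1e-12)
      stop("uniform (case ii) structure requires equal excitatory and inhibitory rates")
    g1 <- data.frame(neuron = c(1L, 1L), type = c("e", "i"),
                     K = c(pool$n_exc, pool$n_inh), w = c(w_e, w_i))
    g1 <- g1[g1$K > 0, ]
    g2 <- g1; g2$neuron <- 2L
    comps <- mixture(g1, g2, r_e)
  }
  if (!length(comps)) stop("model has no active inputs")
  new_sync_model("cross_mixture", pool, 2L, comps,
                 rho = rho, rho_cross = rho_cross, structure_case = structure)
}

#' @rdname calibrate_cross_neuron
#' @param ... Passed to `calibrate_cross_neuron()`.
#' @export
sync_cross_neuron <- function(...) calibrate_cross_neuron(...)

## ---------------------------------------------------------------------------
## Model-level accessors
## ---------------------------------------------------------------------------

#' Total synaptic event rate of a model
#'
#' @param model A `synchrony_model`.
#' @return Event rate b_A in Hz for the modeled neuron set.
#' @export
model_event_rate <- function(model)
  sum(vapply(model$components, function(c) c$rate_hz, numeric(1)))

## activation probability per event of a specific input (neuron/type) under
## each component, weighted by component rates -> per-input spiking rate
#' Per-input spiking rate implied by a synchrony model
#'
#' Recovers the individual input rate `r_k = b * P(X_k = 1)` (per event) for an
#' input of the given type; the inverse relation used to calibrate event
#' rates from target per-input rates.
#'
#' @param model A `synchrony_model`.
#' @param neuron Neuron index owning the input.
#' @param type `"e"` or `"i"`.
#' @param index Input index within its pool (matters only for heterogeneous
#'   asynchronous pools).
#' @return Spiking rate in Hz.
#' @export
input_rate_from_event_rate <- function(model, neuron = 1L, type = c("e", "i"),
                                       index = 1L) {
  type <- match.arg(type)
  if (model$kind == "asynchronous") {
    r <- if (type == "e") model$pool$rate_exc[index] else model$pool$rate_inh[index]
    w <- if (type == "e") model$pool$w_exc[index] else model$pool$w_inh[index]
    return(if (w > 0) r else 0)
  }
  if (model$kind == "shared_inputs") {
    return(if (type == "e") model$pool$rate_exc[1L] else model$pool$rate_inh[1L])
  }
  tot <- 0
  for (comp in model$components) {
    if (comp$flavor != "bb") next
    g <- comp$groups
    if (!any(g$neuron == neuron & g$type == type)) next
    N <- sum(g$K)
    tot <- tot + comp$rate_hz * count_fmoments(comp$pmf)[1] / N
  }
  tot
}

#' Pairwise spiking correlation implied by a model
#'
#' Evaluates the normalized coactivation coefficient
#' `rho = E[Xk Xl] / sqrt(E[Xk] E[Xl])` (expectations per synaptic event)
#' between two inputs identified by neuron and pool type, from the model's
#' component decomposition.  Used to verify calibrations.
#'
#' @param model A `synchrony_model` built from beta-binomial components.
#' @param neuron1,neuron2 Neuron owning each input.
#' @param type1,type2 Pool type of each input (`"e"` or `"i"`).
#' @return The implied pairwise coefficient.
#' @export
implied_rho <- function(model, neuron1 = 1L, type1 = "e",
                        neuron2 = 1L, type2 = "e") {
  b <- model_event_rate(model)
  p1 <- input_rate_from_event_rate(model, neuron1, type1) / b
  p2 <- input_rate_from_event_rate(model, neuron2, type2) / b
  if (p1 <= 0 || p2 <= 0) stop("inputs with zero rate have undefined correlation")
  exy <- 0
  for (comp in model$components) {
    if (comp$flavor != "bb") next
    g <- comp$groups
    has1 <- any(g$neuron == neuron1 & g$type == type1)
    has2 <- any(g$neuron == neuron2 & g$type == type2)
    if (!(has1 && has2)) next
    N <- sum(g$K)
    if (N < 2) next
    fm <- count_fmoments(comp$pmf)
    exy <- exy + (comp$rate_hz / b) * fm[2] / (N * (N - 1))
  }
  exy / sqrt(p1 * p2)
}

#' Pair event rate from individual rates and input overlap
#'
#' The event rate seen by a pair of neurons is
#' `b12 = (b1 + b2) / (1 + q12)` where `q12 = P(W1 > 0, W2 > 0 | W1+W2 > 0)`
#' is the probability that both neurons receive input at a common event.
#' The bounds `max(b1, b2) <= b12 <= b1 + b2` always hold.
#'
#' @param b1,b2 Individual event rates, Hz.
#' @param q12 Synchronous-event probability; feasibility requires
#'   `0 <= q12 <= min(b1, b2)/max(b1, b2)`.
#' @return The pair event rate, Hz.
#' @export
pair_event_rate <- function(b1, b2, q12) {
  stopifnot(b1 >= 0, b2 >= 0)
  hi <- if (max(b1, b2) > 0) min(b1, b2) / max(b1, b2) else 0
  if (q12 < 0 || q12 > hi + 1e-12)
    stop(sprintf("q12 must lie in [0, %.6g] for these rates", hi))
  (b1 + b2) / (1 + q12)
}

## ---------------------------------------------------------------------------
## Exact jump law of a model
## ---------------------------------------------------------------------------

#' Jump distribution implied by a synchrony model
#'
#' Enumerates the exact finite-support law of the per-event jump vectors
#' `(W_e,a, W_i,a)` for the model's neuron set, together with the event rate
#' `b_A`.  Beta-binomial components are expanded over their count law with
#' hypergeometric splits across input groups; a relative probability-mass
#' truncation (`tol`) keeps supports finite for large pools.
#'
#' @param model A `synchrony_model`.
#' @param neurons Optional subset of neurons (defaults to all); subsampling
#'   follows the marginal law via [jd_marginal()].
#' @param tol Discarded probability-mass bound for support truncation.
#' @param max_atoms Guard on support size.
#' @return A [jump_dist()].
#' @export
jump_distribution <- function(model, neurons = NULL, tol = 1e-13,
                              max_atoms = 500000L) {
  b <- model_event_rate(model)
  nn <- model$n_neurons
  parts <- lapply(model$components, function(comp) {
    if (comp$flavor == "atoms") {
      list(prob = comp$prob * comp$rate_hz / b, w_e = comp$w_e, w_i = comp$w_i)
    } else {
      at <- bb_component_atoms(comp, nn, tol, max_atoms)
      list(prob = at$prob * comp$rate_hz / b, w_e = at$w_e, w_i = at$w_i)
    }
  })
  jd <- jump_dist(unlist(lapply(parts, `[[`, "prob")),
                  do.call(rbind, lapply(parts, `[[`, "w_e")),
                  do.call(rbind, lapply(parts, `[[`, "w_i")),
                  rate_hz = b)
  jd <- jd_compress(jd)
  if (!is.null(neurons)) jd <- jd_marginal(jd, neurons)
  jd
}

## expand one beta-binomial component into jump atoms: enumerate total count
## n, then split counts across groups by multivariate hypergeometric weights.
bb_component_atoms <- function(comp, n_neurons, tol, max_atoms) {
  g <- comp$groups
  pmf <- comp$pmf
  keep_n <- which(pmf > 0)
  ## truncate negligible tail mass (renormalized)
  o <- order(pmf[keep_n], decreasing = TRUE)
  cum <- cumsum(pmf[keep_n][o])
  keep_n <- sort(keep_n[o][seq_len(which(cum >= 1 - tol)[1])])
  pmf_t <- pmf[keep_n] / sum(pmf[keep_n])

  rows_p <- list(); rows_e <- list(); rows_i <- list(); ridx <- 0L
  for (j in seq_along(keep_n)) {
    n <- keep_n[j]
    splits <- hyper_splits(n, g$K)      # matrix: rows = group count vectors
    pr <- splits$prob * pmf_t[j]
    cnt <- splits$counts
    we <- matrix(0, nrow(cnt), n_neurons)
    wi <- matrix(0, nrow(cnt), n_neurons)
    for (k in seq_len(nrow(g))) {
      if (g$type[k] == "e") we[, g$neuron[k]] <- we[, g$neuron[k]] + cnt[, k] * g$w[k]
      else                  wi[, g$neuron[k]] <- wi[, g$neuron[k]] + cnt[, k] * g$w[k]
    }
    ridx <- ridx + 1L
    rows_p[[ridx]] <- pr; rows_e[[ridx]] <- we; rows_i[[ridx]] <- wi
    if (sum(vapply(rows_p, length, integer(1))) > max_atoms)
      stop("jump-law support too large; use jd_empirical() on model_sampler() instead")
  }
  list(prob = unlist(rows_p), w_e = do.call(rbind, rows_e),
       w_i = do.call(rbind, rows_i))
}

## multivariate hypergeometric: all ways to split n active among groups of
## sizes K, with probabilities prod(choose(K_g, n_g)) / choose(sum(K), n)
hyper_splits <- function(n, K) {
  cnt <- matrix(n, 1L, 1L)
  if (length(K) > 1L) {
    cnt <- matrix(0L, 0L, 0L)
    grid <- list()
    for (k in seq_along(K)) grid[[k]] <- 0:min(n, K[k])
    cnt <- as.matrix(expand.grid(grid))
    cnt <- cnt[rowSums(cnt) == n, , drop = FALSE]
  }
  lp <- -lchoose(sum(K), n)
  for (k in seq_along(K)) lp <- lp + lchoose(K[k], cnt[, k])
  prob <- exp(lp)
  keep <- prob > 0
  list(counts = cnt[keep, , drop = FALSE], prob = prob[keep])
}

## ---------------------------------------------------------------------------
## Faulty synaptic transmission
## ---------------------------------------------------------------------------

#' Apply all-or-none synaptic failure to a model
#'
#' Thins every input's activations independently with success probability
#' `p`: a spike is transmitted with probability `p` and fails otherwise.
#' Effective per-input rates scale as `p * r`, pairwise spiking correlations
#' as `sqrt(p_a p_b) * rho`, and the n-input coefficients as
#' `p^(n-1) * rho_{1..n}`.  For beta-binomial components the thinned count
#' law is computed exactly (binomial thinning of the count pmf, renormalized
#' over surviving events); events losing all their spikes are dropped, which
#' lowers the event rate accordingly.
#'
#' @param model A `synchrony_model`.
#' @param p_success Transmission probability in (0, 1\] (uniform across
#'   inputs).
#' @return The transformed `synchrony_model` (same kind).
#' @export
apply_synaptic_failure <- function(model, p_success) {
  stopifnot(p_success > 0, p_success <= 1)
  if (p_success == 1) return(model)
  p <- p_success
  comps <- lapply(model$components, function(comp) {
    if (comp$flavor == "bb") {
      N <- length(comp$pmf)
      pmf2 <- numeric(N)
      for (k in seq_len(N)) {
        n <- k:N
        pmf2[k] <- sum(comp$pmf[n] * dbinom(k, n, p))
      }
      surv <- sum(pmf2)
      comp$pmf <- pmf2 / surv
      comp$rate_hz <- comp$rate_hz * surv
      comp
    } else {
      ## atoms represent single-input events (asynchronous) or shared-input
      ## events transmitted independently to each listed neuron
      active <- (comp$w_e > 0) + (comp$w_i > 0)    # per atom x neuron
      n_tgt <- rowSums(active > 0)
      if (all(n_tgt == 1L)) {
        comp$rate_hz <- comp$rate_hz * p
        comp
      } else {
        ## split multi-neuron atoms over transmission outcomes
        probs <- c(); we <- NULL; wi <- NULL
        for (a in seq_along(comp$prob)) {
          tgt <- which(active[a, ] > 0)
          outc <- expand.grid(rep(list(c(TRUE, FALSE)), length(tgt)))
          for (r in seq_len(nrow(outc))) {
            on <- unlist(outc[r, ])
            if (!any(on)) next
            pr <- prod(ifelse(on, p, 1 - p))
            row_e <- comp$w_e[a, ]; row_i <- comp$w_i[a, ]
            row_e[tgt[!on]] <- 0; row_i[tgt[!on]] <- 0
            probs <- c(probs, comp$prob[a] * pr)
            we <- rbind(we, row_e); wi <- rbind(wi, row_i)
          }
        }
        surv <- sum(probs)
        comp$rate_hz <- comp$rate_hz * surv
        comp$prob <- probs / surv
        comp$w_e <- we; comp$w_i <- wi
        comp
      }
    }
  })
  out <- model
  out$components <- comps
  out$failure_p <- p * if (is.null(model$failure_p)) 1 else model$failure_p
  ## implied targets after thinning
  for (f in c("rho_e", "rho_i", "rho_ei", "rho", "rho_cross"))
    if (!is.null(out[[f]])) out[[f]] <- out[[f]] * p
  out$pool$rate_exc <- out$pool$rate_exc * p
  out$pool$rate_inh <- out$pool$rate_inh * p
  out
}
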