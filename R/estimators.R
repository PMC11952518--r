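#' Estimator configuration
#'
#' @param burn_in_ms Initial transient discarded before averaging, ms.
#'   The default 20 tau (300 ms at tau = 15 ms) leaves less than e^-20 of
#'   initial-condition weight.
#' @param batches Number of contiguous batches for batch-means standard
#'   errors.
#' @param bootstrap Number of seeded bootstrap resamples (over batches) for
#'   skewness and correlation standard errors.
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(burn_in_ms = 300, batches = 50L,
                             bootstrap = 1000L) {
  stopifnot(burn_in_ms >= 0, batches >= 2L, bootstrap >= 10L)
  structure(list(burn_in_ms = burn_in_ms, batches = as.integer(batches),
                 bootstrap = as.integer(bootstrap)),
            class = "estimator_config")
}

## exact time integrals of V^p (p = 1..3) and the pair product V1*V2 over
## the inter-event exponential segments of an event-anchored trace.
## Returns per-segment integral matrices; columns are per neuron (and the
## last column the pair product when the trace has two neurons).
segment_integrals <- function(trace, t_from, t_to) {
  nn <- length(trace$v0)
  tau <- vapply(trace$params, `[[`, numeric(1), "tau")
  ig  <- vapply(trace$params, `[[`, numeric(1), "i_ext_over_g")
  anchor_t <- c(trace$horizon[1], trace$times, trace$horizon[2])
  anchor_v <- rbind(trace$v0, trace$v_post)
  ## segment k runs from anchor_t[k] (value anchor_v[k,]) to anchor_t[k+1]
  seg_a <- anchor_t[-length(anchor_t)]
  seg_b <- anchor_t[-1]
  keep <- seg_b > t_from & seg_a < t_to
  seg_a <- pmax(seg_a[keep], t_from)
  seg_b <- pmin(seg_b[keep], t_to)
  v_at <- anchor_v[keep, , drop = FALSE]
  off <- pmax(seg_a - anchor_t[-length(anchor_t)][keep], 0)
  d <- seg_b - seg_a
  out <- list(d = d)
  A <- matrix(0, length(d), nn)
  for (a in seq_len(nn)) {
    A[, a] <- (v_at[, a] - ig[a]) * exp(-off / tau[a])  # value offset at seg_a
    e1 <- exp(-d / tau[a]); e2 <- e1^2; e3 <- e1 * e2
    c0 <- ig[a]
    out[[paste0("p1_", a)]] <- c0 * d + A[, a] * tau[a] * (1 - e1)
    out[[paste0("p2_", a)]] <- c0^2 * d + 2 * c0 * A[, a] * tau[a] * (1 - e1) +
      A[, a]^2 * (tau[a] / 2) * (1 - e2)
    out[[paste0("p3_", a)]] <- c0^3 * d + 3 * c0^2 * A[, a] * tau[a] * (1 - e1) +
      3 * c0 * A[, a]^2 * (tau[a] / 2) * (1 - e2) +
      A[, a]^3 * (tau[a] / 3) * (1 - e3)
  }
  if (nn == 2L) {
    tau12 <- 1 / (1 / tau[1] + 1 / tau[2])
    out$cross <- ig[1] * ig[2] * d +
      ig[1] * A[, 2] * tau[2] * (1 - exp(-d / tau[2])) +
      ig[2] * A[, 1] * tau[1] * (1 - exp(-d / tau[1])) +
      A[, 1] * A[, 2] * tau12 * (1 - exp(-d / tau12))
  }
  out
}

#' Time-weighted stationary moments of a simulated trajectory
#'
#' Computes exact time averages of `V^p` (p = 1, 2, 3) and, for neuron
#' pairs, of `V1 V2`, by closed-form integration over each inter-event
#' exponential segment of the event-anchored trace — no sampling grid and
#' no discretization bias.  Standard errors come from batch means over
#' contiguous time batches; skewness and correlation errors from a seeded
#' bootstrap over batches.
#'
#' @param trace A [voltage_trace()] from [simulate_marcus()].
#' @param config An [estimator_config()].
#' @param seed Seed for the bootstrap resamples.
#' @return A [moment_report()] with method `"monte_carlo"` and `se` filled.
#' @export
time_weighted_moments <- function(trace, config = estimator_config(),
                                  seed = 1L) {
  t0 <- trace$horizon[1] + config$burn_in_ms
  t1 <- trace$horizon[2]
  if (t1 <= t0) stop("horizon shorter than burn-in")
  nn <- length(trace$v0)
  nb <- config$batches
  edges <- seq(t0, t1, length.out = nb + 1L)
  raw <- array(0, c(nb, 3L, nn))
  cross_b <- numeric(nb)
  len <- diff(edges)
  for (k in seq_len(nb)) {
    si <- segment_integrals(trace, edges[k], edges[k + 1L])
    for (a in seq_len(nn)) for (p in 1:3)
      raw[k, p, a] <- sum(si[[paste0("p", p, "_", a)]]) / len[k]
    if (nn == 2L) cross_b[k] <- sum(si$cross) / len[k]
  }
  w <- len / sum(len)
  stat_from <- function(idx, wts) {
    wts <- wts / sum(wts)
    e1 <- vapply(seq_len(nn), function(a) sum(wts * raw[idx, 1L, a]), 0)
    e2 <- vapply(seq_len(nn), function(a) sum(wts * raw[idx, 2L, a]), 0)
    e3 <- vapply(seq_len(nn), function(a) sum(wts * raw[idx, 3L, a]), 0)
    m <- e1
    v <- e2 - m^2
    t3 <- e3 - 3 * m * e2 + 2 * m^3
    cv <- NA_real_; cr <- NA_real_
    if (nn == 2L) {
      cv <- sum(wts * cross_b[idx]) - m[1] * m[2]
      cr <- cv / sqrt(prod(pmax(v, .Machine$double.eps)))
    }
    list(m = m, v = v, t3 = t3, s = t3 / pmax(v, .Machine$double.eps)^1.5,
         cv = cv, cr = cr)
  }
  full <- stat_from(seq_len(nb), w)
  ## batch-means s.e. for mean/variance/covariance; bootstrap for skewness
  ## and correlation (statistics nonlinear in batch averages)
  per_batch_mean <- matrix(raw[, 1L, ], nb, nn)
  per_batch_var <- vapply(seq_len(nn), function(a)
    raw[, 2L, a] - per_batch_mean[, a]^2, numeric(nb))
  se_mean <- apply(per_batch_mean, 2L, stats::sd) / sqrt(nb)
  se_var <- apply(per_batch_var, 2L, stats::sd) / sqrt(nb)
  se_cov <- NA_real_
  if (nn == 2L) {
    per_batch_cov <- cross_b - per_batch_mean[, 1] * per_batch_mean[, 2]
    se_cov <- stats::sd(per_batch_cov) / sqrt(nb)
  }
  if (!is.null(seed)) set.seed(seed)
  bs <- replicate(config$bootstrap, {
    idx <- sample.int(nb, nb, replace = TRUE)
    st <- stat_from(idx, w[idx])
    c(st$s, st$cr)
  })
  if (is.null(dim(bs))) bs <- matrix(bs, nrow = 1L)
  se_skew <- apply(bs[seq_len(nn), , drop = FALSE], 1L, stats::sd)
  se_corr <- if (nn == 2L) stats::sd(bs[nn + 1L, ]) else NA_real_
  moment_report(full$m, full$v, full$cv, full$t3, full$s, full$cr,
                method = "monte_carlo",
                se = list(mean = se_mean, variance = se_var,
                          covariance = se_cov, skewness = se_skew,
                          correlation = se_corr))
}

#' Palm (pre-event) moments of a simulated trajectory
#'
#' Averages products of the voltages sampled just before each synaptic
#' event, `V(T_n^-)`.  By the PASTA principle these equal the time-weighted
#' stationary moments for Poisson-driven dynamics, which
#' [time_weighted_moments()] estimates independently; comparing the two is
#' the standard consistency check.
#'
#' @param trace A [voltage_trace()].
#' @param config An [estimator_config()] (burn-in and batch count reused;
#'   at least 100 post-burn-in events are required).
#' @return A [moment_report()] with method `"monte_carlo"`.
#' @export
palm_moments <- function(trace, config = estimator_config()) {
  nn <- length(trace$v0)
  tau <- vapply(trace$params, `[[`, numeric(1), "tau")
  ig  <- vapply(trace$params, `[[`, numeric(1), "i_ext_over_g")
  if (length(trace$times) < 2L) stop("too few events")
  anchor_t <- c(trace$horizon[1], trace$times[-length(trace$times)])
  anchor_v <- rbind(trace$v0, trace$v_post[-nrow(trace$v_post), , drop = FALSE])
  dt <- trace$times - anchor_t
  v_pre <- matrix(0, length(dt), nn)
  for (a in seq_len(nn))
    v_pre[, a] <- ig[a] + (anchor_v[, a] - ig[a]) * exp(-dt / tau[a])
  keep <- trace$times >= trace$horizon[1] + config$burn_in_ms
  if (sum(keep) < 100L) stop("fewer than 100 events after burn-in")
  v_pre <- v_pre[keep, , drop = FALSE]
  n <- nrow(v_pre)
  m <- colMeans(v_pre)
  v <- colMeans(v_pre^2) - m^2
  t3 <- colMeans(v_pre^3) - 3 * m * colMeans(v_pre^2) + 2 * m^3
  cv <- NA_real_; cr <- NA_real_
  if (nn == 2L) {
    cv <- mean(v_pre[, 1] * v_pre[, 2]) - m[1] * m[2]
    cr <- cv / sqrt(v[1] * v[2])
  }
  nb <- config$batches
  grp <- ceiling(seq_len(n) / (n / nb))
  bm <- apply(v_pre, 2L, function(x) tapply(x, grp, mean))
  se_mean <- apply(bm, 2L, stats::sd) / sqrt(nb)
  bv <- vapply(seq_len(nn), function(a)
    tapply(v_pre[, a]^2, grp, mean) - tapply(v_pre[, a], grp, mean)^2,
    numeric(nb))
  se_var <- apply(bv, 2L, stats::sd) / sqrt(nb)
  se_cov <- NA_real_
  if (nn == 2L) {
    bc <- tapply(v_pre[, 1] * v_pre[, 2], grp, mean) -
      tapply(v_pre[, 1], grp, mean) * tapply(v_pre[, 2], grp, mean)
    se_cov <- stats::sd(bc) / sqrt(nb)
  }
  bt <- vapply(seq_len(nn), function(a) {
    e1 <- tapply(v_pre[, a], grp, mean)
    e2 <- tapply(v_pre[, a]^2, grp, mean)
    e3 <- tapply(v_pre[, a]^3, grp, mean)
    e3 - 3 * e1 * e2 + 2 * e1^3
  }, numeric(nb))
  se_t3 <- apply(bt, 2L, stats::sd) / sqrt(nb)
  moment_report(m, v, cv, t3, t3 / v^1.5, cr, method = "monte_carlo",
                se = list(mean = se_mean, variance = se_var,
                          covariance = se_cov, third_central = se_t3))
}

#' Empirical voltage correlation of a simulated pair
#'
#' Pearson correlation of the two voltage trajectories under the exact
#' time-weighted inner product, with a bootstrap standard error.
#'
#' @param trace A two-neuron [voltage_trace()].
#' @param config An [estimator_config()].
#' @param seed Bootstrap seed.
#' @return A list with `estimate` and `se`.
#' @export
empirical_voltage_correlation <- function(trace, config = estimator_config(),
                                          seed = 1L) {
  stopifnot(length(trace$v0) == 2L)
  rep <- time_weighted_moments(trace, config, seed = seed)
  if (any(rep$variance <= 0)) stop("zero-variance trace")
  list(estimate = rep$correlation, se = rep$se$correlation)
}

#' Empirical skewness of a simulated trajectory
#'
#' `S[V] = M3 / M2^(3/2)` from exact time-weighted central moments, with a
#' seeded bootstrap-over-batches standard error.  Invariant under affine
#' rescaling of the trace.
#'
#' @param trace A [voltage_trace()].
#' @param config An [estimator_config()].
#' @param seed Bootstrap seed.
#' @param neuron Neuron index.
#' @return A list with `estimate` and `se`.
#' @export
empirical_skewness <- function(trace, config = estimator_config(), seed = 1L,
                               neuron = 1L) {
  rep <- time_weighted_moments(trace, config, seed = seed)
  if (rep$variance[neuron] <= 0) stop("degenerate trace")
  list(estimate = rep$skewness[neuron], se = rep$se$skewness[neuron])
}

#' Windowed spike-count correlation
#'
#' Pearson correlation of per-window spike counts of two inputs over
#' disjoint counting windows of length `window_ms`:
#' `rho_ij(Dt) = Cov(N_i, N_j) / sqrt(Var N_i Var N_j)`.
#' This is the timescale-dependent empirical synchrony measure; for
#' instantaneously synchronous (unjittered) trains it is independent of the
#' window, while jittered trains lose correlation below the jitter
#' timescale.  Standard error by batch means over blocks of windows.
#'
#' @param spikes_i,spikes_j Spike time vectors (ms), or a [spike_list()]
#'   together with `ids`.
#' @param window_ms Counting window, ms.
#' @param t_range Time range to analyze (defaults to the spikes' range).
#' @param batches Number of batches for the standard error.
#' @param ids Length-2 character vector of input ids when a `spike_list` is
#'   given.
#' @return A list with `estimate`, `se`, `n_windows`.
#' @export
windowed_spike_correlation <- function(spikes_i, spikes_j = NULL,
                                       window_ms, t_range = NULL,
                                       batches = 50L, ids = NULL) {
  stopifnot(window_ms > 0)
  if (inherits(spikes_i, "spike_list")) {
    stopifnot(length(ids) == 2L)
    sl <- spikes_i
    spikes_j <- sl$time_ms[sl$input_id == ids[2]]
    spikes_i <- sl$time_ms[sl$input_id == ids[1]]
  }
  if (is.null(t_range))
    t_range <- range(c(spikes_i, spikes_j))
  nw <- floor(diff(t_range) / window_ms)
  if (nw < 10L) stop("too few counting windows")
  bin <- function(t) {
    k <- floor((t - t_range[1]) / window_ms) + 1L
    tabulate(k[k >= 1L & k <= nw], nbins = nw)
  }
  ni <- bin(spikes_i); nj <- bin(spikes_j)
  if (stats::var(ni) == 0 || stats::var(nj) == 0)
    stop("zero count variance")
  est <- stats::cor(ni, nj)
  nb <- min(batches, nw %/% 10L)
  grp <- ceiling(seq_len(nw) / (nw / nb))
  bc <- vapply(seq_len(nb), function(g) {
    i <- grp == g
    if (stats::var(ni[i]) == 0 || stats::var(nj[i]) == 0) NA_real_
    else stats::cor(ni[i], nj[i])
  }, 0)
  bc <- bc[is.finite(bc)]
  list(estimate = est, se = stats::sd(bc) / sqrt(length(bc)), n_windows = nw)
}
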