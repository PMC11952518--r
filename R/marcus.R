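#' Marcus jump update
#'
#' Voltage update of an AONCB neuron receiving simultaneous dimensionless
#' conductance jumps `(w_e, w_i)` in the instantaneous-synapse limit.  The
#' voltage moves toward the jump target `R = (w_e V_e + w_i V_i)/(w_e + w_i)`
#' by the fraction `1 - exp(-(w_e + w_i))`:
#' `J = (R - v) * (1 - exp(-(w_e + w_i)))`.
#' The update keeps the voltage inside `[V_i, V_e]` for any jump size and
#' saturates at the reversal potentials as the jumps grow.
#'
#' @param v Pre-event membrane voltage(s), mV (within `[v_inh, v_exc]`).
#' @param w_e,w_i Nonnegative dimensionless jumps with `w_e + w_i > 0`.
#' @param params A [neuron_params()].
#' @return The jump `J` in mV (the post-event voltage is `v + J`).
#' @examples
#' p <- neuron_params()
#' marcus_jump(0, 0.01, 0, p)      # 60 * (1 - exp(-0.01)) ~ 0.597 mV
#' @export
marcus_jump <- function(v, w_e, w_i, params) {
  stopifnot(all(w_e >= 0), all(w_i >= 0))
  if (any(w_e + w_i <= 0))
    stop("marcus_jump requires w_e + w_i > 0 (pure relaxation is not an event)")
  if (any(v < params$v_inh - 1e-9) || any(v > params$v_exc + 1e-9))
    stop("voltage outside [v_inh, v_exc]")
  w <- w_e + w_i
  r <- (w_e * params$v_exc + w_i * params$v_inh) / w
  (r - v) * (1 - exp(-w))
}

#' Event-anchored voltage trajectory
#'
#' Exact representation of an AONCB trajectory under instantaneous synapses:
#' post-event voltages at the event times, plus the per-neuron parameters.
#' Between events each neuron relaxes exponentially toward its resting
#' offset I/G with time constant tau, so the voltage at any time is
#' reconstructed without discretization error (see [resample_trace()]).
#'
#' @param times Event times, ms.
#' @param v_post Post-event voltages (events x neurons), mV.
#' @param v0 Initial voltages at `t_start`, mV.
#' @param horizon `(t_start, t_end)`, ms.
#' @param params List of [neuron_params()] per neuron.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(times, v_post, v0, horizon, params) {
  if (is.vector(v_post)) v_post <- matrix(v_post, ncol = length(v0))
  params <- as_params_list(params, length(v0))
  structure(list(times = times, v_post = v_post, v0 = v0,
                 horizon = horizon, params = params),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("Event-anchored voltage trace: %d events, %d neuron(s), [%g, %g] ms\n",
              length(x$times), length(x$v0), x$horizon[1], x$horizon[2]))
  invisible(x)
}

#' Exact event-driven simulation under the Marcus rule
#'
#' Between consecutive synaptic events every neuron relaxes exponentially
#' toward its resting offset `I/G`; at each event, neurons receiving a
#' positive total jump update via [marcus_jump()] while the others continue
#' relaxing.  The returned event-anchored trace is exact: no discretization
#' error is incurred at any point of the trajectory.
#'
#' @param train An [event_train()].
#' @param params [neuron_params()] per neuron (recycled if a single set).
#' @param v0 Initial voltages, mV (default: resting offsets I/G).
#' @return A [voltage_trace()].
#' @export
simulate_marcus <- function(train, params, v0 = NULL) {
  nn <- ncol(train$w_e)
  params <- as_params_list(params, nn)
  tau <- vapply(params, `[[`, numeric(1), "tau")
  ig  <- vapply(params, `[[`, numeric(1), "i_ext_over_g")
  ve  <- vapply(params, `[[`, numeric(1), "v_exc")
  vi  <- vapply(params, `[[`, numeric(1), "v_inh")
  if (is.null(v0)) v0 <- ig
  stopifnot(length(v0) == nn)
  if (any(v0 < vi) || any(v0 > ve)) stop("v0 outside [v_inh, v_exc]")
  n_ev <- length(train$times)
  v_post <- matrix(0, n_ev, nn)
  v <- v0
  t_prev <- train$horizon[1]
  for (k in seq_len(n_ev)) {
    dt <- train$times[k] - t_prev
    v <- ig + (v - ig) * exp(-dt / tau)
    we <- train$w_e[k, ]; wi <- train$w_i[k, ]
    w <- we + wi
    pos <- w > 0
    if (any(pos)) {
      r <- (we[pos] * ve[pos] + wi[pos] * vi[pos]) / w[pos]
      v[pos] <- v[pos] + (r - v[pos]) * (1 - exp(-w[pos]))
    }
    v_post[k, ] <- v
    t_prev <- train$times[k]
  }
  voltage_trace(train$times, v_post, v0, train$horizon, params)
}

#' Resample an event-anchored trace on arbitrary times
#'
#' Evaluates the exact trajectory `V(t) = I/G + (V(T_n) - I/G) *
#' exp(-(t - T_n)/tau)` between anchors; values at event times (from the
#' right) agree with the anchors to machine precision.
#'
#' @param trace A [voltage_trace()].
#' @param times Sample times within the horizon, or `NULL` to use `dt`.
#' @param dt Uniform sampling step, ms (used when `times` is `NULL`).
#' @return A list with `times` and matrix `v` (samples x neurons).
#' @export
resample_trace <- function(trace, times = NULL, dt = NULL) {
  if (is.null(times)) {
    stopifnot(!is.null(dt), dt > 0)
    times <- seq(trace$horizon[1], trace$horizon[2], by = dt)
  }
  stopifnot(all(times >= trace$horizon[1] - 1e-9),
            all(times <= trace$horizon[2] + 1e-9))
  nn <- length(trace$v0)
  tau <- vapply(trace$params, `[[`, numeric(1), "tau")
  ig  <- vapply(trace$params, `[[`, numeric(1), "i_ext_over_g")
  anchor_t <- c(trace$horizon[1], trace$times)
  anchor_v <- rbind(trace$v0, trace$v_post)
  seg <- findInterval(times, anchor_t, rightmost.closed = FALSE)
  seg[seg < 1L] <- 1L
  v <- matrix(0, length(times), nn)
  for (a in seq_len(nn))
    v[, a] <- ig[a] + (anchor_v[seg, a] - ig[a]) *
      exp(-(times - anchor_t[seg]) / tau[a])
  list(times = times, v = v)
}

#' Read and write uniformly sampled voltage traces
#'
#' Tab-separated `time_ms  V_1 ... V_n` with `#`-prefixed metadata headers.
#'
#' @param trace A [voltage_trace()].
#' @param path File path.
#' @param dt Sampling step, ms.
#' @param seed Optional seed recorded in the metadata header.
#' @return `path`, invisibly (writer); a list `times`, `v` (reader).
#' @export
write_voltage_trace <- function(trace, path, dt = 1, seed = NA) {
  s <- resample_trace(trace, dt = dt)
  con <- file(path, "w")
  on.exit(close(con))
  p <- trace$params[[1]]
  writeLines(sprintf("# voltage_trace tau=%g ve=%g vi=%g seed=%s dt_ms=%g",
                     p$tau, p$v_exc, p$v_inh, as.character(seed), dt), con)
  writeLines(paste(c("# time_ms", sprintf("V_%d", seq_len(ncol(s$v)))),
                   collapse = "\t"), con)
  utils::write.table(format(cbind(s$times, s$v), digits = 17, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
read_voltage_trace <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  df <- utils::read.table(text = body, sep = "\t")
  list(times = df[[1]], v = as.matrix(df[, -1, drop = FALSE]))
}

#' Euler simulation with finite synaptic time
#'
#' Integrates the conductance-based dynamics with all-or-none rectangular
#' conductance pulses of duration `tau_s = epsilon * tau`: each spike of
#' weight `w` raises the dimensionless conductance by `w / (epsilon * tau)`
#' (per ms) for `tau_s` ms, so each pulse transfers the same charge as the
#' corresponding instantaneous Marcus jump.  Integration is explicit
#' first-order time stepping; the terminal state converges to the
#' [simulate_marcus()] trajectory at rate O(epsilon) as `epsilon -> 0`.
#'
#' @param spikes Data frame with columns `time_ms`, `w_e`, `w_i` (one spike
#'   or synchronous-event arrival per row; weights are the total
#'   dimensionless jumps delivered at that arrival).
#' @param params A [neuron_params()] with `epsilon > 0`.
#' @param horizon_ms Integration horizon `[0, horizon_ms]`.
#' @param dt Time step, ms; must resolve the pulse (`dt < tau_s`); default
#'   `tau_s / 20`.
#' @param v0 Initial voltage, mV.
#' @param record_dt Output sampling step, ms (default `dt`).
#' @return A list with `times`, `v` (single-neuron trace on the grid).
#' @export
simulate_euler_finite_ts <- function(spikes, params, horizon_ms,
                                     dt = NULL, v0 = NULL, record_dt = NULL) {
  stopifnot(params$epsilon > 0)
  tau_s <- params$epsilon * params$tau
  if (is.null(dt)) dt <- tau_s / 20
  if (dt >= tau_s) stop("dt must be smaller than tau_s = epsilon * tau")
  if (nrow(spikes) && (any(spikes$w_e < 0) || any(spikes$w_i < 0)))
    stop("negative weights")
  if (is.null(v0)) v0 <- params$i_ext_over_g
  n_steps <- ceiling(horizon_ms / dt)
  ## active dimensionless conductance (per-ms) staircases via difference arrays
  ge <- numeric(n_steps + 1L); gi <- numeric(n_steps + 1L)
  if (nrow(spikes)) {
    i0 <- pmin(pmax(floor(spikes$time_ms / dt) + 1L, 1L), n_steps + 1L)
    i1 <- pmin(floor((spikes$time_ms + tau_s) / dt) + 1L, n_steps + 1L)
    ## charge-conserving amplitude: scale to the realized on-grid duration so
    ## every pulse transfers exactly its dimensionless weight
    dur <- pmax(i1 - i0, 1L) * dt
    amp_e <- spikes$w_e / dur
    amp_i <- spikes$w_i / dur
    for (s in seq_len(nrow(spikes))) {
      ge[i0[s]] <- ge[i0[s]] + amp_e[s]
      gi[i0[s]] <- gi[i0[s]] + amp_i[s]
      if (i1[s] <= n_steps) {
        ge[i1[s]] <- ge[i1[s]] - amp_e[s]
        gi[i1[s]] <- gi[i1[s]] - amp_i[s]
      }
    }
    ge <- cumsum(ge); gi <- cumsum(gi)
  }
  tau <- params$tau
  drive <- (params$i_ext_over_g / tau + ge * params$v_exc + gi * params$v_inh) * dt
  decay <- 1 - dt / tau - (ge + gi) * dt
  ## blockwise linear recursion v[k+1] = decay[k] v[k] + drive[k], solved by
  ## cumulative products within blocks to avoid an O(n_steps) scalar loop
  v <- numeric(n_steps + 1L)
  v[1] <- v0
  block <- max(1000L, min(20000L, ceiling(tau / dt)))
  k <- 1L
  while (k <= n_steps) {
    kk <- k:min(k + block - 1L, n_steps)
    P <- cumprod(decay[kk])
    incr <- cumsum(drive[kk] / P)
    v[kk + 1L] <- P * (v[k] + incr)
    k <- kk[length(kk)] + 1L
  }
  times <- (0:n_steps) * dt
  if (!is.null(record_dt) && record_dt > dt) {
    pick <- seq(1L, n_steps + 1L, by = max(1L, round(record_dt / dt)))
    times <- times[pick]; v <- v[pick]
  }
  list(times = times, v = v)
}
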