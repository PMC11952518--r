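#' Passive membrane parameters of an AONCB neuron
#'
#' Bundles the passive parameters of one all-or-none conductance-based
#' (AONCB) neuron.  Voltages are measured as deviations from the leak
#' reversal potential, which is fixed at 0 mV, so `v_inh < 0 < v_exc`.
#' A tonic current enters only through the resting offset `i_ext_over_g`
#' (I/G, in mV), toward which the voltage relaxes between synaptic events.
#'
#' @param tau Membrane time constant in ms (tau = C/G).
#' @param v_exc Excitatory reversal potential in mV (relative to leak).
#' @param v_inh Inhibitory reversal potential in mV (relative to leak),
#'   must be negative.
#' @param i_ext_over_g Tonic-current resting offset I/G in mV.
#' @param epsilon Dimensionless synaptic time ratio tau_s/tau.  `epsilon = 0`
#'   selects the instantaneous-synapse (Marcus) regime; `epsilon > 0` gives
#'   rectangular conductance pulses of duration `epsilon * tau`.
#'
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params()                   # biophysical defaults (tau 15 ms, -10/60 mV)
#' neuron_params(tau = 20, epsilon = 0.25)
#' @export
neuron_params <- function(tau = 15, v_exc = 60, v_inh = -10,
                          i_ext_over_g = 0, epsilon = 0) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0)
  stopifnot(is.numeric(v_exc), length(v_exc) == 1L, is.finite(v_exc))
  stopifnot(is.numeric(v_inh), length(v_inh) == 1L, is.finite(v_inh))
  if (!(v_inh < 0 && 0 < v_exc))
    stop("reversal potentials must satisfy v_inh < 0 < v_exc (leak at 0 mV)")
  stopifnot(is.numeric(i_ext_over_g), length(i_ext_over_g) == 1L,
            is.finite(i_ext_over_g))
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  structure(
    list(tau = tau, v_leak = 0, v_exc = v_exc, v_inh = v_inh,
         i_ext_over_g = i_ext_over_g, epsilon = epsilon),
    class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("AONCB neuron parameters\n")
  cat(sprintf("  tau          : %g ms\n", x$tau))
  cat(sprintf("  reversals    : v_inh = %g mV < v_leak = 0 < v_exc = %g mV\n",
              x$v_inh, x$v_exc))
  cat(sprintf("  I/G offset   : %g mV\n", x$i_ext_over_g))
  cat(sprintf("  epsilon      : %g (%s)\n", x$epsilon,
              if (x$epsilon == 0) "instantaneous synapses" else
                sprintf("tau_s = %g ms", x$epsilon * x$tau)))
  invisible(x)
}

#' Biophysical parameter presets
#'
#' Common parameter values used throughout: passive time constant 15 ms,
#' reversal potentials -10 mV (inhibitory) and 60 mV (excitatory) relative
#' to leak, and two synaptic weight regimes: `"large"` weights
#' (w_e = 0.01, w_i = 0.04, typical of strong thalamo-cortical projections,
#' paired with small pools Ke = 4 Ki = 100) and `"moderate"` weights
#' (w_e = 0.001, w_i = 0.004, typical cortico-cortical, with large pools
#' Ke = 4 Ki = 1000).  Inhibitory weights are fourfold the excitatory ones
#' in both regimes.
#'
#' @param weights Either `"moderate"` or `"large"`.
#' @return A list with elements `neuron` (a [neuron_params()]) and `pool`
#'   (an [input_pool()], with per-input rates of 1 Hz to be overridden).
#' @export
biophysical_preset <- function(weights = c("moderate", "large")) {
  weights <- match.arg(weights)
  w_e <- if (weights == "moderate") 0.001 else 0.01
  k_e <- if (weights == "moderate") 1000L else 100L
  list(neuron = neuron_params(),
       pool = input_pool(n_exc = k_e, n_inh = k_e %/% 4L,
                         rate_exc = 1, rate_inh = 1,
                         w_exc = w_e, w_inh = 4 * w_e))
}

## internal: recycle a scalar-or-list of neuron_params to n neurons
as_params_list <- function(params, n) {
  if (inherits(params, "neuron_params")) params <- list(params)
  stopifnot(all(vapply(params, inherits, logical(1), "neuron_params")))
  if (length(params) == 1L && n > 1L) params <- rep(params, n)
  if (length(params) != n)
    stop("need one neuron_params per neuron (or a single set to recycle)")
  params
}

## internal: rates are accepted in Hz at the API boundary; all internal
## formulas use 1/ms so that b*tau terms are dimensionless.
hz_to_per_ms <- function(r) r / 1000
per_ms_to_hz <- function(r) r * 1000
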