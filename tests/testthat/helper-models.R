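## Shared fixtures: small jump laws and models built in code.

default_params <- function(...) neuron_params(...)

## a handful of finite-support single-neuron laws exercising mixed E/I jumps
example_jump_laws <- function() {
  list(
    pure_exc = jump_dist(c(0.6, 0.4), c(0.05, 0.3), c(0, 0), rate_hz = 800),
    mixed = jump_dist(c(0.5, 0.3, 0.2), c(0.3, 0.05, 0), c(0, 0.2, 0.4),
                      rate_hz = 5000),
    heavy = jump_dist(c(0.25, 0.25, 0.25, 0.25),
                      c(1.5, 0.2, 0, 0.01), c(0, 0.1, 2.0, 0.04),
                      rate_hz = 300))
}

## small two-neuron pool used for pair-law tests (kept tiny so exact
## enumeration of cross-mixture supports stays cheap)
small_pair_pool <- function(rate = 5)
  input_pool(n_exc = 12, n_inh = 3, rate_exc = rate, rate_inh = rate,
             w_exc = 0.05, w_inh = 0.2)

## moderate-weight single neuron (large-pool regime scaled down for speed)
small_bb_model <- function(rho_e = 0.03, rho_i = 0.03, rho_ei = 0,
                           rate = 5)
  sync_beta_binomial(input_pool(100, 25, rate, rate, 0.01, 0.04),
                     rho_e, rho_i, rho_ei)
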