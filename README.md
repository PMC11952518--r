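# syncshot

Subthreshold voltage statistics of conductance-based neurons driven by
synchronous shot noise.

Cortical neurons receive thousands of synaptic inputs, yet their membrane
voltage fluctuates far more — and far more asymmetrically, and far more in
step with neighboring cells — than independent inputs could explain.
`syncshot` implements a jump-process framework for quantifying how *weak but
nonzero spiking synchrony* shapes the stationary subthreshold statistics of
all-or-none conductance-based (AONCB) neurons: voltage mean, variance,
cross-neuron covariance, third moment and skewness.

## Model

A feedforward set of AONCB neurons obeys

C dV_a/dt = G (V_L − V_a) + G_e,a (V_e − V_a) + G_i,a (V_i − V_a) + I_a,

with leak reversal V_L = 0, reversal potentials V_i < 0 < V_e, and
conductances driven by K_e excitatory and K_i inhibitory synapses that switch
on all-or-none for a duration τ_s.  In the limit of instantaneous synapses
(ε = τ_s/τ → 0) the drive becomes a compound Poisson process: synaptic
events arrive at the collective rate b, and event n delivers dimensionless
jump vectors (W_e,a, W_i,a) whose joint law is the *sole carrier of input
synchrony*.  Between events each voltage relaxes exponentially toward I/G;
at an event it updates by the Marcus rule

J_a = ( (W_e,a V_e + W_i,a V_i)/(W_e,a + W_i,a) − V_a ) · (1 − e^−(W_e,a + W_i,a)),

which keeps V_a inside [V_i, V_e] and admits an *exact* event-driven
simulation scheme.

Because Poisson arrivals see time averages (PASTA), the stationary mixed
moments of the voltages satisfy a triangular fixed-point system that can be
solved exactly, order by order, for any finite-support jump law.  The
package implements both the generic solver and the closed forms it yields —
for the mean (synchrony-aware synaptic efficacies), the pair covariance,
and the third central moment — together with the interpretable small-weight
reductions in terms of pairwise spiking correlations ρ_αβ: the synchrony
gain 1 + (K−1)ρ on the variance, the excitatory share q of variability,
the fully-synchronous/asynchronous variance ratio κ, the cross-neuron
voltage correlation ρ_V = ρ′ / ((1−ρ)/κ + ρ), and skewness approximations.

Synchrony itself is generated by exchangeable beta-binomial models (pairwise
correlation ρ = 1/(1+β), collective rate r·β·(ψ(β+K) − ψ(β))), shared-input
pools, calibrated cross-neuron mixtures, Gaussian spike-time jitter and
Bernoulli synaptic failure.

## Worked example

A neuron with standard biophysics (τ = 15 ms, V_e = 60 mV, V_i = −10 mV)
receiving 1000 excitatory and 250 inhibitory moderate synapses
(w_e = 0.001, w_i = 0.004) at 1 Hz each, with weak within-pool synchrony
ρ_e = ρ_i = 0.03:

```r
library(syncshot)

params <- neuron_params()                     # tau 15 ms, -10/60 mV, leak 0
pool   <- input_pool(n_exc = 1000, n_inh = 250, rate_exc = 1, rate_inh = 1,
                     w_exc = 0.001, w_inh = 0.004)
model  <- sync_beta_binomial(pool, rho_e = 0.03, rho_i = 0.03)

moment_report_analytic(model, params)
#> Stationary moments (exact)
#>   mean      : 0.71764 mV
#>   variance  : 0.77524 mV^2
#>   third     : 1.5954 mV^3
#>   skewness  : 2.3373

train <- sample_event_train(model, horizon_ms = 60000, seed = 1)
trace <- simulate_marcus(train, params)       # exact event-driven trajectory
time_weighted_moments(trace, seed = 1)
#> Stationary moments (monte_carlo)
#>   mean      : 0.71272 mV
#>   variance  : 0.77499 mV^2
#>   third     : 1.6384 mV^3
#>   skewness  : 2.4014
```

The analytic and simulated moments agree within the Monte-Carlo error.  The
skewness near 2.4 — versus about 0.23 for the same drive without synchrony —
shows how ρ_e = 0.03 amplifies the depolarizing tail of the voltage
distribution at spontaneous rates.

For a pair of neurons with within-neuron spiking correlation ρ = 0.02 and
cross-neuron correlation ρ′ = 0.013 (uniformly correlated excitation and
inhibition):

```r
voltage_correlation_pipeline(pool, params, rho = 0.02, rho_cross = 0.013)
#> $m      0.728      # mean depolarization, mV
#> $q      0.884      # excitatory share of variability
#> $kappa  593        # synchrony gain
#> $rho_v  0.600      # cross-neuron voltage correlation
```

so physiological synchrony alone produces the strong voltage correlations
seen in paired recordings, without any shared inputs.

A thin command-line front end over these functions lives at
`inst/cli/syncshot.R` (verbs `sample`, `simulate`, `moments`, `estimate`,
`validate`, `fixtures`).

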