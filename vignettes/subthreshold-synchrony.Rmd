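---
title: "Stationary subthreshold statistics under synchronous shot noise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary subthreshold statistics under synchronous shot noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncshot)
```

## The model

`syncshot` analyzes all-or-none conductance-based (AONCB) neurons: passive
membranes (time constant $\tau = C/G$, leak reversal fixed at 0 mV,
reversal potentials $V_i < 0 < V_e$) whose synapses switch their conductance
on by a fixed amount for a fixed duration $\tau_s$, rather than decaying
exponentially.  Writing $\epsilon = \tau_s/\tau$ and holding the
dimensionless synaptic weights $w = g\,\tau_s/C$ fixed as
$\epsilon \to 0^+$, the synaptic drive converges to a two-dimensional shot
noise: a compound Poisson process of *synaptic events* at collective rate
$b$, each delivering a jump vector $(W_e, W_i)$ equal to the weighted sum of
the coactive inputs' weights.  The voltage then follows Marcus-type jump
dynamics: exponential relaxation toward $I/G$ between events and, at each
event, the discontinuous update

$$ V \mapsto V + \Bigl(\tfrac{W_e V_e + W_i V_i}{W_e + W_i} - V\Bigr)\,
   \bigl(1 - e^{-(W_e+W_i)}\bigr), $$

which confines $V$ to $[V_i, V_e]$.  Crucially, *all* synchrony enters
through the joint law of the jumps: inputs that coactivate at the same event
produce large jumps, and jumps shared across neurons produce covarying
voltages.  `simulate_marcus()` implements this scheme exactly
(event-anchored, no discretization error); `simulate_euler_finite_ts()`
integrates the finite-$\tau_s$ dynamics with explicit first-order stepping
for convergence checks against the instantaneous-synapse limit.

Key assumptions: events form a homogeneous Poisson process; jump vectors are
i.i.d. across events (no temporal structure in the synchrony); spiking
correlations are nonnegative; neurons are feedforward (no recurrence) and
subthreshold (no spiking mechanism).

## Stationary moments from the PASTA fixed point

Because Poisson arrivals see time averages, the voltage sampled just before
an event is distributed as the stationary voltage.  Combining this with the
single-event update gives, for every multiset $B$ of neuron indices, a
linear equation that couples the shifted moment
$\mu_B = E\prod_{a\in B}(V_a - I_a/G_a)$ only to strictly lower orders —
a triangular system solved exactly, lowest order first, by
`solve_shifted_moments()`.  Three ingredients enter: independence of the
pre-event state from the incoming jump; the exponential inter-event interval
($E[e^{-cS}] = b/(b+c)$, which is where heterogeneous time constants
aggregate as $\sum_{a \in B} 1/\tau_a$); and the per-neuron decomposition
$V' = Y V + (1-Y) R$ with $Y = e^{-(W_e+W_i)}$ and jump target $R$ (a
zero-jump neuron contributes $Y = 1$, so the ratio $R$ is never formed when
$W_e + W_i = 0$).

Carrying the expansion through by hand yields compact closed forms that the
package exposes directly:

* mean (`stationary_mean()`): a weighted combination of the reversal
  potentials with synchrony-aware efficacies
  $c_\alpha = b\,E[\tfrac{W_\alpha}{W_e+W_i}(1 - e^{-(W_e+W_i)})]$;
* covariance/variance (`stationary_covariance()`): numerator
  $b_{12} E[(R_1-m_1)(1-Y_1)(R_2-m_2)(1-Y_2)]$ over the effective rate
  $1/\tau_1 + 1/\tau_2 + b_{12}E[1-Y_1Y_2]$;
* third central moment (`third_central_moment()`):
  $$ M_3 = \frac{E[(R-m)^3(1-Y)^3] + 3 M_2\, E[(R-m)(Y^2-1)(1-Y)]}
     {3/(b\tau) + E[1-Y^3]}. $$

The middle term of $M_3$ deserves a note: deriving the third-order fixed
point produces tonic-current terms that cancel identically once the
first-order relation $E[(1-Y)(R-m)] = (m - I/G)/(b\tau)$ is substituted, so
the compact form above is exact for any constant current.  The test suite
asserts agreement between these closed forms and the generic solver to
$10^{-10}$ relative error on finite-support laws — two independently coded
routes to the same number.

## Synchrony models

All parametric models reduce to superpositions of independent
compound-Poisson *components*, each either an explicit finite jump support
(asynchronous pools, shared inputs) or an exchangeable beta-binomial count
law over a union of inputs.

**Beta-binomial pools.**  For $K$ exchangeable inputs the per-event
coactivation count follows the $\alpha \to 0^+$ beta-binomial law
conditioned on at least one active input,
$P(n) \propto \binom{K}{n} B(n, \beta + K - n)$, computed in log space
(`event_count_pmf()`), with limits handled explicitly ($\beta = \infty$:
point mass at 1; $\beta = 0$: point mass at $K$, full synchrony).  This law
is the unique choice consistent with both identities the framework relies
on: the pairwise correlation $\rho = 1/(1+\beta)$ with higher-order
coefficients $\rho_{1..n} = \prod_{k<n} k/(\beta+k)$, and the digamma
collective rate $r\,\beta(\psi(\beta+K) - \psi(\beta))$ — both verified
numerically in the tests.

**Correlation coefficients.**  Coefficients are defined per event as
$\rho_{k_1..k_n} = E[X_{k_1}\cdots X_{k_n}] / (\prod_k E[X_k])^{1/n}$, the
$n$-th-root normalization under which the diagonal coefficients are exactly
one and the rate-weighted small-weight sums take the form
$\sum_{kl} \rho_{kl}\sqrt{r_k r_l}\, w_k w_l$.  This reading was an open
design choice; it is the only one for which the asynchronous limit of the
small-weight variance reduces to $\sum_k r_k w_k^2$ and the beta-binomial
identities above hold simultaneously.

**Cross-neuron mixtures.**  Two neurons with within-neuron correlation
$\rho$ and cross-neuron correlation $\rho' \le \rho$ are generated by mixing
*joint* components (one beta-binomial over the union of both neurons'
inputs) with *private* per-neuron components, all sharing
$\beta = 1/\rho - 1$.  Because the within-pair coactivation ratio of every
component equals $1/(1+\beta)$ regardless of pool size, the within-neuron
coefficient is exactly $\rho$ for *any* mixture split, and the cross-neuron
target fixes the joint component's share of each input's rate in closed
form ($b_J\,p_J = t\,r$ with $t = \rho'/\rho$).  No root-finding is needed
and the implied coefficients (`implied_rho()`) match targets to machine
precision.  Two structures mirror the physiological cases: `"within_pool"`
keeps excitation and inhibition independent, `"uniform"` merges them (equal
rates required) so every within-neuron pair shares $\rho$.  The
construction is limited to symmetric pairs with uniform coefficients —
heterogeneous cross-neuron targets are rejected — because the higher-order
structure of a heterogeneous mixture is not identified by pairwise targets
alone.

**Shared inputs, jitter, failure.**  `sync_shared_inputs()` realizes
asynchronous pairs sharing fractions $f_e, f_i$ of their inputs (shared
counts rounded half up).  `jitter_spikes()` shifts each spike by a centered
Gaussian of s.d. $\sigma_J$; jittered spikes are delivered as singleton
events (never re-merged), which is how the temporally broadened synchrony
is compared against the instantaneous idealization.
`apply_synaptic_failure()` thins activations by Bernoulli($p$), computing
the thinned count laws exactly; implied rates scale as $p\,r$ and pairwise
coefficients as $\sqrt{p_a p_b}\,\rho$, and compensating $K \to K/p$
preserves second- and third-order voltage statistics to first order in the
weights.

## Interpretable reductions

In the biophysically relevant small-weight regime ($W_e + W_i \ll 1$ with
high probability) the moments reduce to quadratic forms in the spiking
correlations: `variance_small_weight()` (within-pool gain
$1 + (K-1)\rho$, variability-reducing excitation–inhibition cross term),
`covariance_small_weight()` (linear in each cross coefficient), the
excitatory share `excitatory_share_q()`, the synchrony gain `kappa_ratio()`
(case i: $K_e q + K_i(1-q)$; case ii from the variance-ratio definition,
which simplifies to $(\sqrt{K_e q} - \sqrt{K_i(1-q)})^2$ at equal rates —
the definition is used rather than a transcribed shorthand, with tests
pinning the special values), and
`synchronous_voltage_correlation()` ($\rho_V = \rho'/((1-\rho)/\kappa +
\rho)$).  A warning (not an error) is raised when a typical per-event jump
exceeds 0.2, where the quadratic forms become strained.

The excitation-only skewness approximation
(`skewness_conductance_approx()`) is reconstructed from the small-weight
second and third moments under $K_e w_e \simeq 1$:
$S[V] \simeq s[V]\,\frac{1 - 2r\tau}{1 + r\tau}\sqrt{1 + \rho_e K_e}$ with
the current-based reference $s[V] = \tfrac{2\sqrt{2}}{3}/\sqrt{K_e r \tau}$.
This parenthesization reproduces the expected magnitudes at
$K_e = 1000$, $r = 1$ Hz ($\approx 0.23$ without synchrony, $\approx 1.3$
at $\rho_e = 0.03$) and the sign change at $r = 1/(2\tau)$.  Note that at
$\rho_e = 0.03$ the *exact* skewness from the third-moment formula is
substantially larger ($\approx 2.45$ at these parameters, confirmed by
simulation): occasional coactivation clusters of hundreds of inputs carry
total jumps far outside the small-weight regime, and the approximation is
deliberately interpretable rather than tight.

## Estimators

Event-anchored traces admit *exact* time averages: over each inter-event
segment the integrals of $V^p$ ($p \le 3$) and $V_1 V_2$ are computed in
closed form, so `time_weighted_moments()` has no discretization bias and is
the default estimator.  `palm_moments()` averages pre-event voltages; the
agreement of the two (the PASTA identity) is asserted across all fixture
scenarios in the test suite.  Standard errors use batch means over 50
contiguous time batches; skewness and correlation errors use a seeded
bootstrap (1000 resamples) over batches, since those statistics are
nonlinear in batch averages.  The default burn-in is $20\tau$ (300 ms),
leaving under $e^{-20}$ of initial-condition weight.
`windowed_spike_correlation()` estimates the timescale-dependent spiking
correlation from disjoint counting windows, with batch-means errors.

## Numerical choices

* Rates are accepted in Hz at every API boundary and converted to 1/ms
  internally, so all $b\tau$ combinations are dimensionless.
* Special functions (`lgamma`, `lbeta`, `lchoose`, `digamma`) are evaluated
  in log space; count laws remain stable to $K = 10^5$.
* Exact jump-law enumeration truncates count supports at a relative tail
  mass of $10^{-13}$ (renormalized) and guards total support size; the
  Monte-Carlo path (`model_sampler()` + `jd_empirical()`) covers laws whose
  exact support would be impractically large, such as merged-pool pairs
  with thousands of inputs.
* The Euler integrator resolves each rectangular pulse with
  $dt = \tau_s/20$ by default and scales pulse amplitudes to the realized
  on-grid duration so every pulse transfers exactly its dimensionless
  charge; the linear update recursion is evaluated blockwise by cumulative
  products to avoid per-step interpreter overhead.
* Exact spike-time ties merge into one event (`coincidence_tol = 0`); the
  tolerance is exposed for robustness checks only.
* All samplers take a single integer seed; identical (configuration, seed)
  pairs reproduce trains byte for byte.

## What the generator emulates — and what it does not

The synthetic models reproduce the *stationary, instantaneous-synchrony*
idealization: Poisson event times, i.i.d. jump vectors, exchangeable pools
with uniform rates and weights, perfect coactivation at zero lag (optionally
broadened by Gaussian jitter).  Real cortical input is richer: rates and
correlations drift over time, synchrony has characteristic timescales tied
to network state, correlations can be negative, synapses adapt and
depress.  Passing tests therefore demonstrate internal consistency of the
theory and its simulators under the stated assumptions — not that those
assumptions exhaust the biology.  The jitter comparison is the bridge: it
shows the stationary statistics are governed by synchrony measured at a
single effective timescale (about 25 ms windows for $\sigma_J = 50$ ms
jitter at membrane constant 15 ms).

## Problem sizes and limitations

The shipped tests use scaled-down study conditions — pools of tens to
hundreds of inputs, horizons of 15–120 s for moment estimation, 200–500 s
for spike-train correlations, 2500 s in the acceptance script's jitter
entry — chosen so each statistical comparison has standard errors well
below the effects being asserted.  Analytic pipelines run at the full
published pool sizes ($K_e = 1000$, $K_i = 250$) since they are closed
form.

Known limitations: only nonnegative spiking correlations are representable;
cross-neuron calibration covers symmetric pairs with uniform coefficients;
the moment solver is capped at order 4 (the multiset lattice grows
combinatorially); no transient (time-dependent) moments, spectra or
autocorrelation analysis; no recurrent coupling or spiking mechanism.
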