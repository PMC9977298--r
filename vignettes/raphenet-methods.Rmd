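---
title: "Models and methods behind raphenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind raphenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

raphenet models dorsal raphe nucleus (DRN) neurons — serotonin (5-HT)
projection neurons and somatostatin (SOM) GABA interneurons — with
generalized integrate-and-fire (GIF) models, and builds feedforward
inhibition (FFI) network simulations on top of them. This vignette
documents the models, the estimation procedures, every numerically
consequential choice, and what the synthetic-data generator does and does
not emulate.

Units are fixed package-wide: voltage in mV, time in ms, current in pA,
conductance in nS, capacitance in pF, so the membrane time constant
`tau_mem = C / g_l` is in ms directly and intensities are in Hz.

## Single-neuron models

### GIF

The subthreshold voltage obeys

$$C \frac{dV}{dt} = -g_l (V - E_l) - \sum_{\hat t_i < t} \eta(t - \hat t_i) + I(t),$$

with spikes emitted as an inhomogeneous Poisson ("escape-rate") process of
intensity

$$\lambda(t) = \lambda_0 \exp\!\left[\frac{V - V_T^* - \sum_{\hat t_i < t}\gamma(t - \hat t_i)}{\Delta V}\right],
\qquad \lambda_0 = 1\ \text{Hz}.$$

$\eta$ (the spike-triggered adaptation current, pA, positive =
hyperpolarizing) and $\gamma$ (the spike-triggered threshold movement, mV)
are sums of exponentials $\sum_j w_j e^{-s/\tau_j}$ over the lag $s$ since
each past spike. The basis time constants are fixed hyperparameters;
the default is log-spaced {10, 30, 100, 300, 1000, 3000} ms for both
filters, wide enough to express the multi-second adaptation seen in 5-HT
neurons while remaining identifiable from minute-long recordings. Both are
configurable.

On a spike the voltage is reset to `V_reset` and held there for an
absolute refractory period `T_ref`. Neither quantity is part of the
published model family's core equations, so the package makes a concrete,
testable choice: `T_ref` equals the post-spike half of the cell type's
spike exclusion window (6.5 ms for 5-HT, 4.0 ms for SOM and mPFC — the
same windows excluded when scoring dV/dt), and during fitting `V_reset`
is estimated as the mean recorded voltage `T_ref` after each spike onset.

### aGIF

The aGIF adds two Hodgkin-Huxley-style potassium currents to the
subthreshold equation:

$$I_A = \bar g_A\, m_\infty(V)\, h\, (V - E_K), \qquad
  I_K = \bar g_K\, n_\infty(V)\, (V - E_K),$$

with scaled-Boltzmann equilibrium gates
$x_\infty(V) = A_x / (1 + e^{-k_x (V - V_x^*)})$. The activation gates `m`
and `n` are instantaneous; the inactivation gate `h` relaxes toward
$h_\infty(V)$ with a single voltage-independent time constant `tau_h`.
Default gate parameters are the measured 5-HT values
(`serotonin_gates()`): m (A 1.61, k 0.0985 /mV, V* −23.7 mV),
h (1.03, −0.165, −59.2), n (1.55, 0.216, −24.3); `tau_h` defaults to
42.9 ms and `E_K` to −101 mV (room-temperature recording conditions;
−89.1 mV is appropriate near physiological temperature). With
$\bar g_A = \bar g_K = 0$ the aGIF reduces to the GIF exactly — bitwise,
since both run through the same integrator code path (a tested
invariant).

### iGIF

The iGIF augments the threshold instead: a variable $\theta$ is added to
the numerator of the escape-rate exponent and relaxes toward a
piecewise-constant function of voltage,
$\theta_\infty(V) = \beta_j$ for $V \in [A_j, A_{j+1})$ (5 bins by
default), with time constant $\tau_\theta$. Voltages outside the covered
range take the first/last step value.

### Toy LIF with an inactivating current

To isolate the effect of the A-type current the package includes a
nondimensional leaky integrate-and-fire model,

$$\frac{dV}{dt} = E_l - V - \bar g_A'\, m_\infty(V)\, h\, (V - E_K) + V_{inj}(t),$$

with time in units of `tau_mem`, conductance relative to `g_l`
(`g_A_eff` = $\bar g_A / g_l$), inputs as effective voltages
($V_{inj} = I / g_l$), a deterministic threshold (default −45 mV) and
instant reset. Spiking stochasticity enters only through optional white
current noise, which is how the population desynchronization experiments
are run. The reference configuration for those experiments is
`g_A_eff = 10` with `tau_h_eff = 1.2`.

## Numerical methods

All models integrate with the forward Euler method: `dt = 0.1` ms for the
GIF family (matching the 10 kHz sampling of the recordings the models are
meant for) and `0.001 tau_mem` for the toy model. The `h` (and iGIF
$\theta$) gates use the exact exponential update
`x' = x_inf + (x - x_inf) exp(-dt/tau)` at the global step, which is
unconditionally stable and lets the fitting stage reconstruct the
generator's gate trajectory from the voltage trace exactly.

Per-bin spike probability is `1 - exp(-λ dt)` with the exponent clamped at
700 before exponentiation. One uniform random number is consumed on every
step of a stochastic simulation — including refractory steps where it is
ignored — so that random streams stay aligned across conditions sharing a
seed (e.g. an intact and a manipulated network), and `identical (model,
input, seed)` always reproduces results bitwise. All generators take a
`seed` argument, use it through R's RNG, and restore the caller's RNG
state.

## Two-stage estimation

**Stage 1 (subthreshold, least squares).** The observed forward-difference
dV/dt is regressed on {V, 1, I, the η-basis convolved with the detected
spike train, and — for the aGIF — the two current regressors
$m_\infty(V) h (V - E_K)$ and $n_\infty(V)(V - E_K)$ with gates and
`tau_h` fixed from voltage clamp}, excluding a window around each spike
(1.5 ms before to 6.5/4.0 ms after). Coefficients map back to
C, g_l, E_l, the η weights and the maximal conductances. A rank-deficient
design aborts with the names of the collinear regressors. On noiseless
surrogate data this recovers the generator essentially exactly because
data generation and regression share the same discretization.

**Stage 2 (threshold, maximum likelihood).** The subthreshold voltage is
reconstructed with spikes clamped to the data, and the per-bin Poisson
log-likelihood $\sum_k [y_k u_k - \lambda_0 e^{u_k}\,dt]$ is maximized
over the natural parameters $(1/\Delta V,\ V_T^*/\Delta V,\
\gamma_j/\Delta V[,\ \beta_j^{(\theta)}/\Delta V])$, in which it is
concave. The optimizer is Newton ascent with backtracking line search;
accepted iterations never decrease the log-likelihood (asserted in
tests), and a non-finite likelihood aborts with the iteration index.
Refractory bins after each spike are excluded since the model assigns
them no hazard. For the iGIF, bin edges sit at the quintiles of the
reconstructed subthreshold voltage and $\tau_\theta$ is chosen by grid
search over {1, 3, 5, 10, 30, 100} ms on a held-out final 25% of each
sweep.

Note one identifiability limit: γ components with time constants at or
below the refractory gap (the 10 ms basis element) are constrained by very
few samples and carry large uncertainty; the fitted γ is reliable as a
function, less so coefficient-by-coefficient.

## Metrics

**Spike-window-excluded R²** on dV/dt uses the same per-spike exclusion
windows as the regression; zero-variance observations yield `NA` rather
than a number.

**Md\*** compares a set of recorded spike trains with a set of
model-predicted trains over repeats of the same frozen stimulus:

$$\mathrm{Md}^* = \frac{2\,(n_{dm} - c_{dm})}{(n_{dd} - c_{dd}) + (n_{mm} - c_{mm})},$$

where each $n$ is the mean coincidence count over ordered sweep pairs
(self-pairs included for the within-set terms) and each $c$ is the
analytic chance count $2 \nu_x \nu_y \Delta T$ for independent Poisson
trains at the sets' mean rates ($\Delta$ = 8 ms by default).
Coincidences are counted as boxcar-kernel spike pairs (the number of
cross-set spike pairs within $\Delta$), whose chance expectation equals
the analytic term exactly; a one-to-one matching count was considered and
rejected because it under-counts relative to that term and biases the
chance level a few hundredths below zero. With this definition an exact
copy of the validation set scores exactly 1 and statistically independent
predictions score 0 in expectation (both tested, the latter to ±0.05 over
100 draws).

**Intrinsic reliability** is the mean pairwise chance-corrected
coincidence factor
$(c_{ij} - e_{ij}) / (\sqrt{c_{ii} c_{jj}} - e_{ij})$ over distinct
sweep pairs. Recordings are excluded by QC if the spike-count-vs-sweep
Pearson correlation exceeds 0.9 (drift; the signed criterion, as stated)
or reliability falls below 0.1.

## The synthetic-data generator

`cell_type_template()` provides one ground-truth parameter set per cell
type. Membrane parameters are the measured population means (5-HT:
R 1.16 GΩ, C 67 pF; SOM: 1.07 GΩ, 43.5 pF; mPFC: 0.188 GΩ, 160.6 pF).
The 5-HT maximal conductances derive from the measured voltage-clamp
amplitudes: a 928 pA peak with a 142 pA steady state at −20 mV from a
−90 mV hold, with the default gates and E_K = −101 mV, gives
$\bar g_A \approx 10$ nS and $\bar g_K \approx 1.6$ nS. Adaptation-filter
magnitudes are not measured directly; they were calibrated once against
the measured f/I facts — 5-HT rheobase ≈ 34 pA, gain ≈ 52 Hz/nA and
≈ 2.8 Hz at 50 pA; SOM rheobase ≈ 11 pA, gain ≈ 87 Hz/nA — yielding
potent, protracted adaptation in the 5-HT template (η(0) ≈ 73 pA,
γ(0) ≈ 15.5 mV; simulated steady f/I gain ≈ 47 Hz/nA) and weaker
adaptation in SOM (≈ 109 Hz/nA). The SOM template lands steeper than the
measured mean gain; making it shallower would have required adaptation
comparable to 5-HT's, contradicting the measured filter asymmetry, and the
asymmetry was judged the more important feature to preserve.

`generate_bank()` jitters positive parameters lognormally
(mean-preserving) and potentials normally. Membrane CVs follow the
measured spreads (5-HT R CV 0.47, C CV 0.26; SOM 0.54/0.36); membrane
resistance, not leak conductance, is jittered so the bank's mean R matches
the template. SOM potential SDs (E_l 5 mV, V_T* 6 mV) are set so the SOM
rheobase spread approaches the measured ±16 pA — an order of magnitude
wider than naive mV-scale jitter would give, and functionally important:
it is what makes the SOM population recruit gradually across input
amplitudes.

Training/validation protocols use frozen Ornstein-Uhlenbeck (OU) noise
(exact discretization, stationary start): 60 s training and a distinct
10 s validation stimulus, with ≥ 9 validation repeats so the pairwise
metric terms are defined. Default OU parameters (μ 60/10/60 pA,
σ 60/60/250 pA for 5-HT/SOM/mPFC, τ 3 ms) were chosen to put template
firing in the 2–10 Hz range; with the 5-HT template's potent adaptation,
lower means cannot reach that range at any σ. Surrogate recordings write
a +30 mV one-sample marker at each spike so threshold-crossing detection
works as on experimental sweeps, and can add white Gaussian observation
noise to V.

What the generator does **not** emulate: action-potential waveforms
(spikes are point events with a marker sample), electrode artifacts and
access-resistance errors, slow drift and non-stationarity within a
recording, temperature effects beyond the two E_K settings, and any
within-cell-type covariance structure between parameters (all jitters are
independent). Passing recovery tests on surrogate data therefore shows
the estimators are correct and well-conditioned under the model's own
assumptions, not that real recordings satisfy those assumptions.

## Network simulations

Populations are bootstrapped by sampling with replacement from a bank
(400 SOM and 600 5-HT at full scale; the test suite uses 100 → 150 with
the connection probability raised from 0.02 to 0.08 so the expected
in-degree stays at the full-scale value of 8). Connectivity is i.i.d.
Bernoulli. GABA synapses are conductance-based with reversal −76.7 mV,
biexponential kinetics (τ_rise 1.44 ms, τ_decay 26 ms), 2 ms delay, and
the waveform normalized to unit peak so the quoted 0.3 nS is the literal
peak conductance per spike (the closed-form peak time, ≈ 4.41 ms after
the delay, is tested). Each trial draws fresh independent per-neuron
background OU noise (σ configurable, default 15 pA in
`simulate_network()`, 30 pA in the analysis experiments; τ 3 ms; zero
mean — the stimulus carries the mean); SOM are simulated first and their
delayed spikes drive the 5-HT conductances.

Population rates are spike counts per 1 ms bin normalized to Hz/neuron;
the time-integral times `n_neurons × n_trials` equals the spike count
exactly, at any bin width. A causal boxcar smoother is available and its
width is always reported with results that use it.

## Gain and derivative analyses

Input-output (IO) functions are rectified-linear fits
`rate = gain × max(0, I − threshold)` over ≥ 4 amplitudes (default grid:
8 steps spanning 0–120 pA); the threshold is found by 1-D search with the
slope in closed form. `time_resolved_gain()` fits an IO function per
post-onset time bin; the transient gain is the maximum within the first
100 ms after onset, the stationary gain the mean over the final 25% of
the response, and the adaptation ratio is peak gain over stationary gain.
The ratio deliberately uses the stationary mean, not the pointwise
minimum: at these population sizes the binwise minimum is noise-dominated,
and the build-up phase of a slow response would otherwise masquerade as
adaptation. For a memoryless population the ratio is 1 (tested
analytically on synthetic rectified-linear responses); the empirical
estimator carries a small upward bias because the peak is a maximum over
noisy bins, which is why comparisons across conditions use matched bin
widths and trial counts.

`derivative_encoding()` ramps the input from a baseline to a fixed target
(default +100 pA) at varying slopes and holds it there, so the final
intensity is identical across slopes and only dI/dt varies; the peak
smoothed 5-HT population rate is then regressed on slope per baseline.
This design is what makes the linearity R² informative: with a
slope-proportional final intensity the peak would track intensity and
every condition would look linear.

## Scale of the shipped experiments

The test suite runs every experiment at a reduced but statistically
meaningful scale, chosen as the package's own defaults for desk-scale
verification: 60-model banks, 100 SOM → 150 5-HT networks (in-degree 8),
1.1 s steps with 5–8 amplitudes and 3–8 trials, ramp grids of 5 slopes ×
4–6 trials, and 600-neuron toy populations. Full-scale runs (400 → 600,
20 trials, 5 s steps) use the same functions with the default arguments.

The parameter-recovery pipeline is exercised on a 5-HT template surrogate
with the threshold sharpness reduced to ΔV = 0.7 mV for the spike-time
prediction endpoint: at the template's ΔV = 2 mV the generator's own
repeats only reach Md* ≈ 0.65 (intrinsic reliability ≈ 0.19), so a
spike-time score there measures the generator's stochasticity, not the
fit. The parameter-recovery tolerances themselves are checked at the
template values.

## Known limitations

- The fitted γ basis is poorly identified at lags shorter than the
  refractory period (see above).
- Escape-rate spiking has no explicit action-potential shape; comparisons
  with data near the spike are only meaningful outside the exclusion
  windows.
- Under the synthetic banks, heterogeneous FFI shows a residual
  subtractive component (~10 pA threshold shift) alongside its dominant
  divisive effect, and homogenizing the SOM population does not produce a
  clearly larger transient shift: the synthetic SOM f/I keeps rising over
  the amplitude range, so even homogenized inhibition grows with input.
  Similarly, weakening the SOM drive by 30% raises the transient gain
  proportionally more than the stationary gain (the adaptation ratio
  rises ~25–35%). These are properties of the synthetic study conditions,
  not of the estimators; banks fitted to real recordings need not share
  them.
- iGIF fitting selects τ_θ from a small grid by holdout likelihood; the
  grid is a package choice and coarse by design.
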