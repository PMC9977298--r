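# raphenet

Single-neuron and network modeling of the dorsal raphe nucleus (DRN) in R:
augmented generalized integrate-and-fire (aGIF) models of serotonin (5-HT)
neurons, two-stage parameter estimation from current-clamp data,
spike-prediction metrics, and a feedforward-inhibition (FFI) population
simulator used to study how the DRN encodes the intensity and temporal
derivative of its inputs.

The package is written for cellular/computational neurophysiologists who
want to fit interpretable spiking models to patch-clamp recordings (or to
surrogate data with known ground truth) and then ask population-level
questions — gain, adaptation, divisive vs subtractive inhibition,
derivative encoding — with the same models.

## The models

The **GIF** combines a passive membrane with spike-triggered adaptation and
stochastic escape-rate spiking:

```
C dV/dt = -g_l (V - E_l) - Σ_{t̂_i < t} η(t - t̂_i) + I(t)
λ(t)    = λ₀ exp[ (V - V_T* - Σ γ(t - t̂_i)) / ΔV ],   λ₀ = 1 Hz
```

where η (pA) is the spike-triggered adaptation current, γ (mV) the
spike-triggered threshold movement (both sums of exponentials on a fixed
log-spaced basis), and spikes are emitted as an inhomogeneous Poisson
process with intensity λ(t); per time step, `P(spike) = 1 − exp(−λ dt)`.

The **aGIF** adds Hodgkin-Huxley-style potassium currents constrained by
voltage clamp, with scaled-Boltzmann gating
`x∞(V) = A / (1 + exp[−k (V − V*)])`:

```
I_A = ḡ_A m∞(V) h (V - E_K)     (inactivating, τ_h ≈ 43 ms)
I_K = ḡ_K n∞(V) (V - E_K)       (non-inactivating)
```

The **iGIF** instead augments the threshold with a variable θ whose
equilibrium is a piecewise-constant function of voltage. A nondimensional
**toy LIF + I_A** isolates the effect of the A-type current on spike
latency and population synchrony.

Estimation is two-stage, as is standard for this model family: subthreshold
parameters by least squares on dV/dt (excluding a window around each
spike), then threshold parameters by maximum likelihood of the observed
spike train (Newton ascent with line search; the likelihood is concave in
the natural parameters). Model quality is scored by the spike-window
excluded R² on dV/dt and by Md*, a chance-corrected spike-time coincidence
score (1 = perfect, 0 = chance, 8 ms precision).

Network models connect a bootstrapped population of 400 SOM interneuron
models to 600 5-HT neuron models with 2% random connectivity (expected
in-degree 8) through conductance-based GABA synapses (E_rev = −76.7 mV,
peak 0.3 nS, biexponential 1.44/26 ms, 2 ms delay).

## Worked example

Generate a surrogate recording from a known 5-HT aGIF, fit it back, and
inspect the estimates:

```r
library(raphenet)

truth <- cell_type_template("5-HT")
stim  <- ou_noise(mu = 100, sigma = 80, tau = 3, duration = 30000, seed = 11)
rec   <- generate_surrogate_recording(truth, stim, n_sweeps = 2, seed = 12)

fit <- fit_gif(rec, kind = "agif")
glance(fit)
#> # A tibble: 1 × 6
#>   kind  cell_type r_squared loglik n_spikes converged
#> 1 agif  5-HT          1.000   673.      227 TRUE
tidy(fit) |> head(6)
#>   term     estimate unit
#> 1 C          67.0   pF
#> 2 g_l         0.863 nS
#> 3 E_l       -70.0   mV
#> 4 V_T_star  -44.7   mV
#> 5 DeltaV      2.04  mV
#> 6 V_reset   -55     mV
```

The generator had C = 67 pF, g_l = 0.862 nS, E_l = −70 mV, V_T* = −45 mV,
ΔV = 2 mV: the subthreshold parameters come back to a fraction of a
percent and the threshold to a fraction of a millivolt. Gating curves are
characterized the same way:

```r
V <- seq(-90, -20, by = 1)
tidy(fit_gating_params(V, equilibrium_gate(V, serotonin_gates()$m)))
#>   term   estimate
#> 1 A        1.61
#> 2 k        0.0985
#> 3 V_star -23.7
```

Population experiments chain the same pieces:

```r
net  <- drn_network(generate_bank("SOM", 60, seed = 21),
                    generate_bank("5-HT", 60, seed = 22),
                    n_som = 100, n_ht = 150, p = 0.08, seed = 23)
resp <- step_response_experiment(net, n_trials = 8, seed = 31)
glance(time_resolved_gain(resp, gain_bin = 50))
```

`apply_manipulation()` implements the circuit dissections (zeroing or
raising ḡ_A, swapping adaptation filters between cell types, homogenizing
the SOM population, scaling the SOM drive), and `derivative_encoding()`
runs the ramp protocol that probes how linearly the 5-HT population's peak
rate reports dI/dt.

See `vignettes/raphenet-methods.Rmd` for the modeling assumptions, all
tunable parameters with units and defaults, and known limitations.

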