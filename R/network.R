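#' GABA synapse parameters
#'
#' Conductance-based GABA synapse with fixed reversal potential,
#' unit-peak biexponential kinetics and a fixed propagation delay.  The
#' conductance waveform for a presynaptic spike at time `t_hat` is
#' `g(t) = g_peak * [exp(-s/tau_decay) - exp(-s/tau_rise)] / norm` with
#' `s = t - t_hat - delay` and `norm` chosen so the waveform's maximum
#' equals 1 (the quoted conductance is therefore the literal peak).
#' Contributions from successive spikes sum linearly, and the synaptic
#' current is `I_syn = g(t) * (V - E_rev)`.
#'
#' @param E_rev Reversal potential, mV.
#' @param g_peak Peak conductance per spike, nS.
#' @param tau_rise,tau_decay Biexponential time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param delay Propagation delay, ms.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(E_rev = -76.7, g_peak = 0.3, tau_rise = 1.44,
                           tau_decay = 26.0, delay = 2.0) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0, delay >= 0, g_peak >= 0)
  structure(list(E_rev = E_rev, g_peak = g_peak, tau_rise = tau_rise,
                 tau_decay = tau_decay, delay = delay),
            class = "synapse_params")
}

#' Synaptic conductance trace from a presynaptic spike train
#'
#' @param presyn_spikes Presynaptic spike times, ms.
#' @param synapse A [synapse_params()].
#' @param t_grid Evaluation times, ms.
#' @return Conductance at `t_grid`, nS.
#' @export
gaba_conductance <- function(presyn_spikes, synapse, t_grid) {
  stopifnot(inherits(synapse, "synapse_params"))
  tr <- synapse$tau_rise; td <- synapse$tau_decay
  sstar <- tr * td / (td - tr) * log(td / tr)
  norm <- exp(-sstar / td) - exp(-sstar / tr)
  g <- numeric(length(t_grid))
  for (ts in presyn_spikes) {
    s <- t_grid - ts - synapse$delay
    on <- s > 0
    g[on] <- g[on] + synapse$g_peak * (exp(-s[on] / td) - exp(-s[on] / tr)) / norm
  }
  g
}

#' Bootstrap a population from a model bank
#'
#' Draws `n` models i.i.d. with replacement from the bank; the draw
#' indices are recorded for reproducibility.
#'
#' @param bank A [generate_bank()] result (or any `model_bank`).
#' @param n Population size (600 for 5-HT, 400 for SOM by default in
#'   [drn_network()]).
#' @param seed Optional integer seed.
#' @return An object of class `population`: list with `models`,
#'   `indices`, `cell_type`.
#' @export
build_population <- function(bank, n, seed = NULL) {
  stopifnot(inherits(bank, "model_bank"), length(bank$models) > 0)
  idx <- with_seed(seed, sample.int(length(bank$models), n, replace = TRUE))
  structure(list(models = bank$models[idx], indices = idx,
                 cell_type = bank$cell_type),
            class = "population")
}

#' Random feedforward connectivity
#'
#' Independent Bernoulli(`p`) binary connections from `n_pre`
#' presynaptic to `n_post` postsynaptic units; with the default sizes
#' and `p = 0.02` the expected number of GABAergic synapses per
#' postsynaptic 5-HT model is `400 * 0.02 = 8`.
#'
#' @param n_pre,n_post Population sizes.
#' @param p Connection probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A binary `n_pre` x `n_post` matrix.
#' @export
connect_ffi <- function(n_pre = 400, n_post = 600, p = 0.02, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  with_seed(seed,
    matrix(as.integer(runif(n_pre * n_post) < p), n_pre, n_post))
}

#' Feedforward-inhibition DRN network model
#'
#' A population of SOM interneuron models connected onto a population of
#' 5-HT neuron models in a feedforward arrangement via conductance-based
#' GABA synapses; both populations receive the (same) external input.
#'
#' @param som_bank,ht_bank Model banks for the two populations.
#' @param n_som,n_ht Population sizes.
#' @param p Connection probability.
#' @param synapse A [synapse_params()].
#' @param seed Integer seed for the population bootstrap and
#'   connectivity.
#' @return An object of class `network_model`.
#' @export
drn_network <- function(som_bank, ht_bank, n_som = 400, n_ht = 600,
                        p = 0.02, synapse = synapse_params(), seed = 1) {
  with_seed(seed, {
    som_pop <- build_population(som_bank, n_som)
    ht_pop <- build_population(ht_bank, n_ht)
    W <- connect_ffi(n_som, n_ht, p)
  })
  structure(list(som_pop = som_pop, ht_pop = ht_pop, W = W,
                 synapse = synapse, input_scale_som = 1, seed = seed),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d SOM -> %d 5-HT, %d synapses (mean in-degree %.2f)\n",
              length(x$som_pop$models), length(x$ht_pop$models),
              sum(x$W), mean(colSums(x$W))))
  if (x$input_scale_som != 1)
    cat(sprintf("  SOM input scaled by %.2f\n", x$input_scale_som))
  invisible(x)
}

# Flatten a population into the matrices the C++ population loop expects.
population_matrices <- function(pop) {
  ps <- lapply(pop$models, as_sim_pars)
  pars <- t(vapply(ps, function(p)
    c(p$C, p$g_l, p$E_l, p$V_T_star, p$DeltaV, p$V_reset, p$T_ref,
      p$g_A, p$g_K, p$E_K, p$tau_h), numeric(11)))
  list(pars = pars,
       eta_w = t(vapply(ps, `[[`, numeric(length(ps[[1]]$eta_w)), "eta_w")),
       eta_tau = ps[[1]]$eta_tau,
       gamma_w = t(vapply(ps, `[[`, numeric(length(ps[[1]]$gamma_w)), "gamma_w")),
       gamma_tau = ps[[1]]$gamma_tau,
       m_gate = ps[[1]]$m_gate, h_gate = ps[[1]]$h_gate,
       n_gate = ps[[1]]$n_gate)
}

simulate_population_once <- function(pop, I, dt, noise_sd, noise_tau,
                                     arrivals = NULL, synapse = NULL) {
  pm <- population_matrices(pop)
  syn <- synapse %||% synapse_params()
  sim_population_cpp(pm$pars, pm$eta_w, pm$eta_tau, pm$gamma_w, pm$gamma_tau,
                     pm$m_gate, pm$h_gate, pm$n_gate, I, dt,
                     noise_sd, noise_tau,
                     arrivals %||% list(), syn$E_rev, syn$g_peak,
                     syn$tau_rise, syn$tau_decay, 1)
}

#' Simulate the feedforward-inhibition network
#'
#' For each trial: fresh independent background noise is drawn for every
#' neuron, the SOM population is simulated first, its spikes (after the
#' propagation delay) drive GABA conductances onto the connected 5-HT
#' models, and the 5-HT population is simulated.  Results are collected
#' as tidy spike tables and trial-averaged population rates.
#'
#' @param net A [drn_network()].
#' @param input_som,input_5ht Input current to each population: stimulus
#'   tibbles or numeric vectors of equal length, pA.  `input_som` is
#'   multiplied by the network's SOM input scale (see
#'   [apply_manipulation()]).
#' @param noise_sd,noise_tau Per-neuron background OU noise SD (pA) and
#'   correlation time (ms).
#' @param n_trials Number of independent trials.
#' @param dt Time step, ms.
#' @param rate_bin Width of the population-rate bins, ms.
#' @param seed Optional master seed; identical seeds reproduce the
#'   simulation bitwise.
#' @return An object of class `network_sim`: list with `spikes` (tibble:
#'   `population`, `trial`, `neuron`, `time`), `rates` (tibble:
#'   `population`, `t`, `rate` in Hz/neuron), sizes and timing info.
#' @export
simulate_network <- function(net, input_som, input_5ht,
                             noise_sd = 15, noise_tau = 3,
                             n_trials = 20, dt = 0.1, rate_bin = 1,
                             seed = NULL) {
  stopifnot(inherits(net, "network_model"))
  I_som <- stimulus_current(input_som) * net$input_scale_som
  I_ht <- stimulus_current(input_5ht)
  if (length(I_som) != length(I_ht))
    abort("SOM and 5-HT input traces must have the same length")
  duration <- length(I_ht) * dt
  n_som <- length(net$som_pop$models); n_ht <- length(net$ht_pop$models)

  res <- with_seed(seed, purrr::map_dfr(seq_len(n_trials), function(trial) {
    som_spk <- simulate_population_once(net$som_pop, I_som, dt,
                                        noise_sd, noise_tau)
    arrivals <- lapply(seq_len(n_ht), function(j) {
      pre <- which(net$W[, j] == 1)
      if (length(pre) == 0) return(numeric(0))
      sort(unlist(som_spk[pre]) + net$synapse$delay)
    })
    ht_spk <- simulate_population_once(net$ht_pop, I_ht, dt,
                                       noise_sd, noise_tau,
                                       arrivals, net$synapse)
    dplyr::bind_rows(
      tibble(population = "SOM", trial = trial,
             neuron = rep(seq_len(n_som), lengths(som_spk)),
             time = unlist(som_spk) %||% numeric(0)),
      tibble(population = "5-HT", trial = trial,
             neuron = rep(seq_len(n_ht), lengths(ht_spk)),
             time = unlist(ht_spk) %||% numeric(0)))
  }))

  rates <- dplyr::bind_rows(
    population_rate(res$time[res$population == "SOM"], n_som, n_trials,
                    duration, rate_bin) |>
      dplyr::mutate(population = "SOM", .before = 1),
    population_rate(res$time[res$population == "5-HT"], n_ht, n_trials,
                    duration, rate_bin) |>
      dplyr::mutate(population = "5-HT", .before = 1))

  structure(list(spikes = res, rates = rates, n_som = n_som, n_ht = n_ht,
                 n_trials = n_trials, duration = duration, dt = dt,
                 rate_bin = rate_bin),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf("<network_sim> %d trials, %.3g ms; %d spikes\n",
              x$n_trials, x$duration, nrow(x$spikes)))
  invisible(x)
}

#' Trial-averaged population firing rate
#'
#' Bins spike times and normalizes to Hz per neuron:
#' `count / (n_neurons * n_trials * bin)`.  The time-integral of the
#' rate times `n_neurons * n_trials` equals the total spike count
#' exactly, whatever the bin width.
#'
#' @param spike_times Pooled spike times (all neurons and trials), ms.
#' @param n_neurons,n_trials Normalization counts.
#' @param duration Trace duration, ms.
#' @param bin Bin width, ms.
#' @param smooth Optional causal boxcar width, ms.
#' @return A tibble with columns `t` (bin start, ms) and `rate`
#'   (Hz/neuron).
#' @export
population_rate <- function(spike_times, n_neurons, n_trials, duration,
                            bin = 1, smooth = NULL) {
  stopifnot(bin > 0)
  edges <- seq(0, duration + bin, by = bin)
  counts <- graphics::hist(spike_times, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  rate <- 1000 * counts / (n_neurons * n_trials * bin)
  if (!is.null(smooth) && smooth > bin) {
    k <- max(1L, round(smooth / bin))
    rate <- as.numeric(stats::filter(rate, rep(1 / k, k), sides = 1))
    rate[is.na(rate)] <- 0
  }
  tibble(t = edges[-length(edges)], rate = rate)
}

#' Network manipulations
#'
#' Returns a modified copy of the network implementing one of the
#' manipulations used to dissect the circuit:
#' \describe{
#'   \item{`set_gA`}{Set the maximal A-type conductance of every 5-HT
#'     model to `value` (nS), leaving all else untouched.}
#'   \item{`swap_adaptation`}{For each 5-HT model, draw one random model
#'     from `source_bank` and copy its `eta` and `gamma` filter
#'     coefficients only.}
#'   \item{`homogenize_som`}{Replace every SOM model's parameters by the
#'     per-parameter median over the current SOM population.}
#'   \item{`scale_som_input`}{Multiply the drive to the SOM population
#'     by `value` (e.g. 0.7 for a 30% weakening), leaving the 5-HT
#'     drive intact.}
#'   \item{`disconnect`}{Remove all SOM to 5-HT synapses (no-FFI
#'     condition).}
#' }
#'
#' @param net A [drn_network()].
#' @param which Manipulation name.
#' @param value Numeric argument (`set_gA`, `scale_som_input`).
#' @param source_bank Source bank (`swap_adaptation`).
#' @param seed Optional seed (`swap_adaptation`).
#' @return A modified `network_model`.
#' @export
apply_manipulation <- function(net,
                               which = c("set_gA", "swap_adaptation",
                                         "homogenize_som",
                                         "scale_som_input", "disconnect"),
                               value = NULL, source_bank = NULL,
                               seed = NULL) {
  which <- match.arg(which)
  out <- net
  if (which == "set_gA") {
    stopifnot(is.numeric(value), value >= 0)
    out$ht_pop$models <- lapply(net$ht_pop$models, function(p) {
      if (!inherits(p, "agif_params")) {
        p <- agif_params(p$C, p$g_l, p$E_l, p$eta, p$gamma, p$V_T_star,
                         p$DeltaV, p$V_reset, p$T_ref,
                         k_currents = potassium_current_model(g_A_bar = 0,
                                                              g_K_bar = 0))
      }
      p$k_currents$g_A_bar <- value
      p
    })
  } else if (which == "swap_adaptation") {
    stopifnot(inherits(source_bank, "model_bank"))
    out$ht_pop$models <- with_seed(seed,
      lapply(net$ht_pop$models, function(p) {
        src <- source_bank$models[[sample.int(length(source_bank$models), 1)]]
        p$eta <- filter_coeffs(src$eta$weights, p$eta$timescales)
        p$gamma <- filter_coeffs(src$gamma$weights, p$gamma$timescales)
        p
      }))
  } else if (which == "homogenize_som") {
    tab <- as_tibble(structure(list(cell_type = net$som_pop$cell_type,
                                    models = net$som_pop$models,
                                    provenance = list(kind = "population")),
                               class = "model_bank"))
    med <- dplyr::summarise(tab, dplyr::across(-model, stats::median))
    eta_w <- apply(vapply(net$som_pop$models,
                          function(p) p$eta$weights,
                          numeric(length(net$som_pop$models[[1]]$eta$weights))),
                   1, stats::median)
    gam_w <- apply(vapply(net$som_pop$models,
                          function(p) p$gamma$weights,
                          numeric(length(net$som_pop$models[[1]]$gamma$weights))),
                   1, stats::median)
    taus <- net$som_pop$models[[1]]$eta$timescales
    hom <- gif_params(med$C, med$g_l, med$E_l,
                      filter_coeffs(eta_w, taus),
                      filter_coeffs(gam_w,
                                    net$som_pop$models[[1]]$gamma$timescales),
                      med$V_T_star, med$DeltaV, med$V_reset, med$T_ref)
    out$som_pop$models <- rep(list(hom), length(net$som_pop$models))
  } else if (which == "scale_som_input") {
    stopifnot(is.numeric(value), value >= 0)
    out$input_scale_som <- value
  } else if (which == "disconnect") {
    out$W[] <- 0L
  }
  out
}
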