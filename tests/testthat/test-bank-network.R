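test_that("synthetic banks reproduce the template's mean membrane parameters", {
  bank <- generate_bank("5-HT", 500, seed = 71)
  tab <- tibble::as_tibble(bank)
  expect_lt(abs(mean(tab$R) / 1.16 - 1), 0.05)
  expect_lt(abs(mean(tab$C) / 67.0 - 1), 0.05)
  # zero heterogeneity: identical copies of the template
  hz <- heterogeneity_defaults("5-HT")
  hz[] <- 0
  b0 <- generate_bank("5-HT", 5, heterogeneity = hz, seed = 1)
  expect_identical(b0$models[[1]], b0$models[[5]])
  expect_identical(b0$models[[1]], cell_type_template("5-HT"))
})

test_that("SOM banks are more heterogeneous than 5-HT banks", {
  set.seed(1)
  som <- tibble::as_tibble(generate_bank("SOM", 300, seed = 72))
  ht <- tibble::as_tibble(generate_bank("5-HT", 300, seed = 73))
  # relative spread of gain-related parameters (adaptation, excitability)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(som$eta_integral), cv(ht$eta_integral))
  expect_gt(sd(som$V_T_star - som$E_l), sd(ht$V_T_star - ht$E_l))
})

test_that("population bootstrap draws with replacement, reproducibly", {
  bank <- generate_bank("SOM", 10, seed = 74)
  p1 <- build_population(bank, 50, seed = 5)
  p2 <- build_population(bank, 50, seed = 5)
  expect_identical(p1$indices, p2$indices)
  one <- structure(list(cell_type = "SOM", models = bank$models[1],
                        provenance = bank$provenance), class = "model_bank")
  pn <- build_population(one, 7, seed = 1)
  expect_true(all(pn$indices == 1))
})

test_that("feedforward connectivity matches its Bernoulli construction", {
  expect_true(all(connect_ffi(50, 40, 0, seed = 1) == 0))
  expect_true(all(colSums(connect_ffi(50, 40, 1, seed = 1)) == 50))
  # mean realized in-degree across seeds close to n_pre * p
  deg <- vapply(1:100, function(s)
    mean(colSums(connect_ffi(400, 60, 0.02, seed = s))), 0)
  expect_lt(abs(mean(deg) - 8), 0.5)
})

test_that("GABA conductance has the stated biexponential waveform", {
  syn <- synapse_params()
  t <- seq(0, 60, by = 0.01)
  g <- gaba_conductance(0, syn, t)
  expect_true(all(g[t <= syn$delay] == 0))
  # peak value equals g_peak at the closed-form peak time after the delay
  sstar <- syn$tau_rise * syn$tau_decay / (syn$tau_decay - syn$tau_rise) *
    log(syn$tau_decay / syn$tau_rise)
  expect_equal(sstar, 4.41, tolerance = 0.01)
  expect_equal(max(g), syn$g_peak, tolerance = 1e-5)
  expect_equal(t[which.max(g)], syn$delay + sstar, tolerance = 0.01)
  # linear summation across spikes
  g2 <- gaba_conductance(c(0, 10), syn, t)
  expect_equal(g2, g + gaba_conductance(10, syn, t))
})

test_that("population rates conserve spike counts exactly", {
  expect_equal(population_rate(numeric(0), 10, 2, 1000)$rate, rep(0, 1001))
  set.seed(81)
  spk <- runif(600, 0, 1000) # 600 neurons firing once in 1 s, one trial
  r <- population_rate(spk, 600, 1, 1000, bin = 1000)
  expect_equal(r$rate[1], 1) # 1 Hz/neuron
  r1 <- population_rate(spk, 600, 1, 1000, bin = 2)
  r2 <- population_rate(spk, 600, 1, 1000, bin = 1)
  expect_equal(sum(r1$rate) * 2, sum(r2$rate) * 1) # time-integral preserved
  expect_equal(sum(r2$rate) / 1000 * 600, 600) # total count
})

test_that("network manipulations modify deep copies as specified", {
  som <- generate_bank("SOM", 20, seed = 91)
  ht <- generate_bank("5-HT", 20, seed = 92)
  net <- drn_network(som, ht, n_som = 30, n_ht = 40, p = 0.1, seed = 93)

  n0 <- apply_manipulation(net, "set_gA", value = 0)
  expect_true(all(vapply(n0$ht_pop$models,
                         function(p) p$k_currents$g_A_bar, 0) == 0))
  # all else untouched
  expect_identical(n0$ht_pop$models[[1]]$eta, net$ht_pop$models[[1]]$eta)
  expect_identical(n0$som_pop, net$som_pop)

  nh <- apply_manipulation(net, "homogenize_som")
  expect_identical(nh$som_pop$models[[1]], nh$som_pop$models[[17]])
  expect_equal(nh$som_pop$models[[1]]$C,
               median(vapply(net$som_pop$models, `[[`, 0, "C")))

  ns <- apply_manipulation(net, "scale_som_input", value = 0.7)
  expect_equal(ns$input_scale_som, 0.7)
  expect_identical(ns$ht_pop, net$ht_pop)

  nw <- apply_manipulation(net, "swap_adaptation", source_bank = som, seed = 3)
  src_ints <- vapply(som$models, function(p) filter_integral(p$eta), 0)
  new_ints <- vapply(nw$ht_pop$models, function(p) filter_integral(p$eta), 0)
  expect_true(all(new_ints %in% src_ints))
  # membrane parameters untouched by the swap
  expect_identical(nw$ht_pop$models[[1]]$C, net$ht_pop$models[[1]]$C)

  expect_error(apply_manipulation(net, "not_a_thing"))
})

test_that("network simulation is reproducible and FFI only suppresses 5-HT", {
  som <- generate_bank("SOM", 20, seed = 94)
  ht <- generate_bank("5-HT", 20, seed = 95)
  net <- drn_network(som, ht, n_som = 40, n_ht = 50, p = 0.2, seed = 96)
  stim <- make_step(0, 80, 100, 800, 800)
  s1 <- simulate_network(net, stim, stim, n_trials = 2, noise_sd = 30,
                         seed = 7)
  s2 <- simulate_network(net, stim, stim, n_trials = 2, noise_sd = 30,
                         seed = 7)
  expect_identical(s1$spikes, s2$spikes)
  expect_error(simulate_network(net, stim$I[1:100], stim, seed = 1),
               "same length")
  # disconnecting the inhibitory synapses cannot decrease 5-HT output
  s0 <- simulate_network(apply_manipulation(net, "disconnect"), stim, stim,
                         n_trials = 2, noise_sd = 30, seed = 7)
  n_ffi <- sum(s1$spikes$population == "5-HT")
  n_open <- sum(s0$spikes$population == "5-HT")
  expect_lte(n_ffi, n_open)
  # SOM output identical under identical seeds (simulated first)
  expect_identical(s1$spikes$time[s1$spikes$population == "SOM"],
                   s0$spikes$time[s0$spikes$population == "SOM"])
})
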