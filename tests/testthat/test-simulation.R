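empty_network <- function() {
  kb <- knowledge_base(NULL)
  structure(list(populations = build_populations_empty(), izhikevich = kb$izhikevich,
                 groups = tibble::tibble(), scale = 1, master_seed = 1),
            class = "network_spec")
}

build_populations_empty <- function() {
  tibble::tibble(type_name = character(), subregion = character(),
                 polarity = character(), size = integer(),
                 first_index = integer())
}

one_neuron_network <- function(params = rs_params()) {
  structure(list(
    populations = tibble::tibble(type_name = "Solo", subregion = "CA3",
                                 polarity = "excitatory", size = 1L,
                                 first_index = 1L),
    izhikevich = tibble::tibble(
      name = "Solo", C_pF = params$C, k_nS_per_mV = params$k,
      Vr_mV = params$Vr, Vt_mV = params$Vt, Vpeak_mV = params$Vpeak,
      Vmin_mV = params$Vmin, a_per_ms = params$a, b_nS = params$b,
      d_pA = params$d, is_default = FALSE),
    groups = tibble::tibble(), scale = 1, master_seed = 1),
    class = "network_spec")
}

# driver (A) spikes tonically and excites a silent follower (B) through a
# single reliable synapse with a fixed delay
driver_follower_network <- function(delay_ms = 1, g_nS = 5) {
  p <- rs_params()
  izh_row <- function(nm) tibble::tibble(
    name = nm, C_pF = p$C, k_nS_per_mV = p$k, Vr_mV = p$Vr, Vt_mV = p$Vt,
    Vpeak_mV = p$Vpeak, Vmin_mV = p$Vmin, a_per_ms = p$a, b_nS = p$b,
    d_pA = p$d, is_default = FALSE)
  edges <- tibble::tibble(pre_index = 1L, post_index = 1L,
                          delay_ms = delay_ms)
  structure(list(
    populations = tibble::tibble(
      type_name = c("Driver", "Follower"), subregion = "CA3",
      polarity = c("excitatory", "excitatory"), size = c(1L, 1L),
      first_index = c(1L, 2L)),
    izhikevich = dplyr::bind_rows(izh_row("Driver"), izh_row("Follower")),
    groups = tibble::tibble(
      pre = "Driver", post = "Follower", probability = 1, contacts = 1,
      g_nS = g_nS, tau_d_ms = 5, tau_r_ms = 400, tau_f_ms = 50, U = 0.5,
      reversal_mV = 0, n_edges = 1L, edges = list(edges)),
    scale = 1, master_seed = 1),
    class = "network_spec")
}

test_that("an empty network yields an empty result", {
  res <- run_simulation(empty_network(), duration_ms = 100)
  expect_equal(nrow(res$spikes), 0)
  expect_equal(nrow(res$traces), 0)
  expect_equal(nrow(population_rates(res)), 0)
})

test_that("a synapse-free neuron reproduces the single-neuron simulator", {
  p <- rs_params()
  net <- one_neuron_network(p)
  amp <- 250
  res <- run_simulation(net, duration_ms = 500,
                        drive = background_drive(amp, 0), seed = 1)
  ref <- simulate_izhikevich(
    p, step_protocol(amp, onset_ms = 0, duration_ms = 500, tail_ms = 0))
  expect_equal(res$spikes$time_ms, ref$spike_times_ms)
})

test_that("postsynaptic conductance obeys the presynaptic spike plus delay", {
  delay <- 1.5
  net <- driver_follower_network(delay_ms = delay)
  res <- run_simulation(net, duration_ms = 200, dt_ms = 0.1,
                        drive = background_drive(
                          mean_pA = c(Driver = 200, Follower = 0),
                          sd_pA = 0),
                        seed = 1)
  first_spike <- min(res$spikes$time_ms[res$spikes$population == "Driver"])
  syn <- res$syn_abs[, 1]
  t_axis <- seq_along(syn) * res$dt_ms
  onset <- t_axis[which(syn > 0)[1]]
  # conductance must appear exactly one step after spike + delay (arrival
  # step), never earlier (causality)
  expect_gte(onset, first_spike + delay)
  expect_lte(onset, first_spike + delay + 2 * res$dt_ms)
  expect_true(all(syn[t_axis < first_spike + delay] == 0))
})

test_that("simulation results are bit-identical across repeated runs", {
  net <- build_network(make_toy_circuit(), scale = 0.2, seed = 2)
  r1 <- run_simulation(net, duration_ms = 150, seed = 42)
  r2 <- run_simulation(net, duration_ms = 150, seed = 42)
  expect_identical(as.data.frame(r1$spikes), as.data.frame(r2$spikes))
  expect_identical(r1$syn_abs, r2$syn_abs)
  r3 <- run_simulation(net, duration_ms = 150, seed = 43)
  expect_false(identical(as.data.frame(r1$spikes), as.data.frame(r3$spikes)))
})

test_that("the LFP proxy is zero without synaptic activity and scales linearly", {
  net <- one_neuron_network()
  res <- run_simulation(net, duration_ms = 100,
                        drive = background_drive(250, 0))
  expect_true(all(lfp_proxy(res, populations = "Solo")$lfp_pA == 0))
  net2 <- driver_follower_network()
  res2 <- run_simulation(net2, duration_ms = 200, dt_ms = 0.1,
                         drive = background_drive(
                           mean_pA = c(Driver = 200, Follower = 0),
                           sd_pA = 0))
  lfp <- lfp_proxy(res2, populations = "Follower", downsample_Hz = NULL)
  expect_gt(max(lfp$lfp_pA), 0)
  doubled <- res2
  doubled$syn_abs <- 2 * res2$syn_abs
  lfp2 <- lfp_proxy(doubled, populations = "Follower", downsample_Hz = NULL)
  expect_equal(lfp2$lfp_pA, 2 * lfp$lfp_pA)
  expect_error(lfp_proxy(res2, populations = character(0)), "empty")
})

test_that("a single PSC's envelope decays with the synaptic time constant", {
  net <- driver_follower_network(delay_ms = 1, g_nS = 0.001)
  # drive one spike only: strong brief drive via short duration
  res <- run_simulation(net, duration_ms = 60, dt_ms = 0.1,
                        drive = background_drive(
                          mean_pA = c(Driver = 120, Follower = 0), sd_pA = 0))
  spk <- res$spikes$time_ms[res$spikes$population == "Driver"]
  syn <- res$syn_abs[, 1]
  t_axis <- seq_along(syn) * res$dt_ms
  win <- t_axis > spk[1] + 1 & t_axis < min(c(spk[2], 60), na.rm = TRUE)
  g_traj <- syn[win]
  # log-linear fit recovers tau_d = 5 ms (voltage barely moves with tiny g)
  fit <- stats::lm(log(g_traj) ~ t_axis[win])
  expect_equal(-1 / coef(fit)[[2]], 5, tolerance = 0.05)
})

test_that("population rates count spikes per neuron per second", {
  net <- one_neuron_network()
  res <- run_simulation(net, duration_ms = 1000,
                        drive = background_drive(250, 0))
  pr <- population_rates(res)
  expect_equal(pr$rate_Hz, length(res$spikes$time_ms) / 1)
  silent <- run_simulation(net, duration_ms = 100,
                           drive = background_drive(0, 0))
  expect_equal(population_rates(silent)$rate_Hz, 0)
})

test_that("non-finite dynamics abort with a diagnostic naming the population", {
  net <- one_neuron_network()
  expect_error(run_simulation(net, duration_ms = 100,
                              drive = background_drive(-1e300, 0)),
               "non-finite dynamics.*Solo")
})

test_that("band-pass keeps in-band sinusoids and rejects remote ones", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  x8 <- sin(2 * pi * 8 * t)
  theta <- bandpass_filter(x8, 4, 12, fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  expect_gt(max(abs(theta[mid])), 0.9)
  ripple <- bandpass_filter(x8, 150, 200, fs)
  expect_lt(max(abs(ripple[mid])), 0.1)
  expect_equal(bandpass_filter(rep(0, 500), 4, 12, fs), rep(0, 500))
  expect_error(bandpass_filter(x8, 200, 100, fs), "lo_Hz < hi_Hz")
  expect_error(bandpass_filter(x8, 100, 600, fs), "lo_Hz < hi_Hz")
})

test_that("band decomposition returns the three canonical bands", {
  bands <- hippocampal_bands()
  expect_equal(bands$lo_Hz, c(4, 25, 150))
  expect_equal(bands$hi_Hz, c(12, 100, 200))
  net <- build_network(make_toy_circuit(), scale = 0.2, seed = 2)
  res <- run_simulation(net, duration_ms = 400, seed = 1)
  lfp <- lfp_proxy(res)
  out <- band_filtered_lfp(lfp)
  expect_setequal(levels(out$band), c("theta", "gamma", "ripple"))
  expect_equal(nrow(out), 3 * nrow(lfp))
})

test_that("total spike count is stable under step refinement", {
  net <- build_network(make_ca3_demo(), scale = 0.001, seed = 1)
  drv <- ca3_demo_drive()
  drv$sd_pA <- 0  # per-step noise is not step-size invariant
  n1 <- nrow(run_simulation(net, duration_ms = 300, dt_ms = 0.1,
                            drive = drv, seed = 1)$spikes)
  n2 <- nrow(run_simulation(net, duration_ms = 300, dt_ms = 0.05,
                            drive = drv, seed = 1)$spikes)
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.05)
})
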