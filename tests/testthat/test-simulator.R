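test_that("a neuron at its resting equilibrium stays silent without input", {
  b <- 0.2
  v_star <- (-4.8 - sqrt(4.8^2 - 4 * 0.04 * 140)) / (2 * 0.04)  # stable root
  st <- c(v_star, b * v_star)
  for (k in 1:500) {
    out <- step_neuron(st, 0, c(0.02, 0.2, -65, 8))
    expect_false(out$spiked)
    st <- out$state
  }
  expect_equal(unname(st[1]), v_star, tolerance = 1e-6)
})

test_that("tonic regular spiking matches a fine-step reference integration", {
  params <- c(a = 0.02, b = 0.2, c = -65, d = 8)
  # package scheme, dt = 1 ms
  st <- c(-70, -14); n_coarse <- 0
  for (k in 1:1000) {
    out <- step_neuron(st, 10, params)
    if (out$spiked) n_coarse <- n_coarse + 1
    st <- out$state
  }
  # independent reference: plain Euler at dt = 0.01 ms
  v <- -70; u <- -14; n_fine <- 0; dt <- 0.01
  for (k in seq_len(1000 / dt)) {
    if (v >= 30) { v <- params["c"]; u <- u + params["d"]; n_fine <- n_fine + 1 }
    dv <- 0.04 * v^2 + 5 * v + 140 - u + 10
    du <- params["a"] * (params["b"] * v - u)
    v <- v + dt * dv; u <- u + dt * du
  }
  expect_gt(n_coarse, 3)                      # actually spiking periodically
  expect_lte(abs(n_coarse - n_fine), 1)
  # inter-spike intervals constant under constant drive
  st <- c(-70, -14); times <- c()
  for (k in 1:2000) {
    out <- step_neuron(st, 10, params)
    if (out$spiked) times <- c(times, k)
    st <- out$state
  }
  expect_lte(diff(range(diff(times[-1]))), 1)
})

test_that("stdp_update matches the exponential closed form", {
  expect_equal(stdp_update(20), 0.1 * exp(-1))
  expect_equal(stdp_update(20), 0.03679, tolerance = 1e-3)
  expect_equal(stdp_update(-10), -0.12 * exp(-0.5))
  expect_equal(stdp_update(1e9), 0)
  expect_equal(stdp_update(0), 0)
  expect_equal(stdp_update(5, A_plus = 0.2, tau_plus = 10), 0.2 * exp(-0.5))
})

test_that("an empty network without noise stays silent forever", {
  net <- structural_network(matrix(0, 4, 4), matrix(0L, 4, 4), 4, "RND", 1)
  cfg <- simulation_config(duration = 5, stdp_freeze_time = 1, noise_amp = 0)
  spk <- run_network(net, cfg, seed = 1)
  expect_equal(nrow(spk$spikes), 0)
})

test_that("spikes are delivered after the conduction delay", {
  # A -> B, strong synapse, 5 ms delay; drive is sparse so most B spikes are
  # transmitted A spikes
  a <- matrix(0, 2, 2); a[1, 2] <- 25
  dl <- matrix(0L, 2, 2); dl[1, 2] <- 5L
  net <- structural_network(a, dl, 2, "RND", 1)
  cfg <- simulation_config(duration = 200, stdp_freeze_time = 0,
                           noise = "gaussian", noise_amp = 3)
  spk <- run_network(net, cfg, seed = 5)
  ta <- spk$spikes$time_ms[spk$spikes$neuron == 1]
  tb <- spk$spikes$time_ms[spk$spikes$neuron == 2]
  expect_gt(length(ta), 20)
  lags <- unlist(lapply(tb, function(t) {
    prev <- ta[ta < t & ta > t - 15]
    if (length(prev)) t - max(prev) else NULL
  }))
  # dominant transmission latency = delay + ~1-2 ms integration
  expect_gte(median(lags), 5)
  expect_lte(median(lags), 8)
  expect_gt(mean(lags >= 5 & lags <= 9), 0.5)
})

test_that("simulation is reproducible and respects STDP constraints", {
  net <- generate_random(60, 48, 10, seed = 2)
  cfg <- simulation_config(duration = 30, stdp_freeze_time = 10)
  s1 <- run_network(net, cfg, seed = 9)
  s2 <- run_network(net, cfg, seed = 9)
  expect_identical(s1$spikes, s2$spikes)
  wf <- attr(s1, "weights_final")
  wz <- attr(s1, "weights_at_freeze")
  # weights frozen after stdp_freeze_time
  expect_identical(wf, wz)
  # support unchanged, excitatory weights clipped to [0, w_max]
  expect_true(all((wf != 0) == (net$adjacency != 0) |
                  (net$adjacency > 0 & wf == 0)))  # excitatory may decay to 0
  expect_true(all(wf[1:48, ] >= 0))
  expect_true(all(wf[1:48, ] <= cfg$w_max))
  # inhibitory weights never change
  expect_identical(wf[49:60, ], net$adjacency[49:60, ])
})

test_that("excitatory weights spread towards both STDP extremes", {
  net <- generate_random(100, 80, 20, seed = 3)
  cfg <- simulation_config(duration = 120, stdp_freeze_time = 120)
  spk <- run_network(net, cfg, seed = 4)
  w0 <- net$adjacency[1:80, ][net$adjacency[1:80, ] != 0]
  w1 <- attr(spk, "weights_final")[1:80, ][net$adjacency[1:80, ] != 0]
  expect_gt(sd(w1), sd(w0))                 # distribution spreads out
  expect_gt(mean(w1 > 9), 0.01)             # mass at the upper clip
  expect_gt(mean(w1 < 5), 0.01)             # depressed mass below the mode
})

test_that("a large network produces sustained, burst-rich activity", {
  net <- generate_random(seed = 6)
  cfg <- simulation_config(duration = 60, stdp_freeze_time = 30)
  spk <- run_network(net, cfg, seed = 7)
  mfr <- mean_firing_rate(spk)
  expect_gt(mfr, 0.5)          # in vitro-like range
  expect_lt(mfr, 30)
  b <- detect_bursts_all(spk)
  expect_gt(nrow(b), 100)      # bursting present
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(duration = 10, stdp_freeze_time = 20),
               "stdp_freeze_time")
})
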