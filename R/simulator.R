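#' Simulation configuration
#'
#' Parameters for the spontaneous-activity simulation: Izhikevich neuron
#' dynamics on a 1 ms grid, synaptic delivery after per-link conduction
#' delays, exponential STDP on excitatory weights up to a freeze time, and a
#' noise drive that sustains spontaneous firing.
#'
#' Two noise models are available.  The default (`"kick"`) injects a fixed
#' current of `noise_amp` into one uniformly chosen neuron per millisecond,
#' the convention of the delay/plasticity network model this simulator
#' follows.  `"gaussian"` instead adds independent zero-mean Gaussian current
#' of SD `noise_amp` to every neuron each millisecond.
#'
#' @param duration simulated time in seconds.
#' @param dt integration step in ms (the network integrator runs on a 1 ms
#'   grid with two 0.5 ms half-steps for the membrane potential).
#' @param stdp_A_plus,stdp_A_minus STDP potentiation/depression amplitudes.
#' @param stdp_tau_plus,stdp_tau_minus STDP time constants (ms).
#' @param stdp_freeze_time time (s) after which excitatory weights are frozen.
#' @param w_max upper clip for plastic excitatory weights.
#' @param noise noise model, `"kick"` or `"gaussian"`.
#' @param noise_amp noise amplitude (current units of the Izhikevich model).
#' @param izhikevich_params named list with numeric `(a, b, c, d)` vectors for
#'   `regular_spiking` and `fast_spiking` neurons.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(duration = 900, dt = 1,
                              stdp_A_plus = 0.1, stdp_A_minus = 0.12,
                              stdp_tau_plus = 20, stdp_tau_minus = 20,
                              stdp_freeze_time = 300, w_max = 10,
                              noise = c("kick", "gaussian"), noise_amp = 20,
                              izhikevich_params = list(
                                regular_spiking = c(a = 0.02, b = 0.2, c = -65, d = 8),
                                fast_spiking    = c(a = 0.1,  b = 0.2, c = -65, d = 8))) {
  noise <- match.arg(noise)
  if (dt <= 0) stop("dt must be positive")
  if (dt != 1) stop("the network integrator supports dt = 1 ms only")
  if (stdp_freeze_time > duration)
    stop("stdp_freeze_time cannot exceed the simulation duration")
  if (stdp_A_plus <= 0 || stdp_A_minus <= 0)
    stop("STDP amplitudes must be positive")
  structure(list(duration = duration, dt = dt,
                 stdp_A_plus = stdp_A_plus, stdp_A_minus = stdp_A_minus,
                 stdp_tau_plus = stdp_tau_plus, stdp_tau_minus = stdp_tau_minus,
                 stdp_freeze_time = stdp_freeze_time, w_max = w_max,
                 noise = noise, noise_amp = noise_amp,
                 izhikevich_params = izhikevich_params),
            class = "simulation_config")
}

#' Spike train set
#'
#' Container for a recording: a data frame of spikes `(neuron, time_ms)`
#' sorted by time, the number of neurons, and the recording duration in
#' seconds.  Neuron ids are 1-based.
#'
#' @param spikes data frame with columns `neuron` and `time_ms`.
#' @param n_neurons number of neurons in the recording.
#' @param duration recording duration (s).
#' @param metadata optional provenance list (config, seed).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, n_neurons, duration, metadata = list()) {
  stopifnot(is.data.frame(spikes), all(c("neuron", "time_ms") %in% names(spikes)))
  if (nrow(spikes) > 0) {
    if (any(spikes$time_ms < 0) || any(spikes$time_ms > duration * 1000))
      stop("spike times must lie in [0, duration]")
    if (any(spikes$neuron < 1) || any(spikes$neuron > n_neurons))
      stop("neuron ids must lie in [1, n_neurons]")
    if (is.unsorted(spikes$time_ms))
      spikes <- spikes[order(spikes$time_ms), , drop = FALSE]
  }
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, n_neurons = n_neurons,
                 duration = duration, metadata = metadata),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d spikes, %d neurons, %.1f s (MFR %.2f spikes/s)\n",
              nrow(x$spikes), x$n_neurons, x$duration, mean_firing_rate(x)))
  invisible(x)
}

#' Single Izhikevich neuron update
#'
#' Advances one neuron by one step of the two-half-step Euler scheme: the
#' membrane potential `v` is integrated in two half-steps of `dt/2`, the
#' recovery variable `u` in one full step.  If the incoming state is at or
#' above the 30 mV spike cut-off, the reset (`v <- c`, `u <- u + d`) is
#' applied before integrating, and the returned `spiked` flag reports whether
#' the new state reached the cut-off.
#'
#' @param state numeric `c(v, u)`.
#' @param input_current synaptic plus noise current `I`.
#' @param params numeric `c(a, b, c, d)`.
#' @param dt step in ms.
#' @return list with `state = c(v, u)` and logical `spiked`.
#' @export
step_neuron <- function(state, input_current, params, dt = 1) {
  if (!all(is.finite(state)) || !is.finite(input_current))
    stop("non-finite neuron state or input")
  v <- state[1]; u <- state[2]
  a <- params[1]; b <- params[2]; cc <- params[3]; d <- params[4]
  if (v >= 30) { v <- cc; u <- u + d }
  v <- v + (dt / 2) * (0.04 * v^2 + 5 * v + 140 - u + input_current)
  v <- v + (dt / 2) * (0.04 * v^2 + 5 * v + 140 - u + input_current)
  if (v > 30) v <- 30   # clamp the Euler overshoot at the spike cutoff
  u <- u + dt * a * (b * v - u)
  list(state = c(v = unname(v), u = unname(u)), spiked = v >= 30)
}

#' STDP weight change for one pre/post spike pairing
#'
#' Exponential spike-timing-dependent plasticity: a presynaptic spike arriving
#' `t` ms before the postsynaptic spike (`dt_pre_post = t > 0`) potentiates
#' the synapse by `A_plus * exp(-t / tau_plus)`; the reverse order
#' (`dt_pre_post < 0`) depresses it by `A_minus * exp(-|t| / tau_minus)`.
#' Only excitatory synapses are plastic in the network model.
#'
#' @param dt_pre_post post-minus-pre timing difference (ms).
#' @param A_plus,A_minus amplitudes (defaults 0.1 and 0.12).
#' @param tau_plus,tau_minus time constants in ms (defaults 20).
#' @return The weight change (dimensionless).
#' @export
stdp_update <- function(dt_pre_post, A_plus = 0.1, A_minus = 0.12,
                        tau_plus = 20, tau_minus = 20) {
  stopifnot(is.finite(dt_pre_post))
  if (dt_pre_post > 0) A_plus * exp(-dt_pre_post / tau_plus)
  else if (dt_pre_post < 0) -A_minus * exp(dt_pre_post / tau_minus)
  else 0
}

#' Simulate spontaneous network activity
#'
#' Runs the Izhikevich network defined by a structural network under a
#' [simulation_config()]: delayed synaptic delivery (a spike of neuron `i` at
#' `t` adds `w_ij` to neuron `j`'s current at `t + delay_ij`), STDP on
#' excitatory weights until the freeze time (nearest-neighbour pre/post
#' pairing at arrival times, weights clipped to `[0, w_max]`), and the
#' configured noise drive.  Deterministic given `seed`.
#'
#' @param net a [structural_network()].
#' @param cfg a [simulation_config()].
#' @param seed integer noise seed.
#' @return A [spike_train_set()]; the evolved weight matrices are attached as
#'   attributes `weights_final` and `weights_at_freeze`.
#' @export
run_network <- function(net, cfg = simulation_config(), seed = 1L) {
  stopifnot(inherits(net, "structural_network"),
            inherits(cfg, "simulation_config"))
  n <- net$n_neurons
  exc <- net$neuron_types == "regular_spiking"
  p_rs <- cfg$izhikevich_params$regular_spiking
  p_fs <- cfg$izhikevich_params$fast_spiking
  a <- ifelse(exc, p_rs["a"], p_fs["a"])
  b <- ifelse(exc, p_rs["b"], p_fs["b"])
  cc <- ifelse(exc, p_rs["c"], p_fs["c"])
  d <- ifelse(exc, p_rs["d"], p_fs["d"])
  res <- .simulate_izhikevich(net$adjacency, net$delays, a, b, cc, d, exc,
                              as.integer(round(cfg$duration * 1000)),
                              as.integer(round(cfg$stdp_freeze_time * 1000)),
                              cfg$stdp_A_plus, cfg$stdp_A_minus,
                              cfg$stdp_tau_plus, cfg$stdp_tau_minus, cfg$w_max,
                              ifelse(cfg$noise == "kick", 0L, 1L),
                              cfg$noise_amp, as.integer(seed))
  spikes <- data.frame(neuron = res$spike_id + 1L, time_ms = res$spike_t)
  out <- spike_train_set(spikes, n, cfg$duration,
                         metadata = list(seed = seed, noise = cfg$noise,
                                         noise_amp = cfg$noise_amp,
                                         topology = net$topology))
  attr(out, "weights_final") <- res$weights_final
  attr(out, "weights_at_freeze") <- res$weights_at_freeze
  out
}
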