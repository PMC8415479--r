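#' Mean firing rate
#'
#' Number of spikes per second averaged over the neurons of the recording
#' (spikes / duration / n_neurons).
#'
#' @param spikes a [spike_train_set()].
#' @return Rate in spikes/s per neuron.
#' @export
mean_firing_rate <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (spikes$duration <= 0) stop("duration must be positive")
  nrow(spikes$spikes) / spikes$duration / spikes$n_neurons
}

#' Burst detection on a single spike train (string method)
#'
#' A burst is a maximal run of spikes whose consecutive inter-spike intervals
#' are all at most `max_isi` ms, containing at least `min_spikes` spikes and
#' followed by a quiescent period longer than `quiescence` ms.  A qualifying
#' run at the very end of the recording counts as a burst even without a
#' trailing quiescent period (no censoring of the last event).
#'
#' @param spike_times sorted spike times (ms) of one neuron.
#' @param min_spikes minimum spikes per burst (default 3).
#' @param max_isi maximum intra-burst inter-spike interval (ms).
#' @param quiescence minimum silent gap after a burst (ms).
#' @return Data frame with columns `start_ms`, `end_ms`, `n_spikes` (zero rows
#'   if no burst).
#' @export
detect_bursts <- function(spike_times, min_spikes = 3, max_isi = 100,
                          quiescence = 100) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted ascending")
  n <- length(spike_times)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      n_spikes = integer(0))
  if (n == 0) return(empty)
  isi <- diff(spike_times)
  run_id <- cumsum(c(1, as.integer(isi > max_isi)))
  starts <- ends <- counts <- c()
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) < min_spikes) next
    last <- idx[length(idx)]
    gap_after <- if (last == n) Inf else spike_times[last + 1] - spike_times[last]
    if (gap_after > quiescence) {
      starts <- c(starts, spike_times[idx[1]])
      ends <- c(ends, spike_times[last])
      counts <- c(counts, length(idx))
    }
  }
  if (length(starts) == 0) return(empty)
  data.frame(start_ms = starts, end_ms = ends, n_spikes = as.integer(counts))
}

#' Burst detection over all neurons of a recording
#'
#' @param spikes a [spike_train_set()].
#' @inheritParams detect_bursts
#' @return Data frame with columns `neuron`, `start_ms`, `end_ms`, `n_spikes`.
#' @export
detect_bursts_all <- function(spikes, min_spikes = 3, max_isi = 100,
                              quiescence = 100) {
  stopifnot(inherits(spikes, "spike_train_set"))
  out <- lapply(seq_len(spikes$n_neurons), function(nr) {
    b <- detect_bursts(spikes$spikes$time_ms[spikes$spikes$neuron == nr],
                       min_spikes, max_isi, quiescence)
    if (nrow(b) > 0) cbind(neuron = nr, b) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(neuron = integer(0), start_ms = numeric(0),
                      end_ms = numeric(0), n_spikes = integer(0))
  out
}

#' Mean bursting rate
#'
#' Bursts per minute averaged over the neurons of the recording.
#'
#' @param bursts burst table from [detect_bursts_all()].
#' @param duration recording duration (s).
#' @param n_neurons number of neurons in the recording.
#' @return Rate in bursts/min per neuron.
#' @export
mean_bursting_rate <- function(bursts, duration, n_neurons) {
  if (duration <= 0) stop("duration must be positive")
  nrow(bursts) / (duration / 60) / n_neurons
}

#' Mean burst duration
#'
#' Temporal extent of the bursting events averaged over all detected bursts.
#'
#' @param bursts burst table from [detect_bursts_all()] or [detect_bursts()].
#' @return Duration in ms, or `NA` if no burst was detected.
#' @export
burst_duration <- function(bursts) {
  if (nrow(bursts) == 0) return(NA_real_)
  mean(bursts$end_ms - bursts$start_ms)
}
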