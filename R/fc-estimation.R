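#' Functional connectivity matrix
#'
#' Full signed N x N functional connectivity estimate: entry `[i, j]` is the
#' estimated strength of the directed influence of neuron `i` on neuron `j`
#' (positive = putatively excitatory, negative = putatively inhibitory), with
#' a zero diagonal.
#'
#' @param values signed numeric matrix with zero diagonal and finite entries.
#' @param estimator_tag short name of the estimator that produced the values.
#' @param delay_window maximum causal lag considered (ms).
#' @param bin histogram bin width (ms).
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, estimator_tag = "xcorr",
                                delay_window = 30, bin = 1) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (!all(is.finite(values))) stop("connectivity values must be finite")
  if (any(diag(values) != 0)) stop("the diagonal must be zero")
  structure(list(values = values, estimator_tag = estimator_tag,
                 delay_window = delay_window, bin = bin),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d (%s, lags 1..%d ms, bin %g ms)\n",
              nrow(x$values), ncol(x$values), x$estimator_tag,
              x$delay_window, x$bin))
  invisible(x)
}

#' Estimate a signed functional connectivity matrix from spike trains
#'
#' The default estimator is a signed delayed cross-correlation.  For each
#' ordered pair (i, j) it histograms, over the whole recording, the delays at
#' which j spikes 1..`delay_window` ms after i (lag 0 is excluded: it carries
#' no direction).  The histogram is reduced to one signed scalar by sliding a
#' short window (5 bins, the width of the synaptic correlation hump) across
#' the lags and comparing the windowed counts with the pair's mean count per
#' lag: the dominant deviation gives sign and magnitude — a window peak marks
#' an excitatory connection around its conduction delay, a window trough
#' marks post-synaptic suppression, i.e. inhibition.  The per-pair
#' mean-across-lags baseline absorbs co-modulation (network bursts) that
#' inflates every lag equally, so statistically independent trains score near
#' zero.  Values are normalized by the geometric mean of the two spike counts
#' to be comparable across firing-rate differences.
#'
#' A different estimator (e.g. a spiking-probability edge estimator) can be
#' plugged in via `estimator`: a function `(spikes, delay_window, bin)`
#' returning an N x N signed matrix.
#'
#' @param spikes a [spike_train_set()] (at least 2 neurons, at least 1 spike).
#' @param delay_window maximum causal lag in ms (default 30, covering the
#'   1-20 ms conduction delays plus the correlation hump width).
#' @param bin bin width in ms (default 1).
#' @param estimator optional replacement estimator function.
#' @return A [connectivity_matrix()].  Rows/columns of silent neurons are zero
#'   (with a warning).
#' @export
estimate_cm <- function(spikes, delay_window = 30, bin = 1, estimator = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (spikes$n_neurons < 2) stop("need at least 2 neurons")
  if (nrow(spikes$spikes) == 0) stop("cannot estimate connectivity from an empty spike set")
  if (!is.null(estimator)) {
    vals <- estimator(spikes, delay_window, bin)
    return(connectivity_matrix(vals, "custom", delay_window, bin))
  }
  active <- tabulate(spikes$spikes$neuron, nbins = spikes$n_neurons) > 0
  if (!all(active))
    warning(sum(!active), " silent neuron(s); their rows/columns are zero")
  vals <- .xcorr_cm(as.integer(spikes$spikes$neuron) - 1L,
                    as.numeric(spikes$spikes$time_ms),
                    spikes$n_neurons, as.integer(round(delay_window / bin)), bin)
  connectivity_matrix(vals, "xcorr", delay_window, bin)
}

# Estimator value for a single ordered pair of spike trains; shares the
# summarization of the full-matrix kernel (used by the shuffle method).
.pair_value <- function(src_ms, tgt_ms, delay_window = 30, bin = 1) {
  counts <- .xcorr_pair_counts(as.numeric(src_ms), as.numeric(tgt_ms),
                               as.integer(round(delay_window / bin)), bin)
  .xcorr_summarize(counts, length(src_ms), length(tgt_ms))
}

#' Shuffle the spike timing of a train
#'
#' Returns a surrogate train with the same number of spikes (hence the same
#' firing rate), times redrawn i.i.d. uniformly on `[0, duration]` and sorted;
#' the original inter-spike-interval structure is destroyed.
#'
#' @param spike_times spike times (ms).
#' @param duration recording duration (ms); must cover the spikes.
#' @param seed optional RNG seed.
#' @return Sorted surrogate spike times (ms).
#' @export
shuffle_train <- function(spike_times, duration, seed = NULL) {
  if (length(spike_times) > 0 && duration < max(spike_times))
    stop("duration must cover every spike time")
  if (!is.null(seed)) set.seed(seed)
  sort(runif(length(spike_times), 0, duration))
}
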