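# Shared fixtures and independent oracles.

# Homogeneous Poisson spike train on [0, duration_ms].
poisson_train <- function(rate_hz, duration_ms) {
  n <- rpois(1, rate_hz * duration_ms / 1000)
  sort(runif(n, 0, duration_ms))
}

# Spike set from a list of per-neuron time vectors.
spikes_from_trains <- function(trains, duration_ms) {
  df <- do.call(rbind, lapply(seq_along(trains), function(i)
    if (length(trains[[i]])) data.frame(neuron = i, time_ms = trains[[i]])))
  if (is.null(df)) df <- data.frame(neuron = integer(0), time_ms = numeric(0))
  spike_train_set(df[order(df$time_ms), ], length(trains), duration_ms / 1000)
}

# Random sparse signed matrix with zero diagonal (threshold-method fodder).
random_signed_cm <- function(n, density = 0.6) {
  m <- matrix(0, n, n)
  idx <- which(row(m) != col(m))
  on <- sample(idx, round(length(idx) * density))
  m[on] <- rnorm(length(on), 0, 1) + sample(c(-2, 2), length(on), replace = TRUE) * rbinom(length(on), 1, 0.3)
  m
}

# Literal step-by-step transcription of the double-threshold pseudocode:
# plain loops, no vectorization, independent of the package implementation.
ddt_oracle <- function(vals, n_exc = 1, n_inh = 2, m_exc = 3, m_inh = 3) {
  n <- nrow(vals)
  pos <- vals[vals > 0]; neg <- vals[vals < 0]
  th_e <- if (length(pos) >= 2) mean(pos) + n_exc * sd(pos)
          else if (length(pos) == 1) pos else Inf
  th_i <- if (length(neg) >= 2) mean(neg) - n_inh * sd(neg)
          else if (length(neg) == 1) neg else -Inf
  t1 <- matrix(0, n, n); rm_ <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- vals[i, j]
    if (v > 0 && v > th_e) t1[i, j] <- v
    else if (v < 0 && v < th_i) t1[i, j] <- v
    else if (v != 0) rm_[i, j] <- v
  }
  t2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- rm_[i, j]
    if (v == 0) next
    row_vals <- rm_[i, -j]
    cand <- if (v > 0) row_vals[row_vals > 0] else row_vals[row_vals < 0]
    if (length(cand) < 2) next
    th <- if (v > 0) mean(cand) + m_exc * sd(cand)
          else mean(cand) - m_inh * sd(cand)
    if ((v > 0 && v > th) || (v < 0 && v < th)) t2[i, j] <- v
  }
  list(t1 = t1, rm = rm_, t2 = t2, fm = t1 + t2)
}

support_of <- function(m) which(m != 0)
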