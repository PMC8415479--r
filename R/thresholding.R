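#' Thresholding result
#'
#' Output of a connectivity-matrix pruning method: the functional thresholded
#' matrix `fm` (support is a subset of the input's support, signs preserved)
#' plus, for the double-threshold method, the intermediates `t1cm` (first-pass
#' kept links), `rm` (first-pass rejected links), `tm` (per-element second
#' thresholds, `NA` where undefined) and `t2cm` (second-pass recovered links).
#' `support(t1cm)` and `support(t2cm)` are disjoint and their union is
#' `support(fm)`.
#'
#' @param fm pruned signed matrix.
#' @param method one of `"DDT"`, `"HT"`, `"DT"`, `"SH"`.
#' @param params list of method parameters.
#' @param t1cm,rm,tm,t2cm DDT intermediates (`NULL` for other methods).
#' @return An object of class `threshold_result` with link counts
#'   `n_exc_links` / `n_inh_links`.
#' @export
threshold_result <- function(fm, method, params = list(), t1cm = NULL,
                             rm = NULL, tm = NULL, t2cm = NULL) {
  structure(list(fm = fm, t1cm = t1cm, rm = rm, tm = tm, t2cm = t2cm,
                 method = method, params = params,
                 n_exc_links = sum(fm > 0), n_inh_links = sum(fm < 0)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s: %d links kept (%d exc / %d inh)\n",
              x$method, x$n_exc_links + x$n_inh_links,
              x$n_exc_links, x$n_inh_links))
  invisible(x)
}

.cm_values <- function(cm) {
  if (inherits(cm, "connectivity_matrix")) cm$values
  else if (is.matrix(cm)) cm
  else stop("cm must be a connectivity_matrix or a square matrix")
}

# First (hard) threshold pass: statistics over all non-zero entries of each
# sign, strict inequalities.  Returns kept/rejected splits.
.ht_split <- function(vals, n_exc, n_inh) {
  pos <- vals[vals > 0]
  neg <- vals[vals < 0]
  keep <- matrix(FALSE, nrow(vals), ncol(vals))
  if (length(pos) == 0) {
    warning("no positive entries: excitatory output is empty")
  } else {
    s <- if (length(pos) >= 2) sd(pos) else 0
    keep <- keep | (vals > mean(pos) + n_exc * s)
  }
  if (length(neg) == 0) {
    warning("no negative entries: inhibitory output is empty")
  } else {
    s <- if (length(neg) >= 2) sd(neg) else 0
    keep <- keep | (vals < 0 & vals < mean(neg) - n_inh * s)
  }
  list(keep = keep,
       t1 = ifelse(keep, vals, 0),
       rm = ifelse(!keep & vals != 0, vals, 0))
}

#' Hard threshold (HT)
#'
#' Keeps the excitatory entries exceeding `mean + n_exc * sd` of the positive
#' non-zero entries of the matrix, and the inhibitory entries below
#' `mean - n_inh * sd` of the negative non-zero entries (sample SDs, strict
#' inequalities).  The two signs are thresholded independently.
#'
#' @param cm a [connectivity_matrix()] or signed square matrix.
#' @param n_exc,n_inh threshold multipliers (benchmark defaults 1 and 2).
#' @return A [threshold_result()] with method `"HT"`.
#' @export
hard_threshold <- function(cm, n_exc = 1, n_inh = 2) {
  vals <- .cm_values(cm)
  sp <- .ht_split(vals, n_exc, n_inh)
  threshold_result(sp$t1, "HT", list(n_exc = n_exc, n_inh = n_inh))
}

#' Double threshold (DDT)
#'
#' The adaptive two-pass pruning algorithm:
#'
#' 1. A hard threshold with multipliers (`n_exc`, `n_inh`) splits the matrix
#'    into the strongest links (`t1cm`) and the rejected ones (`rm`).
#' 2. For every non-zero element `rm[i, j]`, a second, element-specific
#'    threshold is computed from the other same-sign non-zero entries of row
#'    `i` of `rm`: `tm[i, j] = mu + m_exc * sd` for positive candidates and
#'    `mu - m_inh * sd` for negative ones (sample SD, the `ij` element always
#'    excluded).  Because most entries of a rejected row are spurious, the row
#'    acts as a pseudo-surrogate null distribution for that element.
#' 3. Rejected elements strictly beyond their own threshold in their sign's
#'    direction are recovered into `t2cm`.
#' 4. The functional matrix is the (disjoint) union `fm = t1cm + t2cm`.
#'
#' Elements whose row offers fewer than `min_candidates` other same-sign
#' non-zero values stay rejected (conservative; the pseudo-surrogate argument
#' needs a minimal sample).  At least 2 candidates are always required so the
#' sample SD exists.
#'
#' @inheritParams hard_threshold
#' @param m_exc,m_inh second-threshold multipliers (benchmark defaults 3).
#' @param min_candidates minimum number of same-sign row entries (excluding
#'   the element itself) required to form its second threshold.
#' @return A [threshold_result()] with method `"DDT"` and all intermediates.
#' @export
ddt <- function(cm, n_exc = 1, n_inh = 2, m_exc = 3, m_inh = 3,
                min_candidates = 2) {
  vals <- .cm_values(cm)
  min_candidates <- max(2, min_candidates)
  sp <- .ht_split(vals, n_exc, n_inh)
  rm_ <- sp$rm
  n <- nrow(vals)
  tm <- matrix(NA_real_, n, n)
  keep2 <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    row <- rm_[i, ]
    for (sign_pos in c(TRUE, FALSE)) {
      idx <- if (sign_pos) which(row > 0) else which(row < 0)
      k <- length(idx)
      if (k - 1 < min_candidates) next
      x <- row[idx]
      mu_ex <- (sum(x) - x) / (k - 1)                 # row mean excluding ij
      var_ex <- (sum(x^2) - x^2 - (k - 1) * mu_ex^2) / (k - 2)
      sd_ex <- sqrt(pmax(var_ex, 0))
      th <- if (sign_pos) mu_ex + m_exc * sd_ex else mu_ex - m_inh * sd_ex
      tm[i, idx] <- th
      keep2[i, idx] <- if (sign_pos) x > th else x < th
    }
  }
  t2 <- ifelse(keep2, rm_, 0)
  threshold_result(sp$t1 + t2, "DDT",
                   list(n_exc = n_exc, n_inh = n_inh, m_exc = m_exc,
                        m_inh = m_inh, min_candidates = min_candidates),
                   t1cm = sp$t1, rm = rm_, tm = tm, t2cm = t2)
}

#' Density-based threshold (DT)
#'
#' Keeps exactly the `m_exc_links` largest positive and the `m_inh_links`
#' most-negative entries of the matrix.  Ties at the cut are broken by keeping
#' the earliest entries in row-major order (deterministic).  To compare DT
#' without bias against the double threshold, set the two counts to the link
#' counts of a DDT result on the same matrix.
#'
#' @inheritParams hard_threshold
#' @param m_exc_links number of excitatory links to keep.
#' @param m_inh_links number of inhibitory links to keep.
#' @return A [threshold_result()] with method `"DT"`.
#' @export
density_threshold <- function(cm, m_exc_links, m_inh_links) {
  vals <- .cm_values(cm)
  n <- nrow(vals)
  keep <- matrix(FALSE, n, n)
  pick <- function(idx, ord_val, m_links, label) {
    if (m_links > length(idx)) {
      warning(sprintf("requested %d %s links but only %d available; clipped",
                      m_links, label, length(idx)))
      m_links <- length(idx)
    }
    if (m_links == 0) return(integer(0))
    r <- ((idx - 1) %% n) + 1
    cc <- ((idx - 1) %/% n) + 1
    idx[order(ord_val, (r - 1) * n + cc)][seq_len(m_links)]
  }
  ip <- which(vals > 0)
  im <- which(vals < 0)
  keep[pick(ip, -vals[ip], m_exc_links, "excitatory")] <- TRUE
  keep[pick(im, vals[im], m_inh_links, "inhibitory")] <- TRUE
  threshold_result(ifelse(keep, vals, 0), "DT",
                   list(m_exc_links = m_exc_links, m_inh_links = m_inh_links))
}

#' Shuffle-based threshold (SH)
#'
#' For every ordered pair (i, j), the timing of the target train j is shuffled
#' `n_shuffles` times (spike count preserved) and the connectivity estimator
#' is re-run on each surrogate, giving a null distribution of strengths for
#' the unconnected case.  The observed value is kept if its one-sided z-score
#' against this null exceeds the `alpha` critical value (upper tail for
#' positive values, lower tail for negative).  Surrogates of each target train
#' are generated once and re-used across sources.  Accurate but costly:
#' the run time scales with `n_neurons^2 * n_shuffles`.
#'
#' @param spikes the [spike_train_set()] the matrix was estimated from.
#' @inheritParams hard_threshold
#' @param n_shuffles surrogates per pair (at least 20 for a stable z-test).
#' @param alpha one-sided significance level in (0, 0.5) (default 0.01).
#' @param seed RNG seed for the surrogate draws.
#' @return A [threshold_result()] with method `"SH"`.
#' @export
shuffle_threshold <- function(spikes, cm, n_shuffles = 100, alpha = 0.01,
                              seed = 1L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (n_shuffles < 20) stop("n_shuffles must be at least 20")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  vals <- .cm_values(cm)
  n <- spikes$n_neurons
  stopifnot(nrow(vals) == n)
  dur_ms <- spikes$duration * 1000
  L <- if (inherits(cm, "connectivity_matrix")) cm$delay_window else 30
  bin <- if (inherits(cm, "connectivity_matrix")) cm$bin else 1
  trains <- split(spikes$spikes$time_ms, factor(spikes$spikes$neuron, levels = seq_len(n)))
  set.seed(seed)
  surrogates <- lapply(trains, function(tt)
    lapply(seq_len(n_shuffles), function(k) shuffle_train(tt, dur_ms)))
  zc <- qnorm(1 - alpha)
  keep <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    if (length(trains[[j]]) == 0) next
    for (i in seq_len(n)) {
      if (i == j || vals[i, j] == 0 || length(trains[[i]]) == 0) next
      null_vals <- vapply(surrogates[[j]], function(sv)
        .pair_value(trains[[i]], sv, L, bin), numeric(1))
      mu0 <- mean(null_vals)
      sd0 <- sd(null_vals)
      z <- if (sd0 > 0) (vals[i, j] - mu0) / sd0
           else sign(vals[i, j] - mu0) * Inf
      if (is.nan(z)) z <- 0
      keep[i, j] <- if (vals[i, j] > 0) z > zc else z < -zc
    }
  }
  threshold_result(ifelse(keep, vals, 0), "SH",
                   list(n_shuffles = n_shuffles, alpha = alpha, seed = seed))
}
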