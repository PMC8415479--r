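#' Three-class confusion matrix against the structural ground truth
#'
#' Each ordered neuron pair (diagonal excluded) is classified by the sign of
#' its entry — excitatory (> 0), no connection (0), inhibitory (< 0) — in both
#' the thresholded functional matrix (output class) and the structural matrix
#' (target class), and the 3 x 3 counts are tabulated.  Entries sum to
#' `N^2 - N`.
#'
#' @param fm a [threshold_result()] or pruned signed matrix.
#' @param truth a [structural_network()] or signed matrix of the same size.
#' @return A 3 x 3 integer matrix, rows = output class, columns = target
#'   class, classes `Exc`, `NoConn`, `Inh`.
#' @export
confusion_3class <- function(fm, truth) {
  f <- .adj_of(fm)
  t_ <- .adj_of(truth)
  if (!all(dim(f) == dim(t_))) stop("dimension mismatch between output and target")
  off <- !diag(nrow(f))
  cls <- function(v) factor(ifelse(v > 0, "Exc", ifelse(v < 0, "Inh", "NoConn")),
                            levels = c("Exc", "NoConn", "Inh"))
  tab <- table(output = cls(f[off]), target = cls(t_[off]))
  unclass(as.matrix(tab))
}

#' Classification accuracy
#'
#' Fraction of correctly classified ordered pairs: the diagonal of the
#' three-class confusion matrix (true excitatory + true inhibitory + true
#' negative) over all classified pairs.
#'
#' @param confusion 3 x 3 confusion matrix from [confusion_3class()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(confusion)) / total
}

#' Evaluate a thresholding result against the structural ground truth
#'
#' @param result a [threshold_result()].
#' @param net the generating [structural_network()].
#' @param topology compute topology metrics of the functional graph as well
#'   (slower; involves the SWI reference ensemble).
#' @param seed optional seed for the SWI ensemble.
#' @return List of class `evaluation_report`: `confusion`, `accuracy`,
#'   `n_links_detected`, `ei_ratio_detected`, `method`, and optionally
#'   `topology`.
#' @export
evaluate_threshold <- function(result, net, topology = FALSE, seed = NULL) {
  stopifnot(inherits(result, "threshold_result"),
            inherits(net, "structural_network"))
  conf <- confusion_3class(result, net)
  nl <- result$n_exc_links + result$n_inh_links
  rep_ <- list(confusion = conf, accuracy = accuracy(conf),
               n_links_detected = nl,
               ei_ratio_detected = if (nl > 0) result$n_exc_links / nl else NA_real_,
               method = result$method, network_id = net$seed)
  if (topology) rep_$topology <- topology_metrics(result, seed = seed)
  structure(rep_, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: accuracy %.4f, %d links (E/I ratio %.3f)\n",
              x$method, x$accuracy, x$n_links_detected, x$ei_ratio_detected))
  invisible(x)
}

#' Run the in-silico benchmark
#'
#' Full pipeline for each (realization, degree, method) cell: generate a
#' structural network, simulate spontaneous activity, estimate the functional
#' connectivity matrix, threshold it, and score the result against the ground
#' truth.  The density-based method is calibrated per realization to the link
#' counts detected by the double threshold on the same matrix, as in the
#' reference comparison protocol.  Failures in a cell are recorded and the
#' harness continues.
#'
#' @param topology `"RND"`, `"SW"`, `"SF"` or `"MODULAR"`.
#' @param n_realizations networks per degree value.
#' @param k_values vector of degree parameters (out-degree for RND/SW,
#'   attachment minimum for SF).
#' @param methods subset of `c("DDT", "HT", "DT", "SH")`.
#' @param cfg a [simulation_config()].
#' @param delay_window,bin estimator parameters passed to [estimate_cm()].
#' @param ddt_params list of DDT parameters (`n_exc`, `n_inh`, `m_exc`,
#'   `m_inh`).
#' @param seed base seed; realization r at degree k uses derived seeds.
#' @param sh_shuffles surrogates per pair if `"SH"` is requested.
#' @return Data frame with one row per cell: topology, k, realization, method,
#'   accuracy, link counts, E/I ratio, plus an `error` column (NA on success).
#' @export
run_benchmark <- function(topology = "RND", n_realizations = 1,
                          k_values = 40, methods = c("DDT", "HT", "DT"),
                          cfg = simulation_config(),
                          delay_window = 30, bin = 1,
                          ddt_params = list(n_exc = 1, n_inh = 2,
                                            m_exc = 3, m_inh = 3),
                          seed = 1L, sh_shuffles = 30) {
  methods <- match.arg(methods, c("DDT", "HT", "DT", "SH"), several.ok = TRUE)
  rows <- list()
  cell <- 0L
  for (k in k_values) {
    for (r in seq_len(n_realizations)) {
      cell <- cell + 1L
      cell_seed <- as.integer((seed * 1000L + cell) %% .Machine$integer.max)
      out <- tryCatch({
        net <- switch(topology,
          RND = generate_random(out_degree = k, seed = cell_seed),
          SW = generate_small_world(out_degree = k, seed = cell_seed),
          SF = generate_scale_free(min_links_per_neuron = k, seed = cell_seed),
          MODULAR = generate_modular(seed = cell_seed),
          stop("unknown topology ", topology))
        spk <- run_network(net, cfg, seed = cell_seed + 1L)
        cm <- estimate_cm(spk, delay_window, bin)
        res_ddt <- ddt(cm, ddt_params$n_exc, ddt_params$n_inh,
                       ddt_params$m_exc, ddt_params$m_inh)
        lapply(methods, function(m) {
          res <- switch(m,
            DDT = res_ddt,
            HT = hard_threshold(cm, ddt_params$n_exc, ddt_params$n_inh),
            DT = density_threshold(cm, res_ddt$n_exc_links, res_ddt$n_inh_links),
            SH = shuffle_threshold(spk, cm, n_shuffles = sh_shuffles,
                                   seed = cell_seed + 2L))
          ev <- evaluate_threshold(res, net)
          data.frame(topology = topology, k = k, realization = r,
                     seed = cell_seed, method = m, accuracy = ev$accuracy,
                     n_links = ev$n_links_detected,
                     n_exc_links = res$n_exc_links,
                     n_inh_links = res$n_inh_links,
                     ei_ratio = ev$ei_ratio_detected,
                     error = NA_character_, stringsAsFactors = FALSE)
        })
      }, error = function(e) {
        list(data.frame(topology = topology, k = k, realization = r,
                        seed = cell_seed, method = NA_character_,
                        accuracy = NA_real_, n_links = NA_integer_,
                        n_exc_links = NA_integer_, n_inh_links = NA_integer_,
                        ei_ratio = NA_real_, error = conditionMessage(e),
                        stringsAsFactors = FALSE))
      })
      rows <- c(rows, out)
    }
  }
  do.call(rbind, rows)
}
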