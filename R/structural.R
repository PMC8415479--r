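#' Structural ground-truth networks
#'
#' A `structural_network` holds the ground truth used throughout the benchmark:
#' a signed, directed synaptic weight matrix (entry `[i, j]` is the connection
#' from source neuron `i` to target neuron `j`), integer conduction delays in
#' milliseconds on the same support, and per-neuron type labels.  Excitatory
#' neurons are regular-spiking and carry positive outgoing weights; inhibitory
#' neurons are fast-spiking, carry negative outgoing weights, and project only
#' onto excitatory neurons.  Neuron ids are 1-based: neurons `1..n_excitatory`
#' are excitatory, the rest inhibitory.
#'
#' @param adjacency signed weight matrix (zero diagonal).
#' @param delays integer delay matrix (ms), defined on the adjacency support.
#' @param n_excitatory number of excitatory neurons (the first rows/columns).
#' @param topology tag: one of `"RND"`, `"SW"`, `"SF"`, `"MODULAR"`.
#' @param seed the RNG seed the generator was called with (provenance).
#'
#' @return An object of class `structural_network`: a list with elements
#'   `adjacency`, `delays`, `n_neurons`, `n_excitatory`, `neuron_types`
#'   (`"regular_spiking"`/`"fast_spiking"`), `topology` and `seed`.
#' @export
structural_network <- function(adjacency, delays, n_excitatory,
                               topology = c("RND", "SW", "SF", "MODULAR"),
                               seed = NA_integer_) {
  topology <- match.arg(topology)
  n <- nrow(adjacency)
  stopifnot(ncol(adjacency) == n, all(dim(delays) == dim(adjacency)),
            n_excitatory >= 0, n_excitatory <= n)
  if (any(diag(adjacency) != 0)) stop("self-connections are not allowed")
  exc <- seq_len(n) <= n_excitatory
  if (n_excitatory > 0 && any(adjacency[exc, , drop = FALSE] < 0))
    stop("excitatory neurons must have non-negative outgoing weights")
  if (n_excitatory < n) {
    inh_rows <- adjacency[!exc, , drop = FALSE]
    if (any(inh_rows > 0))
      stop("inhibitory neurons must have non-positive outgoing weights")
    if (n_excitatory < n && any(inh_rows[, !exc, drop = FALSE] != 0))
      stop("inhibitory neurons may project only onto excitatory neurons")
  }
  if (any(delays[adjacency != 0] < 1))
    stop("every link must have a delay of at least 1 ms")
  structure(list(
    adjacency = adjacency, delays = delays, n_neurons = n,
    n_excitatory = n_excitatory,
    neuron_types = ifelse(exc, "regular_spiking", "fast_spiking"),
    topology = topology, seed = seed
  ), class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  cat(sprintf("<structural_network> %s: %d neurons (%d exc / %d inh), %d links\n",
              x$topology, x$n_neurons, x$n_excitatory,
              x$n_neurons - x$n_excitatory, sum(x$adjacency != 0)))
  invisible(x)
}

#' @export
n_links <- function(net) UseMethod("n_links")

#' @export
n_links.structural_network <- function(net) sum(net$adjacency != 0)

# Draw synaptic weights and conduction delays onto a binary support matrix.
# Initial weights: excitatory ~ N(7, 1) floored at 0.1 (signs must not flip),
# inhibitory ~ N(-7, 1) capped at -0.1.  Excitatory delays are uniform on the
# integers 1..20 ms per link; inhibitory delays are fixed at 1 ms.
.dress_support <- function(support, n_excitatory,
                           w_exc_mean = 7, w_inh_mean = -7, w_sd = 1,
                           delay_range = c(1L, 20L)) {
  n <- nrow(support)
  exc <- seq_len(n) <= n_excitatory
  w <- matrix(0, n, n)
  dl <- matrix(0L, n, n)
  idx_e <- which(support & exc, arr.ind = FALSE)
  idx_i <- which(support & !exc, arr.ind = FALSE)
  w[idx_e] <- pmax(0.1, rnorm(length(idx_e), w_exc_mean, w_sd))
  w[idx_i] <- pmin(-0.1, rnorm(length(idx_i), w_inh_mean, w_sd))
  dl[idx_e] <- sample(seq(delay_range[1], delay_range[2]),
                      length(idx_e), replace = TRUE)
  dl[idx_i] <- 1L
  list(weights = w, delays = dl)
}

.check_ei_args <- function(n_neurons, n_excitatory) {
  if (n_excitatory > n_neurons)
    stop("n_excitatory cannot exceed n_neurons")
  if (n_excitatory < 1) stop("at least one excitatory neuron is required")
}

#' Generate a random (RND) structural network
#'
#' Every neuron is connected to `out_degree` distinct targets chosen uniformly
#' at random (no autapses).  Excitatory neurons may target any other neuron;
#' inhibitory neurons target excitatory neurons only.  At the default
#' parameters (500 neurons, 400 excitatory, out-degree 40) the network has
#' exactly 20,000 links, 16,000 excitatory-sourced and 4,000
#' inhibitory-sourced, and the in-degree distribution is binomial
#' (Poisson-like).
#'
#' @param n_neurons total number of neurons.
#' @param n_excitatory number of excitatory neurons (the first ids).
#' @param out_degree number of outgoing links per neuron.
#' @param seed integer RNG seed.
#' @return A [structural_network()].
#' @export
generate_random <- function(n_neurons = 500, n_excitatory = 400,
                            out_degree = 40, seed = 1L) {
  .check_ei_args(n_neurons, n_excitatory)
  if (out_degree >= n_neurons)
    stop("out_degree must be smaller than n_neurons")
  if (out_degree < 0) stop("out_degree must be non-negative")
  n_inh <- n_neurons - n_excitatory
  if (n_inh > 0 && out_degree > n_excitatory)
    stop("inhibitory out-degree cannot exceed the number of excitatory neurons")
  set.seed(seed)
  support <- matrix(FALSE, n_neurons, n_neurons)
  if (out_degree > 0) {
    for (i in seq_len(n_neurons)) {
      pool <- if (i <= n_excitatory) setdiff(seq_len(n_neurons), i)
              else seq_len(n_excitatory)
      support[i, sample(pool, out_degree)] <- TRUE
    }
  }
  dw <- .dress_support(support, n_excitatory)
  structural_network(dw$weights, dw$delays, n_excitatory, "RND", seed)
}

# Directed ring-lattice target list: each of n nodes connects to its k/2
# nearest neighbours on each side.
.ring_lattice_targets <- function(n, k) {
  half <- k %/% 2
  lapply(seq_len(n), function(i) {
    offs <- c(seq_len(half), -seq_len(half))
    ((i - 1 + offs) %% n) + 1
  })
}

#' Generate a small-world (SW) structural network
#'
#' Watts-Strogatz-style construction on the excitatory population: a directed
#' ring lattice with `out_degree/2` neighbours per side is rewired with
#' probability `rewiring_p` per link.  A small number of excitatory links is
#' then "translated": the target is moved from an excitatory to an inhibitory
#' neuron — the minimum drive that recruits the whole inhibitory population,
#' `translated_per_inhibitory` links per interneuron on average with every
#' interneuron guaranteed at least one input.  (Keeping this number minimal
#' preserves the lattice clustering that carries the small-world signature.)
#' The inhibitory-to-excitatory block is connected at random.  The total link
#' count equals `n_neurons * out_degree` exactly.
#'
#' @inheritParams generate_random
#' @param rewiring_p per-link rewiring probability in `[0, 1]`
#'   (the benchmark value is 0.3).
#' @param translated_per_inhibitory mean number of ring-lattice links
#'   re-targeted onto each inhibitory neuron.
#' @return A [structural_network()].
#' @export
generate_small_world <- function(n_neurons = 500, n_excitatory = 400,
                                 out_degree = 40, rewiring_p = 0.3,
                                 translated_per_inhibitory = 4, seed = 1L) {
  .check_ei_args(n_neurons, n_excitatory)
  if (rewiring_p < 0 || rewiring_p > 1)
    stop("rewiring_p must lie in [0, 1]")
  if (out_degree %% 2 != 0)
    stop("out_degree must be even (ring lattice with out_degree/2 per side)")
  if (out_degree >= n_excitatory)
    stop("out_degree must be smaller than the excitatory population")
  n_inh <- n_neurons - n_excitatory
  set.seed(seed)

  targets <- .ring_lattice_targets(n_excitatory, out_degree)
  # Watts-Strogatz rewiring within the excitatory block
  if (rewiring_p > 0) {
    for (i in seq_len(n_excitatory)) {
      tg <- targets[[i]]
      for (s in seq_along(tg)) {
        if (runif(1) < rewiring_p) {
          free <- setdiff(seq_len(n_excitatory), c(i, tg))
          if (length(free) > 0) tg[s] <- free[sample.int(length(free), 1)]
        }
      }
      targets[[i]] <- tg
    }
  }

  support <- matrix(FALSE, n_neurons, n_neurons)
  if (n_inh > 0) {
    # translate the minimum drive onto the inhibitory population
    src_of_link <- rep(seq_len(n_excitatory), each = out_degree)
    n_ee_links <- length(src_of_link)
    n_translate <- translated_per_inhibitory * n_inh
    if (n_translate > n_ee_links)
      stop("not enough excitatory links to cover the inhibitory population")
    sel <- sample(n_ee_links, n_translate)
    inh_ids <- n_excitatory + seq_len(n_inh)
    new_tgt <- c(sample(inh_ids),                       # coverage of every inh
                 sample(inh_ids, n_translate - n_inh, replace = TRUE))
    # resolve duplicate (source, target) pairs per source, keeping coverage
    for (i in unique(src_of_link[sel])) {
      slots <- which(src_of_link[sel] == i)
      while (anyDuplicated(new_tgt[slots])) {
        dup <- slots[duplicated(new_tgt[slots])]
        avail <- setdiff(inh_ids, new_tgt[slots])
        new_tgt[dup] <- sample(avail, length(dup))
      }
    }
    tgt_flat <- unlist(targets)
    tgt_flat[sel] <- new_tgt
    support[cbind(rep(seq_len(n_excitatory), each = out_degree), tgt_flat)] <- TRUE
    # randomly connected inhibitory -> excitatory block
    for (i in inh_ids) support[i, sample(seq_len(n_excitatory), out_degree)] <- TRUE
  } else {
    support[cbind(rep(seq_len(n_excitatory), each = out_degree),
                  unlist(targets))] <- TRUE
  }
  dw <- .dress_support(support, n_excitatory)
  structural_network(dw$weights, dw$delays, n_excitatory, "SW", seed)
}

# Degree sequence from shifted-linear preferential attachment, adjusted to an
# exact sum.  Growth starts from a clique of m+1 nodes; each new node brings m
# links attached with probability proportional to (degree - m/2).  The
# negative initial attractiveness steepens the asymptotic degree exponent
# from the textbook value 3 to 2.5, the middle of the range observed for
# neuronal networks.  Extra degree needed to hit the exact budget is added
# with the same kernel; each degree is capped at the number of available
# targets.
.pa_degree_sequence <- function(n, m, target_sum, max_degree) {
  if (m >= n) stop("min_links_per_neuron too large for this block")
  deg <- rep(m, m + 1)
  if (n > m + 1) {
    for (t in seq(m + 2, n)) {
      w <- pmax(deg - m / 2, 1e-9)
      picked <- sample.int(length(deg), m, prob = w)
      deg[picked] <- deg[picked] + 1
      deg <- c(deg, m)
    }
  }
  deg <- pmin(deg, max_degree)
  while (sum(deg) < target_sum) {
    room <- deg < max_degree
    if (!any(room)) stop("link budget exceeds available targets")
    w <- pmax(deg[room] - m / 2, 1e-9)
    k <- which(room)[sample.int(sum(room), 1, prob = w)]
    deg[k] <- deg[k] + 1
  }
  while (sum(deg) > target_sum) {
    k <- sample(which(deg > 1), 1)
    deg[k] <- deg[k] - 1
  }
  as.integer(deg)
}

#' Generate a scale-free (SF) structural network
#'
#' Barabasi-Albert-style construction, block by block.  Shifted-linear
#' preferential-attachment degree sequences (attachment probability
#' proportional to degree minus half the attachment minimum, which steepens
#' the degree exponent to about 2.5, mid-range for neuronal recordings) are
#' drawn for the excitatory-to-excitatory,
#' excitatory-to-inhibitory and inhibitory-to-excitatory blocks (attachment
#' parameter `min_links_per_neuron` for the main block, scaled by target
#' availability for the others), then each row's targets are assigned uniformly
#' at random within the block — the row shuffle that removes most bidirectional
#' pairs while preserving each neuron's out-degree.  The result has a
#' heavy-tailed (power-law-like) out-degree distribution, an approximately
#' normal in-degree distribution, and exactly `2 * min_links_per_neuron *
#' n_neurons` links (20,000 at the defaults).
#'
#' @inheritParams generate_random
#' @param min_links_per_neuron minimum number of attachment links per neuron
#'   (the Barabasi-Albert `m`); mean out-degree is twice this value.
#' @return A [structural_network()].
#' @export
generate_scale_free <- function(n_neurons = 500, n_excitatory = 400,
                                min_links_per_neuron = 20, seed = 1L) {
  .check_ei_args(n_neurons, n_excitatory)
  m <- min_links_per_neuron
  if (m < 1) stop("min_links_per_neuron must be at least 1")
  n_inh <- n_neurons - n_excitatory
  set.seed(seed)
  kbar <- 2 * m
  exc_budget <- n_excitatory * kbar
  b_ee <- if (n_inh > 0) round(exc_budget * (n_excitatory - 1) /
                               (n_neurons - 1)) else exc_budget
  b_ei <- exc_budget - b_ee
  b_ie <- n_inh * kbar

  d_ee <- .pa_degree_sequence(n_excitatory, m, b_ee, n_excitatory - 1)
  support <- matrix(FALSE, n_neurons, n_neurons)
  for (i in seq_len(n_excitatory)) {
    pool <- setdiff(seq_len(n_excitatory), i)
    if (d_ee[i] > 0) support[i, sample(pool, d_ee[i])] <- TRUE
  }
  if (n_inh > 0) {
    m_ei <- max(1L, round(m * n_inh / (n_neurons - 1)))
    d_ei <- .pa_degree_sequence(n_excitatory, min(m_ei, n_inh - 1L), b_ei, n_inh)
    inh_ids <- n_excitatory + seq_len(n_inh)
    for (i in seq_len(n_excitatory))
      if (d_ei[i] > 0) support[i, sample(inh_ids, d_ei[i])] <- TRUE
    m_ie <- min(m, n_inh - 1L)
    d_ie <- .pa_degree_sequence(n_inh, m_ie, b_ie, n_excitatory)
    for (i in seq_len(n_inh))
      if (d_ie[i] > 0)
        support[inh_ids[i], sample(seq_len(n_excitatory), d_ie[i])] <- TRUE
  }
  dw <- .dress_support(support, n_excitatory)
  structural_network(dw$weights, dw$delays, n_excitatory, "SF", seed)
}

#' Generate a modular structural network
#'
#' Neurons are arranged in weakly coupled modules (by default two excitatory
#' modules of 175 neurons and one inhibitory module of 100, honouring the 80/20
#' excitatory/inhibitory split).  Pairs inside a module connect with
#' probability `intra_p`, all other allowed pairs with `inter_p`; neurons
#' outside every module are sparsely connected through `inter_p`.  Modules are
#' laid out consecutively: excitatory modules from neuron 1, and any module
#' that does not fit in the excitatory range is placed on the inhibitory
#' range.  Inhibitory sources only target excitatory neurons regardless of
#' module membership.
#'
#' @inheritParams generate_random
#' @param module_sizes integer vector of module sizes.
#' @param intra_p within-module connection probability.
#' @param inter_p between-module / out-of-module connection probability
#'   (must not exceed `intra_p`).
#' @return A [structural_network()] with a `modules` attribute giving the
#'   per-neuron module index (`0` = outside every module).
#' @export
generate_modular <- function(n_neurons = 500, module_sizes = c(175, 175, 100),
                             intra_p = 0.15, inter_p = 0.01, seed = 1L) {
  if (any(c(intra_p, inter_p) < 0) || any(c(intra_p, inter_p) > 1))
    stop("connection probabilities must lie in [0, 1]")
  if (intra_p < inter_p)
    stop("modules must be weakly coupled: intra_p must be >= inter_p")
  n_excitatory <- round(0.8 * n_neurons)
  n_inh <- n_neurons - n_excitatory
  if (sum(module_sizes) > n_neurons)
    stop("module sizes exceed the number of neurons")
  set.seed(seed)
  module <- integer(n_neurons)
  cur_exc <- 1L; cur_inh <- n_excitatory + 1L
  for (mi in seq_along(module_sizes)) {
    s <- module_sizes[mi]
    if (cur_exc + s - 1L <= n_excitatory) {
      module[cur_exc:(cur_exc + s - 1L)] <- mi
      cur_exc <- cur_exc + s
    } else if (cur_inh + s - 1L <= n_neurons) {
      module[cur_inh:(cur_inh + s - 1L)] <- mi
      cur_inh <- cur_inh + s
    } else stop("module of size ", s, " does not fit in either population")
  }
  same_mod <- outer(module, module, function(a, b) a == b & a > 0)
  p <- matrix(inter_p, n_neurons, n_neurons)
  p[same_mod] <- intra_p
  diag(p) <- 0
  exc <- seq_len(n_neurons) <= n_excitatory
  if (n_inh > 0) p[!exc, !exc] <- 0          # no inhibitory -> inhibitory links
  support <- matrix(runif(n_neurons^2), n_neurons, n_neurons) < p
  dw <- .dress_support(support, n_excitatory)
  net <- structural_network(dw$weights, dw$delays, n_excitatory, "MODULAR", seed)
  attr(net, "modules") <- module
  net
}
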