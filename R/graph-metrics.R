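# Topological characterization of structural and functional networks.
# Directed signed matrices are binarized and symmetrized (an undirected edge
# wherever either direction is present) before clustering / path-length
# computations: the pair-count denominator of the clustering coefficient is
# undirected.

.as_undirected_graph <- function(adjacency) {
  a <- (adjacency != 0) | (t(adjacency) != 0)
  diag(a) <- FALSE
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

.adj_of <- function(x) {
  if (inherits(x, "structural_network")) x$adjacency
  else if (inherits(x, "threshold_result")) x$fm
  else if (inherits(x, "connectivity_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a matrix, structural_network, threshold_result or connectivity_matrix")
}

#' Clustering coefficient
#'
#' Per-node clustering coefficient of the binarized, symmetrized graph:
#' links among the neighbours of node i divided by `k_i (k_i - 1) / 2`.
#' Nodes with fewer than 2 neighbours contribute 0.
#'
#' @param x adjacency matrix (or a network/threshold object).
#' @return List with `per_node` (numeric vector) and `mean`.
#' @export
clustering_coefficient <- function(x) {
  adjacency <- .adj_of(x)
  if (nrow(adjacency) < 3) stop("need at least 3 nodes")
  g <- .as_undirected_graph(adjacency)
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  ci[is.na(ci)] <- 0
  list(per_node = ci, mean = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over all ordered reachable pairs of the
#' binarized, symmetrized graph.  Unreachable pairs are excluded and their
#' fraction reported.
#'
#' @param x adjacency matrix (or a network/threshold object).
#' @return List with `mean` (hops), `unreachable_fraction`.
#' @export
path_length <- function(x) {
  adjacency <- .adj_of(x)
  n <- nrow(adjacency)
  if (n < 2) stop("need at least 2 nodes")
  g <- .as_undirected_graph(adjacency)
  if (igraph::ecount(g) == 0) stop("path length undefined: the graph has no edges")
  d <- igraph::distances(g)
  off <- d[upper.tri(d)]
  unreachable <- mean(!is.finite(off))
  if (all(!is.finite(off))) stop("path length undefined: fully disconnected graph")
  list(mean = mean(off[is.finite(off)]), unreachable_fraction = unreachable)
}

#' Small-world index (SWI)
#'
#' `SWI = (C_g / C_rand) / (L_g / L_rand)`, where the clustering coefficient
#' and path length of the graph are normalized by their means over an ensemble
#' of random reference graphs with the same number of nodes and undirected
#' edges (Erdos-Renyi G(n, m)).  SWI > 1 indicates small-world organization.
#'
#' @param x adjacency matrix (or a network/threshold object).
#' @param n_reference number of reference graphs (default 20).
#' @param seed optional RNG seed for the reference ensemble.
#' @return List with `swi`, `c_g`, `l_g`, `c_rand`, `l_rand`.
#' @export
small_world_index <- function(x, n_reference = 20, seed = NULL) {
  adjacency <- .adj_of(x)
  if (!is.null(seed)) set.seed(seed)
  g <- .as_undirected_graph(adjacency)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  c_g <- clustering_coefficient(adjacency)$mean
  l_g <- path_length(adjacency)$mean
  cs <- ls_ <- numeric(n_reference)
  for (r in seq_len(n_reference)) {
    gr <- igraph::sample_gnm(n, m)
    ci <- igraph::transitivity(gr, type = "localundirected", isolates = "zero")
    ci[is.na(ci)] <- 0
    cs[r] <- mean(ci)
    ls_[r] <- igraph::mean_distance(gr, directed = FALSE)
  }
  c_rand <- mean(cs); l_rand <- mean(ls_)
  list(swi = (c_g / c_rand) / (l_g / l_rand),
       c_g = c_g, l_g = l_g, c_rand = c_rand, l_rand = l_rand)
}

# Least-squares power-law fit on tabulated (degree, relative frequency) pairs:
# linear regression of log10(frequency) on log10(degree) over positive bins.
.fit_powerlaw_xy <- function(k, freq) {
  ok <- k > 0 & freq > 0
  if (sum(ok) < 3) stop("too few positive bins for a power-law fit")
  fit <- stats::lm(log10(freq[ok]) ~ log10(k[ok]))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log10(freq[ok]) - mean(log10(freq[ok])))^2)
  list(family = "powerlaw", slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Fit a degree distribution
#'
#' Gaussian family: least-squares fit of a normal density to the empirical
#' degree distribution binned in unit-width integer bins, returning the fitted
#' mean, SD and the coefficient of determination of the fit.  Power-law
#' family: linear fit of log10 relative frequency versus log10 degree over the
#' non-empty bins, returning the slope and its R^2.  With
#' `cumulative = TRUE` the complementary cumulative distribution is fitted
#' instead of the density.
#'
#' @param degrees integer vector of node degrees (at least 10 nodes).
#' @param family `"gaussian"` or `"powerlaw"`.
#' @param cumulative fit the complementary cumulative distribution instead of
#'   the binned density.
#' @return List with `family`, fit parameters (`mean`/`sd` or
#'   `slope`/`intercept`) and `r_squared`.
#' @export
fit_degree_distribution <- function(degrees, family = c("gaussian", "powerlaw"),
                                    cumulative = FALSE) {
  family <- match.arg(family)
  if (length(degrees) < 10) stop("need at least 10 nodes")
  if (family == "gaussian") {
    if (sd(degrees) == 0)
      stop("all degrees identical: gaussian fit undefined (sd = 0)")
    ks <- seq(min(degrees), max(degrees))
    if (cumulative) {
      y <- vapply(ks, function(k) mean(degrees >= k), numeric(1))
      model <- function(k, mu, sigma) stats::pnorm(k, mu, sigma, lower.tail = FALSE)
    } else {
      y <- vapply(ks, function(k) mean(degrees == k), numeric(1))
      model <- function(k, mu, sigma) dnorm(k, mu, sigma)
    }
    df <- data.frame(k = ks, y = y)
    fit <- minpack.lm::nlsLM(y ~ model(k, mu, sigma), data = df,
                             start = list(mu = mean(degrees), sigma = sd(degrees)),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    pred <- stats::predict(fit)
    r2 <- 1 - sum((df$y - pred)^2) / sum((df$y - mean(df$y))^2)
    list(family = "gaussian", mean = unname(coef(fit)["mu"]),
         sd = abs(unname(coef(fit)["sigma"])), r_squared = r2)
  } else {
    ks <- sort(unique(degrees[degrees > 0]))
    y <- if (cumulative) vapply(ks, function(k) mean(degrees >= k), numeric(1))
         else vapply(ks, function(k) mean(degrees == k), numeric(1))
    .fit_powerlaw_xy(ks, y)
  }
}

#' Detect hub nodes
#'
#' Hubs are nodes whose degree is at least one standard deviation above the
#' network's mean degree.  A regular graph (zero degree spread) has no hubs.
#'
#' @param degrees vector of node degrees (at least 2 nodes).
#' @return Integer vector of hub node indices.
#' @export
detect_hubs <- function(degrees) {
  if (length(degrees) < 2) stop("need at least 2 nodes")
  s <- sd(degrees)
  if (s == 0) return(integer(0))
  which(degrees >= mean(degrees) + s)
}

#' Total degrees of a network
#'
#' In-degree plus out-degree of the directed link support.
#'
#' @param x adjacency matrix (or a network/threshold object).
#' @return Integer vector of per-node total degrees.
#' @export
total_degrees <- function(x) {
  a <- .adj_of(x) != 0
  rowSums(a) + colSums(a)
}

#' Topology metrics report
#'
#' Convenience bundle: link count, small-world index and its components,
#' hub list (on total degree), and excitatory link fraction.
#'
#' @param x adjacency matrix (or a network/threshold object).
#' @param n_reference reference graphs for the SWI ensemble.
#' @param seed optional RNG seed for the SWI ensemble.
#' @return List with `n_links`, `swi`, `c_g`, `l_g`, `c_rand`, `l_rand`,
#'   `hubs`, `ei_ratio`.
#' @export
topology_metrics <- function(x, n_reference = 20, seed = NULL) {
  a <- .adj_of(x)
  swi <- small_world_index(a, n_reference, seed)
  nl <- sum(a != 0)
  c(list(n_links = nl), swi[c("swi", "c_g", "l_g", "c_rand", "l_rand")],
    list(hubs = detect_hubs(total_degrees(a)),
         ei_ratio = if (nl > 0) sum(a > 0) / nl else NA_real_))
}
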