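test_that("random generator hits the exact link budget and block structure", {
  net <- generate_random(500, 400, 40, seed = 11)
  a <- net$adjacency
  expect_equal(sum(a != 0), 20000)
  expect_equal(sum(a[1:400, ] != 0), 16000)   # excitatory-sourced
  expect_equal(sum(a[401:500, ] != 0), 4000)  # inhibitory-sourced
  expect_equal(sum(a > 0), 16000)
  expect_equal(sum(a < 0), 4000)
  expect_true(all(diag(a) == 0))
  # inhibitory neurons project only onto excitatory neurons
  expect_true(all(a[401:500, 401:500] == 0))
  # counting argument: mean excitatory in-degree and inhibitory in-degree on E
  expect_equal(mean(colSums(a[1:400, ] != 0)), 32.0)
  expect_equal(mean(colSums(a[401:500, 1:400] != 0)), 10.0)
  # delays: excitatory in 1..20 ms, inhibitory exactly 1 ms
  expect_true(all(net$delays[1:400, ][a[1:400, ] != 0] %in% 1:20))
  expect_true(all(net$delays[401:500, ][a[401:500, ] != 0] == 1))
})

test_that("degenerate out-degree gives an empty network; bad arguments error", {
  expect_equal(sum(generate_random(10, 8, 0, seed = 1)$adjacency != 0), 0)
  expect_error(generate_random(10, 8, 10, seed = 1), "out_degree")
  expect_error(generate_random(50, 10, 20, seed = 1), "inhibitory")
  expect_error(generate_small_world(rewiring_p = 1.5), "rewiring_p")
  expect_error(generate_small_world(out_degree = 39), "even")
  expect_error(generate_modular(intra_p = 0.01, inter_p = 0.2), "weakly coupled")
})

test_that("generators are deterministic given the seed", {
  for (gen in list(generate_random, generate_small_world, generate_scale_free)) {
    a <- gen(seed = 42)$adjacency
    b <- gen(seed = 42)$adjacency
    expect_identical(a, b)
  }
})

test_that("random in-degrees follow the binomial law", {
  # excitatory in-degree of excitatory neurons ~ Binomial(399, 40/499)
  deg <- unlist(lapply(1:6, function(s)
    colSums(generate_random(seed = 100 + s)$adjacency[1:400, 1:400] != 0)))
  ks <- 0:400
  p_theory <- dbinom(ks, 399, 40 / 499)
  # collapse bins with expected count < 5
  obs <- tabulate(deg + 1, nbins = 401)
  exp_ <- p_theory * length(deg)
  keep <- exp_ >= 5
  obs2 <- c(sum(obs[!keep & ks < 32]), obs[keep], sum(obs[!keep & ks >= 32]))
  exp2 <- c(sum(exp_[!keep & ks < 32]), exp_[keep], sum(exp_[!keep & ks >= 32]))
  pval <- stats::chisq.test(obs2, p = exp2 / sum(exp2))$p.value
  expect_gt(pval, 0.01)
})

test_that("small-world generator at p = 0 leaves a pure ring lattice", {
  # all-excitatory 20-node lattice, degree 4: clustering coefficient 1/2
  net <- generate_small_world(20, 20, 4, rewiring_p = 0, seed = 3)
  cc <- clustering_coefficient(net)
  expect_equal(unname(cc$per_node), rep(0.5, 20))
  # 500-neuron case: every E->E link is a ring-lattice link
  big <- generate_small_world(rewiring_p = 0, seed = 4)
  ee <- which(big$adjacency[1:400, 1:400] != 0, arr.ind = TRUE)
  ring_dist <- pmin((ee[, 2] - ee[, 1]) %% 400, (ee[, 1] - ee[, 2]) %% 400)
  expect_true(all(ring_dist >= 1 & ring_dist <= 20))
  # every inhibitory neuron receives at least one excitatory input
  expect_true(all(colSums(big$adjacency[1:400, 401:500] != 0) >= 1))
  expect_equal(sum(big$adjacency != 0), 20000)
})

test_that("small-world clustering decreases with the rewiring probability", {
  cc_of <- function(p) clustering_coefficient(
    generate_small_world(rewiring_p = p, seed = 7)$adjacency[1:400, 1:400])$mean
  c0 <- cc_of(0); c3 <- cc_of(0.3); c9 <- cc_of(0.9)
  expect_gt(c0, c3)
  expect_gt(c3, c9)
})

test_that("scale-free generator: heavy-tailed out-degrees, normal in-degrees", {
  net <- generate_scale_free(seed = 21)
  expect_equal(sum(net$adjacency != 0), 20000)
  outdeg <- rowSums(net$adjacency != 0)
  expect_gt(max(outdeg), 2 * median(outdeg))   # non-uniform, long tail
  for (s in 22:24) {
    n2 <- generate_scale_free(seed = s)
    outd <- rowSums(n2$adjacency[1:400, ] != 0)
    ind <- colSums(n2$adjacency != 0)
    g_out <- fit_degree_distribution(outd, "gaussian")$r_squared
    p_out <- fit_degree_distribution(outd, "powerlaw", cumulative = TRUE)$r_squared
    g_in <- fit_degree_distribution(ind, "gaussian")$r_squared
    p_in <- fit_degree_distribution(ind, "powerlaw", cumulative = TRUE)$r_squared
    expect_gt(p_out, g_out)   # out-degrees: power law wins
    expect_gt(g_in, p_in)     # in-degrees: gaussian wins
  }
})

test_that("modular generator respects blocks and weak coupling", {
  # two modules of 50 inside a 125-neuron (100 excitatory) net, no coupling
  net <- generate_modular(125, c(50, 50), intra_p = 0.2, inter_p = 0, seed = 5)
  a <- net$adjacency
  expect_true(all(a[1:50, 51:100] == 0))
  expect_true(all(a[51:100, 1:50] == 0))
  expect_gt(sum(a[1:50, 1:50] != 0), 0)
  # homogeneous probabilities: intra and inter densities statistically equal
  h <- generate_modular(125, c(50, 50), intra_p = 0.05, inter_p = 0.05, seed = 6)
  b <- h$adjacency[1:100, 1:100] != 0
  intra <- c(b[1:50, 1:50][!diag(50)], b[51:100, 51:100][!diag(50)])
  inter <- c(b[1:50, 51:100], b[51:100, 1:50])
  pt <- stats::prop.test(c(sum(intra), sum(inter)),
                         c(length(intra), length(inter)))
  expect_gt(pt$p.value, 0.01)
  # default three-module layout is simulator-ready
  d <- generate_modular(seed = 7)
  expect_s3_class(d, "structural_network")
  expect_true(all(attr(d, "modules")[401:500] == 3))
})

test_that("initial weights respect sign conventions with a positive floor", {
  net <- generate_random(seed = 31)
  w_exc <- net$adjacency[1:400, ][net$adjacency[1:400, ] != 0]
  w_inh <- net$adjacency[401:500, ][net$adjacency[401:500, ] != 0]
  expect_true(all(w_exc >= 0.1))
  expect_true(all(w_inh <= -0.1))
  expect_equal(mean(w_exc), 7, tolerance = 0.05)
  expect_equal(mean(w_inh), -7, tolerance = 0.05)
})
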