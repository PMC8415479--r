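# Square test matrix with a chosen off-diagonal fill, row-major order.
fill_cm <- function(vals, n) {
  m <- matrix(0, n, n)
  slots <- which(t(row(m) != col(m)))  # row-major off-diagonal positions
  mt <- t(m); mt[slots[seq_along(vals)]] <- vals
  t(mt)
}

test_that("hard threshold reproduces the hand-computed example", {
  # positive entries {10, 1, 1, 1, 1}: mu = 2.8, sd = 4.025, th = 6.825
  cm <- fill_cm(c(10, 1, 1, 1, 1), 3)
  res <- suppressWarnings(hard_threshold(cm, n_exc = 1))
  expect_equal(res$n_exc_links, 1)
  expect_equal(sort(res$fm[res$fm != 0]), 10)
  # all positive entries identical: sd = 0, strict inequality keeps nothing
  same <- fill_cm(rep(2, 5), 3)
  res0 <- suppressWarnings(hard_threshold(same, n_exc = 1))
  expect_equal(res0$n_exc_links + res0$n_inh_links, 0)
  # signs thresholded independently with their own multipliers
  mixed <- fill_cm(c(10, 1, 1, 1, -9, -1, -1, -1), 4)
  resm <- hard_threshold(mixed, n_exc = 1, n_inh = 1)
  expect_equal(resm$n_exc_links, 1)
  expect_equal(resm$n_inh_links, 1)
  expect_true(all(resm$fm %in% c(0, 10, -9)))
})

test_that("the second threshold recovers strong rejected rows as hand-derived", {
  # RM row [4, 1, 1, 1]: n_exc huge so the first pass rejects everything
  cm <- matrix(0, 5, 5); cm[1, 2:5] <- c(4, 1, 1, 1)
  res <- suppressWarnings(ddt(cm, n_exc = 10, n_inh = 2, m_exc = 1, m_inh = 1))
  expect_equal(sum(res$t1cm != 0), 0)
  expect_equal(res$rm[1, 2:5], c(4, 1, 1, 1))
  # element 4: candidates {1,1,1} -> mu 1, sd 0, TM 1, recovered
  expect_equal(res$tm[1, 2], 1)
  expect_equal(res$t2cm[1, 2], 4)
  # element 1: candidates {4,1,1} -> mu 2, sd sqrt(3), TM 3.732, rejected
  expect_equal(res$tm[1, 3], 2 + sqrt(3), tolerance = 1e-12)
  expect_equal(res$t2cm[1, 3], 0)
  expect_equal(support_of(res$fm), support_of(res$t2cm))
})

test_that("ddt equals the literal pseudocode oracle on small matrices", {
  set.seed(10)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    cm <- random_signed_cm(n, density = runif(1, 0.4, 0.9))
    pars <- list(n_exc = sample(c(1, 2), 1), n_inh = sample(c(1, 2), 1),
                 m_exc = sample(c(1, 3), 1), m_inh = sample(c(1, 3), 1))
    res <- suppressWarnings(ddt(cm, pars$n_exc, pars$n_inh, pars$m_exc, pars$m_inh))
    ora <- ddt_oracle(cm, pars$n_exc, pars$n_inh, pars$m_exc, pars$m_inh)
    expect_equal(res$t1cm, ora$t1)
    expect_equal(res$rm, ora$rm)
    expect_equal(res$t2cm, ora$t2)
    expect_equal(res$fm, ora$fm)
  }
})

test_that("ddt structural invariants hold on random matrices", {
  set.seed(11)
  for (rep in 1:6) {
    cm <- random_signed_cm(12)
    res <- suppressWarnings(ddt(cm))
    ht <- suppressWarnings(hard_threshold(cm))
    # intermediates partition the input support
    expect_length(intersect(support_of(res$t1cm), support_of(res$t2cm)), 0)
    expect_setequal(support_of(res$fm),
                    union(support_of(res$t1cm), support_of(res$t2cm)))
    expect_setequal(support_of(res$rm),
                    setdiff(support_of(cm), support_of(res$t1cm)))
    # superset of the hard threshold, signs preserved
    expect_true(all(support_of(ht$fm) %in% support_of(res$fm)))
    expect_true(all(sign(res$fm[res$fm != 0]) == sign(cm[res$fm != 0])))
    # m -> Inf degenerates to the hard threshold
    lim <- suppressWarnings(ddt(cm, m_exc = 1e12, m_inh = 1e12))
    expect_equal(lim$fm, ht$fm)
    # all-zero input stays empty
    z <- suppressWarnings(ddt(matrix(0, 6, 6)))
    expect_equal(sum(z$fm != 0), 0)
  }
})

test_that("thresholds are monotone in their multipliers", {
  set.seed(12)
  cm <- random_signed_cm(15)
  t1_sizes <- sapply(c(0.5, 1, 2, 4), function(n_)
    sum(suppressWarnings(ddt(cm, n_exc = n_))$t1cm > 0))
  expect_true(all(diff(t1_sizes) <= 0))
  t2_sizes <- sapply(c(0.5, 1, 2, 4), function(m_)
    sum(suppressWarnings(ddt(cm, m_exc = m_))$t2cm > 0))
  expect_true(all(diff(t2_sizes) <= 0))
})

test_that("relabelling neurons permutes the output identically", {
  set.seed(13)
  cm <- random_signed_cm(10)
  p <- sample(10)
  for (fun in list(function(m) suppressWarnings(ddt(m))$fm,
                   function(m) suppressWarnings(hard_threshold(m))$fm,
                   function(m) density_threshold(m, 8, 4)$fm)) {
    expect_equal(fun(cm[p, p]), fun(cm)[p, p])
  }
})

test_that("density threshold keeps exactly the strongest links", {
  cm <- fill_cm(c(5, 4, 3, 2, 1), 3)
  res <- density_threshold(cm, 2, 0)
  expect_setequal(res$fm[res$fm != 0], c(5, 4))
  # keeping everything reproduces the support
  all_ <- density_threshold(cm, 5, 0)
  expect_setequal(support_of(all_$fm), support_of(cm))
  # over-request clips with a warning
  expect_warning(density_threshold(cm, 9, 0), "clipped")
  # deterministic row-major tie-break
  tied <- matrix(0, 3, 3); tied[1, 2] <- 1; tied[1, 3] <- 1; tied[2, 1] <- 1
  keep1 <- density_threshold(tied, 1, 0)
  expect_equal(support_of(keep1$fm), which(row(tied) == 1 & col(tied) == 2))
  # calibration: DT forced to the DDT link counts matches them exactly
  set.seed(14)
  big <- random_signed_cm(20)
  dres <- suppressWarnings(ddt(big))
  dt <- density_threshold(big, dres$n_exc_links, dres$n_inh_links)
  expect_equal(dt$n_exc_links, dres$n_exc_links)
  expect_equal(dt$n_inh_links, dres$n_inh_links)
})

test_that("shuffle threshold keeps true links and obeys its contract", {
  set.seed(15)
  a <- poisson_train(6, 6e4)
  trains <- list(a, sort(a + 4), poisson_train(6, 6e4))
  spk <- spikes_from_trains(trains, 6e4 + 10)
  cm <- estimate_cm(spk)
  res <- shuffle_threshold(spk, cm, n_shuffles = 30, alpha = 0.01, seed = 16)
  expect_true(res$fm[1, 2] > 0)             # the planted link survives
  expect_error(shuffle_threshold(spk, cm, n_shuffles = 5), "n_shuffles")
  expect_error(shuffle_threshold(spk, cm, alpha = 0.7), "alpha")
})

test_that("shuffle threshold false-positive rate matches the significance level", {
  set.seed(17)
  n <- 60
  trains <- replicate(n, poisson_train(5, 6e4), simplify = FALSE)
  spk <- spikes_from_trains(trains, 6e4)
  cm_full <- estimate_cm(spk)
  # restrict to 200 random independent ordered pairs
  vals <- matrix(0, n, n)
  off <- which(row(vals) != col(vals))
  pairs <- sample(off, 200)
  vals[pairs] <- cm_full$values[pairs]
  cm <- connectivity_matrix(vals)
  res <- shuffle_threshold(spk, cm, n_shuffles = 40, alpha = 0.01, seed = 18)
  kept <- sum(res$fm != 0)
  # binomial(200, 0.01): 99% interval [0, 6]
  expect_lte(kept, qbinom(0.995, 200, 0.01))
})
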