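test_that("the LP instance materializes the right constraint families", {
  P <- matrix(0.5, 3, 3); diag(P) <- 0
  inst <- build_lp(P, eps = 0.5)
  expect_equal(inst$n_vars, 6L)
  expect_equal(inst$n_antisymmetry, 3)
  expect_equal(inst$n_transitivity, 6L)   # ordered triples of distinct nodes
  expect_equal(inst$n_density, 1L)
  expect_error(build_lp(P, eps = 1.2), "eps")
  Pna <- P; Pna[1, 2] <- NA
  expect_error(build_lp(Pna, eps = 0.5), "missing")
  Pbad <- P; Pbad[1, 2] <- 0.9; Pbad[2, 1] <- 0.9
  expect_error(build_lp(Pbad, eps = 0.5), "p\\[u,v\\]")
})

test_that("degenerate coefficient patterns solve in closed form", {
  # uninformative p = 1/2: numerator is half the denominator for any x
  P <- matrix(0.5, 4, 4); diag(P) <- 0
  for (e in c(0, 0.4, 1)) {
    expect_equal(solve_bound(build_lp(P, eps = e), backend = "simplex")$value,
                 0.5, tolerance = 1e-9)
  }
  # n = 2 with a forced pair: set x[1,2] = 1
  P2 <- matrix(0, 2, 2); P2[1, 2] <- 1
  expect_equal(solve_bound(build_lp(P2, eps = 1), backend = "simplex")$value, 1,
               tolerance = 1e-9)
})

test_that("the HiGHS and dense-simplex backends agree", {
  set.seed(14)
  P <- rand_recip_p(6)
  for (e in c(0.2, 0.7, 1)) {
    inst <- build_lp(P, eps = e)
    a <- solve_bound(inst, backend = "simplex")$value
    b <- solve_bound(inst, backend = "highs")$value
    expect_equal(a, b, tolerance = 1e-6)
    expect_true(b >= 0 && b <= 1 + 1e-9)
  }
})

test_that("the relaxation dominates every brute-force-optimal partial order", {
  set.seed(8)
  posets <- enumerate_posets(5)
  expect_length(posets, 4231L)            # known labeled poset count
  P <- rand_recip_p(5)
  for (e in c(0.2, 0.5, 0.8, 1)) {
    lp <- solve_bound(build_lp(P, eps = e), backend = "simplex")$value
    best <- best_poset_objective(posets, P, e)
    expect_gte(lp + 1e-8, best)
  }
  # and the bound is tight at eps = 1 where the best total order is feasible
  lp1 <- solve_bound(build_lp(P, eps = 1), backend = "simplex")$value
  expect_lte(lp1, 1)
})

test_that("bounds are monotone non-increasing in the density floor", {
  set.seed(9)
  P <- rand_recip_p(6)
  vals <- sapply(seq(0.1, 1, by = 0.3), function(e)
    solve_bound(build_lp(P, eps = e), backend = "simplex")$value)
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("the returned fractional solution is feasible and attains the bound", {
  set.seed(15)
  P <- rand_recip_p(5)
  res <- solve_bound(build_lp(P, eps = 0.6), backend = "simplex")
  x <- res$x
  expect_true(all(x >= -1e-9 & x <= 1 + 1e-9))
  expect_true(all(x + t(x) <= 1 + 1e-8))
  expect_gte(sum(x), 0.6 * choose(5, 2) - 1e-8)
  expect_equal(sum(P * x) / sum(x), res$value, tolerance = 1e-8)
  for (u in 1:5) for (v in 1:5) for (w in 1:5) {
    if (length(unique(c(u, v, w))) == 3L) {
      expect_gte(x[u, w] + 1e-8, x[u, v] + x[v, w] - 1)
    }
  }
})

test_that("the bound curve is feasible for the perfect-precision order", {
  h <- permute_snapshot(simulate_pa(n = 16, m = 2, seed = 3), seed = 4)
  dag <- peel(h)
  perf <- perfect_precision_order(dag)
  bc <- bound_curve(h, eps_grid = c(0.05, order_density(perf), 0.6, 1),
                    pairprob_method = "mcmc", k_steps = 2e4, seed = 5)
  expect_true(all(diff(bc$bound) <= 1e-7))
  # the precision-1 order is feasible at its own density, so the bound is ~1
  expect_gte(bc$bound[2], 1 - 0.02)
  expect_error(bound_curve(h, max_n = 10), "too large")
})

test_that("estimator orders are dominated under the LP's own coefficients", {
  h <- permute_snapshot(simulate_pa(n = 12, m = 2, seed = 6), seed = 7)
  dag <- peel(h)
  P <- pair_prob_matrix(mcmc_pair_probs(dag, k_steps = 3e4, seed = 8, h = h))
  for (o in list(perfect_precision_order(dag), peeling_order(dag),
                 peeling_plus_order(h, dag))) {
    if (o$K == 0) next
    e <- order_density(o)
    lp <- solve_bound(build_lp(P, eps = e), backend = "simplex")$value
    expect_gte(lp + 1e-6, integer_objective(o, P))
  }
})
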