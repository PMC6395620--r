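test_that("extension enumeration matches closed-form counts", {
  empty4 <- recovered_dag(4, younger = integer(), older = integer())
  expect_length(enumerate_extensions(empty4), factorial(4))
  chain <- recovered_dag(4, younger = c(4L, 3L, 2L), older = c(3L, 2L, 1L))
  expect_equal(enumerate_extensions(chain), list(1:4))
  # two disjoint 2-chains interleave in 4!/(2! 2!) = 6 ways
  expect_length(enumerate_extensions(methods_dag()), 6L)
  big <- recovered_dag(20, younger = integer(), older = integer())
  expect_error(enumerate_extensions(big), "mcmc_pair_probs")
})

test_that("exact pair probabilities come from the extension fractions", {
  d <- methods_dag()
  expect_equal(exact_pair_probs(d, cbind(4, 1))$p, 1)   # forced: v4 before v1
  expect_equal(exact_pair_probs(d, cbind(1, 4))$p, 0)
  expect_equal(exact_pair_probs(d, cbind(2, 4))$p, 1 / 2)
  empty <- recovered_dag(5, younger = integer(), older = integer())
  expect_true(all(exact_pair_probs(empty)$p == 1 / 2))
  expect_error(exact_pair_probs(d, cbind(2, 2)), "u = v")
})

test_that("sequential extensions are valid linear extensions", {
  # a chain DAG admits a single extension, whatever the seed
  chain <- recovered_dag(3, younger = c(3L, 2L), older = c(2L, 1L))
  for (s in 1:5) {
    expect_equal(sequential_extension(chain, seed = s), 1:3)
  }
  set.seed(99)
  for (r in 1:50) {
    h <- permute_snapshot(simulate_pa(n = 30, m = 2))
    dag <- peel(h)
    ext <- sequential_extension(h, dag)
    pos <- integer(h$n); pos[ext] <- seq_len(h$n)
    a <- dag$arcs
    expect_true(all(pos[a$older] < pos[a$younger]))
  }
})

test_that("the sequential initializer is not uniform over extensions", {
  # on the two-2-chain DAG the random-topological fallback picks each next
  # node uniformly among available ones, giving probability 1/8 (not 1/6)
  # to extensions fixing a full chain first
  d <- methods_dag()
  draws <- withr::with_seed(13, {
    replicate(20000, paste(sequential_extension(d), collapse = ""))
  })
  freq <- table(draws) / length(draws)
  expect_length(freq, 6L)
  expect_gt(max(abs(freq - 1 / 6)), 0.02)
  expect_equal(unname(freq[["2341"]]), 1 / 8, tolerance = 0.15)
})

test_that("walk degrees count admissible adjacent transpositions", {
  d <- methods_dag()
  expect_equal(walk_neighbors(c(4, 1, 2, 3), d)$d, 1L)
  expect_equal(walk_neighbors(c(4, 1, 2, 3), d)$positions, 2L)
  chain <- recovered_dag(4, younger = c(4L, 3L, 2L), older = c(3L, 2L, 1L))
  expect_equal(walk_neighbors(1:4, chain)$d, 0L)
  empty <- recovered_dag(6, younger = integer(), older = integer())
  expect_equal(walk_neighbors(sample(6), empty)$d, 5L)
})

test_that("the ratio-form walk reproduces exact probabilities", {
  d <- methods_dag()
  pp <- mcmc_pair_probs(d, rbind(c(2, 4), c(4, 2), c(4, 1)),
                        k_steps = 5e4, seed = 3)
  expect_equal(pp$p[pp$u == 4 & pp$v == 1], 1)            # forced, exactly
  expect_equal(pp$p[1] + pp$p[2], 1, tolerance = 1e-12)   # shared samples
  expect_equal(pp$p[1], 0.5, tolerance = 0.04)
  expect_equal(attr(pp, "method"), "mcmc")
  # a chain admits one extension: the walk degenerates to the exact answer
  chain <- recovered_dag(3, younger = c(3L, 2L), older = c(2L, 1L))
  pc <- mcmc_pair_probs(chain, cbind(1, 3), k_steps = 10, seed = 1)
  expect_identical(pc$p, 1)
  expect_equal(attr(pc, "method"), "exact")
})

test_that("walk error against the enumeration oracle shrinks with k", {
  d <- methods_dag()
  exact <- exact_pair_probs(d, cbind(2, 4))$p
  med_err <- sapply(c(500, 5000, 50000), function(k) {
    errs <- sapply(1:8, function(s)
      abs(mcmc_pair_probs(d, cbind(2, 4), k_steps = k, seed = s)$p - exact))
    median(errs)
  })
  expect_true(med_err[3] < med_err[1])
  expect_lt(med_err[3], 0.02)
})

test_that("random DAGs: walk matches enumeration across all pairs", {
  set.seed(21)
  for (r in 1:5) {
    d <- random_dag(7, arc_prob = 0.4)
    ex <- exact_pair_probs(d)
    mc <- mcmc_pair_probs(d, cbind(ex$u, ex$v), k_steps = 5e4)
    expect_lt(max(abs(mc$p - ex$p)), 0.05)
  }
})

test_that("the optional convergence rule stops the walk early", {
  d <- methods_dag()
  pp <- mcmc_pair_probs(d, cbind(2, 4), k_steps = 2e5, seed = 2,
                        convergence = list(window = 5000, tol = 5e-3))
  expect_lt(attr(pp, "k"), 2e5)
  expect_equal(pp$p, 0.5, tolerance = 0.05)
})

test_that("reciprocity and forced pairs hold in the full matrix", {
  set.seed(33)
  d <- random_dag(8, arc_prob = 0.3)
  P <- pair_prob_matrix(mcmc_pair_probs(d, k_steps = 2e4))
  expect_true(all(abs(P + t(P) - 1)[upper.tri(P)] < 1e-12))
  forced <- netarch:::dag_reachability(d)
  expect_true(all(P[cbind(which(forced, arr.ind = TRUE)[, 2],
                          which(forced, arr.ind = TRUE)[, 1])] == 1))
})
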