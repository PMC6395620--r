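test_that("seed node carries m self-loops and degree identities hold", {
  for (sim in list(simulate_pa, simulate_ua)) {
    g1 <- sim(n = 1, m = 3, seed = 1)
    expect_equal(nrow(g1$edges), 3L)
    expect_true(all(g1$edges$from == 1L & g1$edges$to == 1L))
    expect_equal(node_degrees(g1), 6L)   # each self-loop contributes 2
  }
  for (m in c(1L, 4L)) {
    g <- simulate_pa(n = 37, m = m, seed = m)
    expect_equal(nrow(g$edges), m * 37L)
    expect_equal(sum(node_degrees(g)), 2L * m * 37L)
    u <- simulate_ua(n = 37, m = m, seed = m)
    expect_equal(nrow(u$edges), m * 37L)
  }
})

test_that("invalid model specifications are rejected", {
  expect_error(model_spec("pa", n = 0, m = 1), "n")
  expect_error(model_spec("pa", n = 5, m = 0), "m")
  expect_error(model_spec("pa", n = 5, m = c(4, 2)), "a <= b")
  expect_error(model_spec("pa", n = 5, m = 1, cf_pref_prob = 1.2), "\\[0, 1\\]")
  expect_error(simulate_pa(model_spec("ua", n = 5, m = 1)), "pa")
})

test_that("PA(m = 1) degree distribution matches the stationary law", {
  # P(k) = 4 / (k (k+1) (k+2)); the analytically derived fraction of
  # degree-1 nodes is 4 / (1*2*3) = 2/3
  g <- simulate_pa(n = 20000, m = 1, seed = 101)
  expect_equal(mean(node_degrees(g) == 1L), 2 / 3, tolerance = 0.02 * 3 / 2)
  # and P(2) = 4/24 = 1/6 as a second point on the law
  expect_equal(mean(node_degrees(g) == 2L), 1 / 6, tolerance = 0.02 * 6)
})

test_that("UA matches an independent straight-line oracle", {
  n <- 150; m <- 2; reps <- 120
  withr::with_seed(7, {
    oracle <- replicate(reps, ua_node1_degree_oracle(n, m))
  })
  withr::with_seed(8, {
    ours <- replicate(reps, node_degrees(simulate_ua(n = n, m = m))[1L])
  })
  se <- sqrt(var(oracle) / reps + var(ours) / reps)
  expect_lt(abs(mean(oracle) - mean(ours)), 3 * se)
})

test_that("snapshot permutation is uniform and structure-preserving", {
  g1 <- simulate_pa(n = 1, m = 2, seed = 1)
  h1 <- permute_snapshot(g1, seed = 2)
  expect_equal(h1$arrival, 1L)          # S_1 has a single element
  g <- simulate_pa(n = 60, m = 3, seed = 3)
  h <- permute_snapshot(g, seed = 4)
  expect_equal(sort(node_degrees(h)), sort(node_degrees(g)))
  expect_equal(sort(h$arrival), 1:60)
  # uniformity over S_3: every permutation within +-0.01 of 1/6
  g3 <- simulate_pa(n = 3, m = 1, seed = 5)
  draws <- withr::with_seed(6, {
    replicate(60000, paste(permute_snapshot(g3)$arrival, collapse = ""))
  })
  freqs <- table(draws) / length(draws)
  expect_length(freqs, 6L)
  expect_lt(max(abs(freqs - 1 / 6)), 0.01)
})

test_that("Cooper-Frieze degenerates to PA and UA at extreme parameters", {
  # with P(new node) = 1 and all-preferential (resp. all-uniform) endpoint
  # coins, the process is distributionally the PA (resp. UA) model; compare
  # degree sequences by a two-sample KS test at alpha = 0.01
  withr::with_seed(42, {
    reject <- c(pa = 0L, ua = 0L)
    reps <- 10L
    for (r in seq_len(reps)) {
      cf_pa <- simulate_cooper_frieze(model_spec("cooper_frieze", n = 400, m = 3,
                                                 cf_new_node_prob = 1, cf_pref_prob = 1))
      pa <- simulate_pa(n = 400, m = 3)
      if (suppressWarnings(ks.test(node_degrees(cf_pa), node_degrees(pa))$p.value) < 0.01)
        reject["pa"] <- reject["pa"] + 1L
      cf_ua <- simulate_cooper_frieze(model_spec("cooper_frieze", n = 400, m = 3,
                                                 cf_new_node_prob = 1, cf_pref_prob = 0))
      ua <- simulate_ua(n = 400, m = 3)
      if (suppressWarnings(ks.test(node_degrees(cf_ua), node_degrees(ua))$p.value) < 0.01)
        reject["ua"] <- reject["ua"] + 1L
    }
    expect_lte(reject[["pa"]], 1L)
    expect_lte(reject[["ua"]], 1L)
  })
})

test_that("Cooper-Frieze adds nodes at the configured rate", {
  g <- simulate_cooper_frieze(n = 5000, m = c(5, 50), seed = 4)
  expect_equal(g$n / g$n_steps, 0.75, tolerance = 0.02 / 0.75)
  expect_equal(length(g$m_of), 5000L)
  expect_true(all(g$m_of >= 5 & g$m_of <= 50))
})

test_that("minimum snapshot degree equals m for fixed-m models", {
  for (s in 1:5) {
    g <- simulate_pa(n = 200, m = 3, seed = s)
    expect_equal(min(node_degrees(g)), 3L)
    expect_equal(node_degrees(g)[200L], 3L)  # the last arrival is untouched
    u <- simulate_ua(n = 200, m = 3, seed = s)
    expect_equal(min(node_degrees(u)), 3L)
  }
})

test_that("true DAG orients younger to older with out-degree m", {
  g <- simulate_pa(n = 80, m = 3, seed = 11)
  d <- true_dag(g)
  expect_true(all(d$arcs$younger > d$arcs$older))
  outdeg <- tabulate(d$arcs$younger, g$n)
  expect_true(all(outdeg[-1L] == 3L))     # the seed's self-loops are dropped
  expect_equal(outdeg[1L], 0L)
})

test_that("simulations are reproducible from their seed", {
  g1 <- simulate_cooper_frieze(n = 300, m = c(2, 6), seed = 99)
  g2 <- simulate_cooper_frieze(n = 300, m = c(2, 6), seed = 99)
  expect_identical(g1$edges, g2$edges)
  h1 <- permute_snapshot(g1, seed = 5)
  h2 <- permute_snapshot(g2, seed = 5)
  expect_identical(h1$arrival, h2$arrival)
})
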