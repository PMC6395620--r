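star_snapshot <- function(leaves = 5L) {
  # center is node 1
  netarch:::new_snapshot(leaves + 1L, u = rep(1L, leaves), v = 2:(leaves + 1L))
}

test_that("peeling a star puts leaves in bin 1 and orients leaf -> center", {
  d <- peel(star_snapshot(5L))
  expect_equal(d$level, c(2L, rep(1L, 5L)))
  expect_equal(d$n_bins, 2L)
  expect_true(all(d$arcs$younger %in% 2:6))
  expect_true(all(d$arcs$older == 1L))
  expect_equal(nrow(d$arcs), 5L)
})

test_that("symmetric graphs collapse into one unoriented bin", {
  tri <- netarch:::new_snapshot(3L, u = c(1L, 2L, 3L), v = c(2L, 3L, 1L))
  d <- peel(tri)
  expect_equal(d$level, rep(1L, 3L))
  expect_equal(nrow(d$arcs), 0L)
  expect_equal(d$dropped_same_bin, 3L)
  expect_equal(peeling_order(d)$K, 0)
})

test_that("peeling exactly recovers the permuted true DAG on fixed-m PA", {
  for (m in c(1L, 2L, 3L, 25L)) {
    for (s in 1:4) {
      g <- simulate_pa(n = 300, m = m, seed = s * 31L + m)
      h <- permute_snapshot(g, seed = s)
      d <- peel(h)
      expect_same_arcs(d, permuted_true_dag(g, h))
      expect_equal(d$dropped_same_bin, 0L)
      # every arc runs from a strictly earlier bin to a later one
      expect_true(all(d$level[d$arcs$younger] < d$level[d$arcs$older]))
    }
  }
})

test_that("fixed_m mode agrees with generalized peeling on PA snapshots", {
  h <- permute_snapshot(simulate_pa(n = 200, m = 3, seed = 9), seed = 10)
  d1 <- peel(h, mode = "min_degree")
  d2 <- peel(h, mode = "fixed_m")
  expect_identical(d1$level, d2$level)
  expect_same_arcs(d1, d2)
})

test_that("empty input is rejected and isolated nodes form a bin", {
  expect_error(peel(structure(list(n = 0L), class = "snapshot")))
  iso <- netarch:::new_snapshot(4L, u = c(1L, 2L), v = c(2L, 1L))  # 3,4 isolated
  d <- peel(iso)
  expect_equal(d$level[3:4], c(1L, 1L))
})

test_that("perfect-precision order is the reachability closure", {
  # chain c -> b -> a (3 -> 2 -> 1): a before b before c, K = 3
  chain <- recovered_dag(3, younger = c(3L, 2L), older = c(2L, 1L))
  o <- perfect_precision_order(chain)
  expect_equal(o$K, 3)
  pr <- tidy(o)
  expect_setequal(paste(pr$before, pr$after),
                  c("1 2", "1 3", "2 3"))
  expect_equal(o$raw_arc_pairs, 2L)      # closure vs raw arcs diagnostic
  # arcless DAG: empty order
  empty <- recovered_dag(4, younger = integer(), older = integer())
  o0 <- perfect_precision_order(empty)
  expect_equal(o0$K, 0)
  expect_warning(s0 <- score_order(o0, 1:4), "undefined")
  expect_true(is.nan(s0$precision))
  expect_equal(s0$density, 0)
  expect_equal(s0$recall, 0)
})

test_that("perfect precision is exactly 1 on fixed-m PA and UA snapshots", {
  for (sim in list(simulate_pa, simulate_ua)) {
    for (s in 1:5) {
      h <- permute_snapshot(sim(n = 250, m = 3, seed = 70 + s), seed = s)
      sc <- score_order(perfect_precision_order(peel(h)), h$arrival)
      expect_identical(sc$precision, 1)
    }
  }
})

test_that("perfect-precision pairs are contained in the peeling order's", {
  for (s in 1:3) {
    h <- permute_snapshot(simulate_pa(n = 120, m = 2, seed = s), seed = s + 50)
    d <- peel(h)
    pp <- tidy(perfect_precision_order(d))
    lv <- d$level
    # every closure pair spans strictly different bins, ordered consistently
    expect_true(all(lv[pp$before] > lv[pp$after]))
    # and the peeling order is strictly denser for n this large
    expect_lt(perfect_precision_order(d)$K, peeling_order(d)$K)
  }
})

test_that("bin orders satisfy the strict partial-order axioms", {
  for (s in 1:3) {
    h <- permute_snapshot(simulate_cooper_frieze(
      model_spec("cooper_frieze", n = 60, m = c(2, 5)), seed = s), seed = s)
    d <- peel(h)
    o <- netarch:::new_partial_order(
      d$n, "pairs", before = setNames(tidy(peeling_order(d)), c("u", "v")),
      K = peeling_order(d)$K)
    expect_silent(validate_partial_order(o))
    op <- peeling_plus_order(h, d)
    o2 <- netarch:::new_partial_order(
      d$n, "pairs", before = setNames(tidy(op), c("u", "v")), K = op$K)
    expect_silent(validate_partial_order(o2))
  }
})

test_that("average neighbor level orders within-bin pairs, ties stay open", {
  # two nodes u=5, v=6 in one bin; anl(v) < anl(u) makes v older: v before u
  lv <- c(3L, 3L, 2L, 2L, 1L, 1L)
  d <- recovered_dag(6, younger = c(5L, 5L, 5L, 6L, 6L),
                     older = c(1L, 2L, 3L, 3L, 4L))
  d$level <- lv
  d$n_bins <- 3L
  h <- netarch:::new_snapshot(6L, u = c(5L, 5L, 5L, 6L, 6L),
                              v = c(1L, 2L, 3L, 3L, 4L))
  o <- peeling_plus_order(h, d)
  # anl(5) = mean(3,3,2) = 8/3; anl(6) = mean(2,2) = 2 -> 6 before 5
  pr <- tidy(o)
  expect_true(any(pr$before == 6L & pr$after == 5L))
  expect_false(any(pr$before == 5L & pr$after == 6L))
  # all distinct anl within bins => total order on comparable bins
  expect_gte(o$K, peeling_order(d)$K)
})

test_that("Peeling+ trades precision for density on PA snapshots", {
  thetas <- matrix(NA_real_, 40, 2)
  deltas <- matrix(NA_real_, 40, 2)
  for (s in seq_len(40)) {
    h <- permute_snapshot(simulate_pa(n = 50, m = 3, seed = 900 + s), seed = s)
    d <- peel(h)
    s1 <- score_order(peeling_order(d), h$arrival)
    s2 <- score_order(peeling_plus_order(h, d), h$arrival)
    thetas[s, ] <- c(s1$precision, s2$precision)
    deltas[s, ] <- c(s1$density, s2$density)
  }
  expect_lte(mean(thetas[, 2]), mean(thetas[, 1]))
  expect_gte(mean(deltas[, 2]), mean(deltas[, 1]))
  expect_true(all(deltas[, 2] > 0.9))    # near-total order
})
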