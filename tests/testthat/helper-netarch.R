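# Shared fixtures and independent oracles for the test suite.

# The 4-node DAG with forced relations v2 before v3 and v4 before v1
# (arcs run younger -> older, so v3 -> v2 and v1 -> v4).
methods_dag <- function() {
  recovered_dag(4, younger = c(3, 1), older = c(2, 4))
}

# Map the true DAG of a grown graph onto the labels of its permuted snapshot.
permuted_true_dag <- function(g, h) {
  relabel_dag(true_dag(g), match(seq_len(g$n), h$arrival))
}

expect_same_arcs <- function(d1, d2) {
  a1 <- netarch:::sorted_arcs(d1)
  a2 <- netarch:::sorted_arcs(d2)
  expect_equal(a1$younger, a2$younger)
  expect_equal(a1$older, a2$older)
}

# Random reciprocal pair-probability matrix.
rand_recip_p <- function(n) {
  p <- matrix(0, n, n)
  ut <- upper.tri(p)
  p[ut] <- runif(sum(ut))
  p[lower.tri(p)] <- (1 - t(p))[lower.tri(p)]
  diag(p) <- 0
  p
}

# Random DAG consistent with a hidden arrival order: arcs point from the
# later arrival to the earlier one, so acyclicity is guaranteed.
random_dag <- function(n, arc_prob = 0.35) {
  hidden <- sample.int(n)                 # hidden[v] = arrival rank of v
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < arc_prob
  u <- pairs[keep, 1L]
  v <- pairs[keep, 2L]
  younger <- ifelse(hidden[u] > hidden[v], u, v)
  older <- ifelse(hidden[u] > hidden[v], v, u)
  recovered_dag(n, younger, older)
}

# Straight-line re-implementation of the uniform-attachment rule, used as an
# independent oracle: returns the final degree of node 1.
ua_node1_degree_oracle <- function(n, m) {
  deg <- integer(n)
  deg[1L] <- 2L * m
  for (t in 2:n) {
    for (j in seq_len(m)) {
      k <- sample.int(t - 1L, 1L)
      deg[k] <- deg[k] + 1L
      deg[t] <- deg[t] + 1L
    }
  }
  deg[1L]
}

# Exhaustive enumeration of all labeled strict partial orders on n elements,
# as a list of logical relation matrices R (R[u, v] = "u before v").
# Decides each unordered pair in a fixed sequence while maintaining the
# transitive closure; branches whose closure would overturn an
# already-decided pair are pruned, so each poset is produced exactly once.
# Counts: n = 3 -> 19, n = 4 -> 219, n = 5 -> 4231.
enumerate_posets <- function(n) {
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  np <- nrow(pairs)
  out <- new.env(parent = emptyenv())
  out$posets <- vector("list", 1024L)
  out$k <- 0L
  emit <- function(R) {
    out$k <- out$k + 1L
    if (out$k > length(out$posets)) length(out$posets) <- 2L * length(out$posets)
    out$posets[[out$k]] <- R
  }
  close_add <- function(R, decided, i, j) {
    # add i<j and close; fail if a newly implied pair was decided incomparable
    xs <- c(i, which(R[, i]))
    ys <- c(j, which(R[j, ]))
    newR <- R
    newR[xs, ys] <- TRUE
    if (newR[j, i] || any(newR[cbind(seq_len(n), seq_len(n))])) return(NULL)
    changed <- which(newR & !R, arr.ind = TRUE)
    if (nrow(changed)) {
      a <- pmin(changed[, 1L], changed[, 2L])
      b <- pmax(changed[, 1L], changed[, 2L])
      pid <- match(paste(a, b), paste(pairs[, 1L], pairs[, 2L]))
      if (any(decided[pid] & !(R[changed] | R[cbind(changed[, 2L], changed[, 1L])]))) {
        return(NULL)
      }
    }
    newR
  }
  recurse <- function(R, decided, k) {
    if (k > np) { emit(R); return(invisible()) }
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    decided2 <- decided; decided2[k] <- TRUE
    if (R[i, j] || R[j, i]) {
      recurse(R, decided2, k + 1L)      # already forced by closure
      return(invisible())
    }
    recurse(R, decided2, k + 1L)        # leave incomparable
    R1 <- close_add(R, decided, i, j)
    if (!is.null(R1)) recurse(R1, decided2, k + 1L)
    R2 <- close_add(R, decided, j, i)
    if (!is.null(R2)) recurse(R2, decided2, k + 1L)
    invisible()
  }
  recurse(matrix(FALSE, n, n), logical(np), 1L)
  out$posets[seq_len(out$k)]
}

# Best integer objective sum(p[R]) / K among all posets with K >= eps * C(n,2).
best_poset_objective <- function(posets, p, eps) {
  n <- nrow(p)
  floor_pairs <- eps * choose(n, 2)
  best <- -Inf
  for (R in posets) {
    K <- sum(R)
    if (K >= floor_pairs - 1e-9 && K > 0L) {
      best <- max(best, sum(p[R]) / K)
    }
  }
  best
}
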