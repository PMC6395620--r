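#' Construct a recovered DAG from explicit arcs
#'
#' Builds a `recovered_dag` directly from arcs oriented younger -> older,
#' e.g. when the age-oriented DAG comes from a file or an external source
#' rather than from [peel()].
#'
#' @param n Number of nodes.
#' @param younger,older Integer vectors of arc endpoints (one entry per
#'   multi-arc), `younger[i] -> older[i]`.
#' @param labels Optional character labels.
#' @return A `recovered_dag` without peel levels.
#' @examples
#' # the 4-node order {v2 before v3, v4 before v1}: arcs younger -> older
#' d <- recovered_dag(4, younger = c(3, 1), older = c(2, 4))
#' @export
recovered_dag <- function(n, younger, older, labels = NULL) {
  stopifnot(length(younger) == length(older))
  if (length(younger) && (max(younger, older) > n || min(younger, older) < 1)) {
    stop("arc endpoints must lie in 1..n", call. = FALSE)
  }
  dag <- new_recovered_dag(n, younger, older, level = NULL,
                           dropped_same_bin = 0L, source = "user",
                           labels = labels)
  if (nrow(dag$arcs)) {
    g <- igraph::graph_from_edgelist(cbind(dag$arcs$younger, dag$arcs$older),
                                     directed = TRUE)
    if (!igraph::is_dag(g)) stop("arcs contain a directed cycle", call. = FALSE)
  }
  dag
}

# node -> unique older prerequisites (nodes that must appear earlier in an
# oldest-first extension)
dag_prereqs <- function(dag) {
  a <- unique(dag$arcs[dag$arcs$younger != dag$arcs$older, , drop = FALSE])
  lapply(split(a$older, factor(a$younger, levels = seq_len(dag$n))), unique)
}

# symmetric node x node "joined by an arc" indicator
arc_adjacency <- function(dag) {
  n <- dag$n
  adj <- matrix(FALSE, n, n)
  if (nrow(dag$arcs)) {
    adj[cbind(dag$arcs$younger, dag$arcs$older)] <- TRUE
    adj[cbind(dag$arcs$older, dag$arcs$younger)] <- TRUE
  }
  adj
}

#' Enumerate all linear extensions of a small DAG
#'
#' Exhaustive backtracking over total orders (oldest node first) consistent
#' with every arc of the DAG.  Counting linear extensions is #P-complete, so
#' this oracle is restricted to small instances; use [mcmc_pair_probs()]
#' beyond the cap.
#'
#' @param dag A `recovered_dag`.
#' @param max_n Node-count cap (default 12).
#' @param max_extensions Abort if more than this many extensions exist.
#' @return A list of integer vectors, each a full extension oldest-first.
#' @examples
#' d <- recovered_dag(4, younger = c(3, 1), older = c(2, 4))
#' length(enumerate_extensions(d))  # 6
#' @export
enumerate_extensions <- function(dag, max_n = 12L, max_extensions = 250000L) {
  stopifnot(inherits(dag, "recovered_dag"))
  n <- dag$n
  if (n > max_n) {
    stop(sprintf(
      "enumeration is exponential; n = %d exceeds the cap %d - use mcmc_pair_probs()",
      n, max_n), call. = FALSE)
  }
  prereq <- dag_prereqs(dag)
  # remaining[u] = number of unplaced prerequisites of u
  remaining <- vapply(prereq, length, integer(1L))
  dependents <- vector("list", n)   # older node -> younger nodes waiting on it
  for (y in seq_len(n)) {
    for (o in prereq[[y]]) dependents[[o]] <- c(dependents[[o]], y)
  }
  acc <- new.env(parent = emptyenv())
  acc$out <- vector("list", 256L)
  acc$k <- 0L
  current <- integer(n)
  placed <- logical(n)
  recurse <- function(depth) {
    if (depth > n) {
      acc$k <- acc$k + 1L
      if (acc$k > max_extensions) {
        stop(sprintf("more than %d extensions; raise `max_extensions`",
                     max_extensions), call. = FALSE)
      }
      if (acc$k > length(acc$out)) length(acc$out) <- 2L * length(acc$out)
      acc$out[[acc$k]] <- current[seq_len(n)]
      return(invisible())
    }
    avail <- which(!placed & remaining == 0L)
    for (v in avail) {
      current[depth] <<- v
      placed[v] <<- TRUE
      deps <- dependents[[v]]
      if (length(deps)) remaining[deps] <<- remaining[deps] - 1L
      recurse(depth + 1L)
      placed[v] <<- FALSE
      if (length(deps)) remaining[deps] <<- remaining[deps] + 1L
    }
    invisible()
  }
  recurse(1L)
  acc$out[seq_len(acc$k)]
}

normalize_pairs <- function(pairs, n) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs[, 1L] == pairs[, 2L])) {
    stop("pair with u = v requested", call. = FALSE)
  }
  if (any(pairs < 1L | pairs > n)) stop("pair outside 1..n", call. = FALSE)
  pairs
}

all_upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(idx[, "row"], idx[, "col"])
}

new_pair_probs <- function(pairs, p, n, method, k = NA_real_) {
  out <- tibble::tibble(u = pairs[, 1L], v = pairs[, 2L], p = as.numeric(p))
  structure(out, n = n, method = method, k = k,
            class = c("pair_probs", class(out)))
}

#' Exact posterior pair-order probabilities by enumeration
#'
#' `p_{u,v}` is the posterior probability that u arrived before v given the
#' snapshot, which equals the fraction of linear extensions of the recovered
#' DAG that rank u before v.  Computed exactly by [enumerate_extensions()],
#' so limited to small DAGs.
#'
#' @param dag A `recovered_dag`.
#' @param pairs Ordered pairs as a 2-column matrix/data frame, or `NULL` for
#'   all pairs `u < v` (label order).
#' @inheritParams enumerate_extensions
#' @return A `pair_probs` tibble with columns `u`, `v`, `p`.
#' @examples
#' d <- recovered_dag(4, younger = c(3, 1), older = c(2, 4))
#' exact_pair_probs(d, cbind(2, 4))  # 1/2 by symmetry of the two chains
#' @export
exact_pair_probs <- function(dag, pairs = NULL, max_n = 12L) {
  stopifnot(inherits(dag, "recovered_dag"))
  pairs <- if (is.null(pairs)) all_upper_pairs(dag$n) else
    normalize_pairs(pairs, dag$n)
  exts <- enumerate_extensions(dag, max_n = max_n)
  counts <- numeric(nrow(pairs))
  for (ext in exts) {
    pos <- integer(dag$n)
    pos[ext] <- seq_len(dag$n)
    counts <- counts + (pos[pairs[, 1L]] < pos[pairs[, 2L]])
  }
  new_pair_probs(pairs, counts / length(exts), dag$n, method = "exact")
}

#' Sample an initial linear extension
#'
#' With a snapshot available this is the sequential variant of peeling: one
#' uniformly chosen current-minimum-degree node is removed at a time, and the
#' reversed removal sequence (oldest first) is a valid extension of the
#' peeled DAG on fixed-m preferential-attachment snapshots (on other graphs
#' the one-at-a-time removal can disagree with the bulk peel, in which case
#' an internal assertion fires and the DAG-based fallback should be used
#' instead).  Without a snapshot (an arbitrary DAG) it falls back to a
#' random topological order obtained by uniformly drawing any node whose
#' older prerequisites are all placed; the sampled distribution over
#' extensions is not uniform in either case.
#'
#' @param x A `snapshot` or a `recovered_dag`.
#' @param dag When `x` is a snapshot: the DAG to validate against (default
#'   `peel(x)`).
#' @param seed Optional seed.
#' @return An integer vector, the extension oldest-first.
#' @export
sequential_extension <- function(x, dag = NULL, seed = NULL) {
  with_seed_(seed, {
    if (inherits(x, "snapshot")) {
      if (is.null(dag)) dag <- peel(x)
      ext <- rev(sequential_removal(x))
    } else if (inherits(x, "recovered_dag")) {
      dag <- x
      ext <- random_topo_extension(x)
    } else {
      stop("`x` must be a snapshot or recovered_dag", call. = FALSE)
    }
    pos <- integer(dag$n)
    pos[ext] <- seq_len(dag$n)
    a <- dag$arcs[dag$arcs$younger != dag$arcs$older, , drop = FALSE]
    if (any(pos[a$older] >= pos[a$younger])) {
      stop("internal error: sequential extension inconsistent with DAG",
           call. = FALSE)
    }
    ext
  })
}

# remove one uniformly chosen minimum-degree node at a time; returns the
# removal sequence (youngest tendency first)
sequential_removal <- function(h) {
  n <- h$n
  eu <- h$edges$u
  ev <- h$edges$v
  ne <- length(eu)
  deg <- tabulate(c(eu, ev), n)
  inc <- split(rep.int(seq_len(ne), 2L), factor(c(eu, ev), levels = seq_len(n)))
  alive_edge <- rep.int(TRUE, max(ne, 1L))
  alive <- rep.int(TRUE, n)
  out <- integer(n)
  for (s in seq_len(n)) {
    cand <- which(alive & deg == min(deg[alive]))
    v <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    out[s] <- v
    eids <- inc[[v]]
    eids <- eids[alive_edge[eids]]
    if (length(eids)) {
      other <- ifelse(eu[eids] == v, ev[eids], eu[eids])
      other <- other[other != v & alive[other]]
      if (length(other)) deg <- deg - tabulate(other, n)
      alive_edge[eids] <- FALSE
    }
    alive[v] <- FALSE
  }
  out
}

random_topo_extension <- function(dag) {
  n <- dag$n
  prereq <- dag_prereqs(dag)
  remaining <- vapply(prereq, length, integer(1L))
  dependents <- vector("list", n)
  for (y in seq_len(n)) {
    for (o in prereq[[y]]) dependents[[o]] <- c(dependents[[o]], y)
  }
  placed <- logical(n)
  out <- integer(n)
  for (depth in seq_len(n)) {
    avail <- which(!placed & remaining == 0L)
    v <- if (length(avail) == 1L) avail else avail[sample.int(length(avail), 1L)]
    out[depth] <- v
    placed[v] <- TRUE
    deps <- dependents[[v]]
    if (length(deps)) remaining[deps] <- remaining[deps] - 1L
  }
  out
}

#' Admissible adjacent transpositions of a linear extension
#'
#' A swap of positions `(i, i+1)` is admissible iff the two nodes are not
#' joined by a DAG arc: adjacent elements of an extension can only be
#' comparable through a direct arc, never through a longer path.  The count
#' of admissible swaps is the degree `d(lambda)` of the extension in the
#' linear-extension graph.
#'
#' @param lambda Integer vector, an extension oldest-first.
#' @param dag The `recovered_dag`.
#' @return List with `positions` (integer vector of admissible `i`) and `d`.
#' @examples
#' d <- recovered_dag(4, younger = c(3, 1), older = c(2, 4))
#' walk_neighbors(c(4, 1, 2, 3), d)$d  # 1
#' @export
walk_neighbors <- function(lambda, dag) {
  stopifnot(inherits(dag, "recovered_dag"), length(lambda) == dag$n)
  adj <- arc_adjacency(dag)
  n <- dag$n
  if (n < 2L) return(list(positions = integer(), d = 0L))
  i <- seq_len(n - 1L)
  ok <- !adj[cbind(lambda[i], lambda[i + 1L])]
  list(positions = i[ok], d = sum(ok))
}

#' Pair-order probabilities by random walk over linear extensions
#'
#' Runs the ratio-form random-walk estimator on the linear-extension graph:
#' a simple random walk choosing uniformly among admissible adjacent
#' transpositions (no lazy self-loops), with accumulators
#' `num = sum_t 1{X_t(u) < X_t(v)} / d(X_t)` and `den = sum_t 1 / d(X_t)`,
#' returning `num / den` per pair.  The degree weighting corrects for the
#' walk's non-uniform stationary distribution, so the estimate converges to
#' the exact linear-extension fraction almost surely.  Pairs forced by the
#' DAG come out exactly 0 or 1, and jointly requested reciprocal pairs
#' satisfy `p(u,v) + p(v,u) = 1` by construction (shared walk samples; in
#' floating point the two accumulators agree to ~1e-13).
#'
#' @param dag A `recovered_dag`.
#' @param pairs Ordered pairs (2-column matrix/data frame) or `NULL` for all
#'   pairs `u < v`.
#' @param k_steps Number of walk states to average over.
#' @param seed Optional seed.
#' @param h Optional `snapshot`, used to draw the initial extension with the
#'   sequential algorithm; otherwise a random topological order is used.
#' @param convergence Optional list `list(window, tol)`: stop early once the
#'   maximum absolute change of all requested probabilities between
#'   consecutive windows of `window` states falls below `tol`.
#' @return A `pair_probs` tibble (`u`, `v`, `p`) with attributes `method`
#'   (`"mcmc"`, or `"exact"` when the DAG admits a single extension) and `k`,
#'   the number of states used.
#' @examples
#' d <- recovered_dag(4, younger = c(3, 1), older = c(2, 4))
#' mcmc_pair_probs(d, cbind(2, 4), k_steps = 2000, seed = 1)
#' @export
mcmc_pair_probs <- function(dag, pairs = NULL, k_steps = 1e5, seed = NULL,
                            h = NULL, convergence = NULL) {
  stopifnot(inherits(dag, "recovered_dag"), k_steps >= 1)
  n <- dag$n
  pairs <- if (is.null(pairs)) all_upper_pairs(n) else normalize_pairs(pairs, n)
  with_seed_(seed, {
    init <- if (!is.null(h)) sequential_extension(h, dag) else
      if (!is.null(dag$level) && !is.null(attr(dag, "snapshot")))
        sequential_extension(attr(dag, "snapshot"), dag) else
          random_topo_extension(dag)
    if (walk_neighbors(init, dag)$d == 0L) {
      # a degree-0 state in the (connected) extension graph means the DAG
      # admits exactly one extension; report the forced answers
      pos <- integer(n)
      pos[init] <- seq_len(n)
      return(new_pair_probs(pairs, as.numeric(pos[pairs[, 1L]] < pos[pairs[, 2L]]),
                            n, method = "exact"))
    }
    adj <- arc_adjacency(dag)
    num <- numeric(nrow(pairs))
    den <- 0
    state <- as.integer(init)
    if (is.null(convergence)) {
      res <- .walk_chunk(adj, state, pairs, as.integer(k_steps), num, den)
      k_used <- k_steps
      p <- res$num / res$den
    } else {
      window <- as.integer(convergence$window %||% 1e4)
      tol <- convergence$tol %||% 1e-3
      k_used <- 0
      p_prev <- NULL
      p <- NULL
      while (k_used < k_steps) {
        chunk <- min(window, k_steps - k_used)
        res <- .walk_chunk(adj, state, pairs, as.integer(chunk), num, den)
        num <- res$num
        den <- res$den
        state <- res$seq
        k_used <- k_used + chunk
        p <- num / den
        if (!is.null(p_prev) && max(abs(p - p_prev)) < tol) break
        p_prev <- p
      }
    }
    new_pair_probs(pairs, p, n, method = "mcmc", k = k_used)
  })
}

#' Expand pair probabilities into a full reciprocal matrix
#'
#' @param pp A `pair_probs` object covering all pairs `u < v`.
#' @return An `n x n` matrix with `P[u, v] + P[v, u] = 1` off the diagonal
#'   and 0 on it.
#' @export
pair_prob_matrix <- function(pp) {
  stopifnot(inherits(pp, "pair_probs"))
  n <- attr(pp, "n")
  P <- matrix(NA_real_, n, n)
  P[cbind(pp$u, pp$v)] <- pp$p
  P[cbind(pp$v, pp$u)] <- 1 - pp$p
  diag(P) <- 0
  if (anyNA(P)) stop("pair_probs does not cover all ordered pairs", call. = FALSE)
  P
}
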