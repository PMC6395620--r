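#' Specify a growing-graph model
#'
#' A `model_spec` bundles the parameters of one of the three supported growth
#' models so simulators and replicated experiments can be driven from a single
#' object.
#'
#' @param model One of `"pa"` (preferential attachment), `"ua"` (uniform
#'   attachment) or `"cooper_frieze"`.
#' @param n Number of nodes in the grown graph (arrival labels `1..n`).
#' @param m Number of connections a new node makes at arrival: either a single
#'   integer (fixed m) or a length-2 integer vector `c(a, b)` meaning
#'   `M ~ unif{a, b}`, drawn independently per arrival.
#' @param cf_new_node_prob Cooper-Frieze only: probability that a step adds a
#'   new node (default 0.75); otherwise the step adds edges between existing
#'   nodes.
#' @param cf_pref_prob Cooper-Frieze only: probability that an edge endpoint is
#'   chosen preferentially (degree-proportional, default 0.5) rather than
#'   uniformly among existing nodes.  Each endpoint flips its own coin.
#' @param seed Optional integer seed recorded in the spec and used by
#'   [simulate_model()].
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("pa", n = 100, m = 3)
#' model_spec("cooper_frieze", n = 500, m = c(5, 50))
#' @export
model_spec <- function(model = c("pa", "ua", "cooper_frieze"),
                       n,
                       m,
                       cf_new_node_prob = 0.75,
                       cf_pref_prob = 0.5,
                       seed = NULL) {
  model <- match.arg(model)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("invalid spec: `n` must be a single integer >= 1", call. = FALSE)
  }
  m <- as.integer(m)
  if (!length(m) %in% c(1L, 2L) || anyNA(m) || any(m < 1L)) {
    stop("invalid spec: `m` must be one integer >= 1 or bounds c(a, b)",
         call. = FALSE)
  }
  if (length(m) == 2L && m[1L] > m[2L]) {
    stop("invalid spec: `m` bounds need a <= b", call. = FALSE)
  }
  if (cf_new_node_prob < 0 || cf_new_node_prob > 1 ||
      cf_pref_prob < 0 || cf_pref_prob > 1) {
    stop("invalid spec: probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(model = model, n = n, m = m,
         cf_new_node_prob = cf_new_node_prob,
         cf_pref_prob = cf_pref_prob,
         seed = seed),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  mm <- if (length(x$m) == 1L) as.character(x$m) else
    sprintf("M ~ unif{%d, %d}", x$m[1L], x$m[2L])
  cat(sprintf("<model_spec> %s: n = %d, m = %s", x$model, x$n, mm))
  if (x$model == "cooper_frieze") {
    cat(sprintf(", P(new node) = %g, P(preferential) = %g",
                x$cf_new_node_prob, x$cf_pref_prob))
  }
  if (!is.null(x$seed)) cat(sprintf(", seed = %d", as.integer(x$seed)))
  cat("\n")
  invisible(x)
}

# Draw one M per requested arrival/step from the spec's m field.
draw_m <- function(m, k) {
  if (length(m) == 1L) rep.int(m, k) else
    m[1L] + sample.int(m[2L] - m[1L] + 1L, k, replace = TRUE) - 1L
}

new_grown_graph <- function(n, from, to, step, m_of, model, spec,
                            n_steps = n) {
  structure(
    list(n = n,
         n_steps = as.integer(n_steps),
         edges = tibble::tibble(from = as.integer(from), to = as.integer(to),
                                step = as.integer(step)),
         m_of = as.integer(m_of),
         model = model,
         spec = spec),
    class = "grown_graph"
  )
}

#' @export
print.grown_graph <- function(x, ...) {
  cat(sprintf("<grown_graph> %s: %d nodes, %d edges (multigraph, arrival labels 1..n)\n",
              x$model, x$n, nrow(x$edges)))
  invisible(x)
}

# Core attachment simulator shared by PA and UA.  The "stub list" holds one
# entry per edge endpoint, so a uniform draw from it is a degree-proportional
# draw; all m targets of a step are sampled before the step's stubs are
# appended, i.e. against degrees frozen at time t-1.
simulate_attachment <- function(spec, preferential) {
  n <- spec$n
  ms <- draw_m(spec$m, n)
  total_edges <- sum(ms)
  from <- integer(total_edges)
  to <- integer(total_edges)
  step <- integer(total_edges)
  stubs <- integer(2L * total_edges)
  # seed node: m self-loops, each contributing 2 to its degree
  m1 <- ms[1L]
  from[seq_len(m1)] <- 1L
  to[seq_len(m1)] <- 1L
  step[seq_len(m1)] <- 1L
  stubs[seq_len(2L * m1)] <- 1L
  ne <- m1
  ns <- 2L * m1
  for (t in seq_len(n)[-1L]) {
    mt <- ms[t]
    if (preferential) {
      targets <- stubs[sample.int(ns, mt, replace = TRUE)]
    } else {
      targets <- sample.int(t - 1L, mt, replace = TRUE)
    }
    idx <- ne + seq_len(mt)
    from[idx] <- t
    to[idx] <- targets
    step[idx] <- t
    stubs[ns + seq_len(2L * mt)] <- c(targets, rep.int(t, mt))
    ne <- ne + mt
    ns <- ns + 2L * mt
  }
  new_grown_graph(n, from, to, step, ms,
                  model = if (preferential) "pa" else "ua", spec = spec)
}

#' Simulate a preferential-attachment graph
#'
#' At `t = 1` a single node is created with `m` self-loops (each contributing
#' 2 to its degree).  Each subsequent node `t` makes `m` independent
#' connections to existing nodes, choosing node `k` with probability
#' `deg_{t-1}(k) / (2 * E_{t-1})` where `E_{t-1}` is the number of edges
#' already present (`= m (t-1)` for fixed m).  Parallel edges are allowed and
#' all `m` draws of one step see the degrees frozen at `t - 1`.
#'
#' @param spec A [model_spec()] with `model = "pa"`, or parameters passed via
#'   `...` to [model_spec()].
#' @param ... Used to build a spec when `spec` is missing (e.g.
#'   `simulate_pa(n = 100, m = 3)`).
#' @param seed Optional seed; defaults to the spec's seed.
#' @return A `grown_graph`: node count `n`, an edge tibble with columns
#'   `from`, `to`, `step`, and `m_of`, the per-node number of connections made
#'   at arrival.
#' @examples
#' g <- simulate_pa(n = 50, m = 2, seed = 1)
#' nrow(g$edges)  # m * n
#' @export
simulate_pa <- function(spec = NULL, ..., seed = NULL) {
  if (is.null(spec)) spec <- model_spec("pa", ...)
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model != "pa") stop("invalid spec: model must be 'pa'", call. = FALSE)
  with_seed_(seed %||% spec$seed, simulate_attachment(spec, preferential = TRUE))
}

#' Simulate a uniform-attachment graph
#'
#' Identical to [simulate_pa()] (including the `m` self-loops at the seed
#' node) except that each target is chosen uniformly at random among the
#' `t - 1` existing nodes.
#'
#' @inheritParams simulate_pa
#' @return A `grown_graph`.
#' @examples
#' g <- simulate_ua(n = 50, m = 2, seed = 1)
#' @export
simulate_ua <- function(spec = NULL, ..., seed = NULL) {
  if (is.null(spec)) spec <- model_spec("ua", ...)
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model != "ua") stop("invalid spec: model must be 'ua'", call. = FALSE)
  with_seed_(seed %||% spec$seed, simulate_attachment(spec, preferential = FALSE))
}

#' Simulate a Cooper-Frieze web-graph
#'
#' The process starts from a single node carrying `M ~ unif{a, b}` self-loops.
#' Each subsequent step either adds a new node with probability
#' `cf_new_node_prob` (the node makes `M` connections to existing nodes) or,
#' otherwise, adds `M` edges between existing nodes.  Every edge endpoint that
#' is not the arriving node is chosen preferentially (degree-proportional)
#' with probability `cf_pref_prob` and uniformly otherwise, each endpoint
#' flipping its own coin.  Degrees are frozen during a step.  Arrival indices
#' increase only on node-addition steps; the simulation runs until `n` nodes
#' exist.
#'
#' @inheritParams simulate_pa
#' @return A `grown_graph`; `step` in the edge tibble is the arrival index of
#'   the newest node present when the edge was created.
#' @examples
#' g <- simulate_cooper_frieze(n = 100, m = c(5, 50), seed = 1)
#' @export
simulate_cooper_frieze <- function(spec = NULL, ..., seed = NULL) {
  if (is.null(spec)) spec <- model_spec("cooper_frieze", ...)
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model != "cooper_frieze") {
    stop("invalid spec: model must be 'cooper_frieze'", call. = FALSE)
  }
  with_seed_(seed %||% spec$seed, simulate_cf_impl(spec))
}

simulate_cf_impl <- function(spec) {
  n <- spec$n
  grow <- function(vec, need, len) {
    while (need > len) { len <- max(2L * len, need); length(vec) <- len }
    vec
  }
  cap <- 4L * n * max(spec$m)
  from <- integer(cap); to <- integer(cap); step <- integer(cap)
  stubs <- integer(2L * cap)
  m_of <- integer(n)
  # step 1 always creates the first node (an edges-only step on an empty
  # graph would be invalid)
  m1 <- draw_m(spec$m, 1L)
  m_of[1L] <- m1
  from[seq_len(m1)] <- 1L; to[seq_len(m1)] <- 1L; step[seq_len(m1)] <- 1L
  stubs[seq_len(2L * m1)] <- 1L
  ne <- m1; ns <- 2L * m1; nn <- 1L; n_steps <- 1L
  pick_endpoints <- function(k) {
    pref <- runif(k) < spec$cf_pref_prob
    out <- integer(k)
    if (any(pref)) out[pref] <- stubs[sample.int(ns, sum(pref), replace = TRUE)]
    if (any(!pref)) out[!pref] <- sample.int(nn, sum(!pref), replace = TRUE)
    out
  }
  while (nn < n) {
    n_steps <- n_steps + 1L
    mt <- draw_m(spec$m, 1L)
    if (runif(1L) < spec$cf_new_node_prob) {
      nn <- nn + 1L
      m_of[nn] <- mt
      targets <- pick_endpoints(mt)
      a <- rep.int(nn, mt); b <- targets
    } else {
      a <- pick_endpoints(mt)
      b <- pick_endpoints(mt)
    }
    from <- grow(from, ne + mt, length(from))
    to <- grow(to, ne + mt, length(to))
    step <- grow(step, ne + mt, length(step))
    stubs <- grow(stubs, ns + 2L * mt, length(stubs))
    idx <- ne + seq_len(mt)
    from[idx] <- a; to[idx] <- b; step[idx] <- nn
    stubs[ns + seq_len(2L * mt)] <- c(a, b)
    ne <- ne + mt; ns <- ns + 2L * mt
  }
  new_grown_graph(n, from[seq_len(ne)], to[seq_len(ne)], step[seq_len(ne)],
                  m_of, model = "cooper_frieze", spec = spec,
                  n_steps = n_steps)
}

#' Simulate from a model spec
#'
#' Dispatches to [simulate_pa()], [simulate_ua()] or
#' [simulate_cooper_frieze()] according to `spec$model`.
#'
#' @inheritParams simulate_pa
#' @return A `grown_graph`.
#' @export
simulate_model <- function(spec, seed = NULL) {
  switch(spec$model,
         pa = simulate_pa(spec, seed = seed),
         ua = simulate_ua(spec, seed = seed),
         cooper_frieze = simulate_cooper_frieze(spec, seed = seed))
}

new_snapshot <- function(n, u, v, arrival = NULL, labels = NULL) {
  structure(
    list(n = as.integer(n),
         edges = tibble::tibble(u = as.integer(u), v = as.integer(v)),
         arrival = if (!is.null(arrival)) as.integer(arrival) else NULL,
         labels = labels %||% as.character(seq_len(n))),
    class = "snapshot"
  )
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("<snapshot> %d nodes, %d edges%s\n", x$n, nrow(x$edges),
              if (is.null(x$arrival)) "" else " (ground-truth arrival order attached)"))
  invisible(x)
}

#' Obfuscate a grown graph into an observed snapshot
#'
#' Relabels the nodes of a grown graph by a permutation drawn uniformly at
#' random, producing the snapshot an archaeology estimator actually observes.
#' The hidden inverse permutation (the true arrival index of each observed
#' label) is stored for evaluation.
#'
#' @param g A `grown_graph`.
#' @param seed Optional seed for the permutation draw.
#' @return A `snapshot` with fields `n`, `edges` (tibble `u`, `v`) and
#'   `arrival`, where `arrival[u]` is the true arrival index of observed node
#'   `u`.
#' @examples
#' h <- simulate_pa(n = 20, m = 2, seed = 1) |> permute_snapshot(seed = 2)
#' sort(h$arrival)  # a bijection 1..n
#' @export
permute_snapshot <- function(g, seed = NULL) {
  stopifnot(inherits(g, "grown_graph"))
  with_seed_(seed, {
    perm <- sample.int(g$n)         # perm[v] = observed label of arrival v
    arrival <- integer(g$n)
    arrival[perm] <- seq_len(g$n)   # arrival[u] = true index of label u
    new_snapshot(g$n, perm[g$edges$from], perm[g$edges$to], arrival = arrival)
  })
}

#' Convert a grown graph to an unpermuted snapshot
#'
#' Keeps the arrival labels as observed labels (identity relabeling); useful
#' for algorithms that only need the graph structure.
#'
#' @param g A `grown_graph`.
#' @return A `snapshot` whose `arrival` is the identity.
#' @export
as_snapshot <- function(g) {
  stopifnot(inherits(g, "grown_graph"))
  new_snapshot(g$n, g$edges$from, g$edges$to, arrival = seq_len(g$n))
}

#' Degrees of a snapshot or grown graph
#'
#' Self-loops contribute 2 to the degree of their node.
#'
#' @param x A `snapshot` or `grown_graph`.
#' @return Integer vector of length `n`.
#' @export
node_degrees <- function(x) {
  if (inherits(x, "grown_graph")) {
    tabulate(c(x$edges$from, x$edges$to), x$n)
  } else if (inherits(x, "snapshot")) {
    tabulate(c(x$edges$u, x$edges$v), x$n)
  } else {
    stop("`x` must be a snapshot or grown_graph", call. = FALSE)
  }
}

#' True age-oriented DAG of a grown graph
#'
#' Orients every non-loop edge from its younger endpoint (higher arrival
#' index) to its older endpoint.  Since arrival labels are a total order the
#' result is acyclic by construction.  Self-loops carry no order information
#' and are dropped.
#'
#' @param g A `grown_graph`.
#' @return A `recovered_dag` (without peel levels) whose arcs run
#'   younger -> older.
#' @export
true_dag <- function(g) {
  stopifnot(inherits(g, "grown_graph"))
  e <- g$edges
  keep <- e$from != e$to
  younger <- pmax(e$from[keep], e$to[keep])
  older <- pmin(e$from[keep], e$to[keep])
  new_recovered_dag(g$n, younger, older, level = NULL,
                    dropped_same_bin = 0L, source = "true")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
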