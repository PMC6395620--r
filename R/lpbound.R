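#' Build the precision/density LP relaxation
#'
#' Materializes the fractional program whose optimum upper-bounds the best
#' achievable expected precision at density floor `eps`: maximize
#' `sum(p_uv x_uv) / sum(x_uv)` over ordered pairs subject to antisymmetry
#' (`x_uv + x_vu <= 1`), transitivity (`x_uw >= x_uv + x_vw - 1` for all
#' ordered triples of distinct nodes), the minimum-density row
#' (`sum(x_uv) >= eps * choose(n, 2)`), and `x_uv` in `[0, 1]`.  The
#' objective includes both orientations of every pair with their reciprocal
#' coefficients `p_vu = 1 - p_uv`.
#'
#' @param probs A `pair_probs` object covering all pairs (from
#'   [exact_pair_probs()] or [mcmc_pair_probs()]) or a full reciprocal
#'   `n x n` matrix.
#' @param n Number of nodes (inferred from `probs` when possible).
#' @param eps Density floor in `[0, 1]`.
#' @return An object of class `lp_instance` with the coefficient matrix and
#'   constraint-family row counts.
#' @examples
#' P <- matrix(0.5, 3, 3); diag(P) <- 0
#' build_lp(P, eps = 0.5)
#' @export
build_lp <- function(probs, n = NULL, eps) {
  if (inherits(probs, "pair_probs")) {
    p <- pair_prob_matrix(probs)
  } else if (is.matrix(probs)) {
    p <- probs
  } else {
    stop("`probs` must be a pair_probs object or matrix", call. = FALSE)
  }
  n <- n %||% nrow(p)
  if (nrow(p) != n || ncol(p) != n) stop("probability matrix must be n x n",
                                         call. = FALSE)
  if (anyNA(p)) stop("missing pair probability", call. = FALSE)
  offd <- abs(p + t(p) - 1)
  diag(offd) <- 0
  if (max(offd) > 1e-6) {
    stop("pair probabilities must satisfy p[u,v] + p[v,u] = 1", call. = FALSE)
  }
  if (eps < 0 || eps > 1) stop("eps must lie in [0, 1]", call. = FALSE)
  structure(
    list(n = as.integer(n), p = p, eps = eps,
         n_vars = n * (n - 1L),
         n_antisymmetry = choose(n, 2),
         n_transitivity = n * (n - 1L) * (n - 2L),
         n_density = 1L),
    class = "lp_instance"
  )
}

#' @export
print.lp_instance <- function(x, ...) {
  cat(sprintf(
    "<lp_instance> n = %d, eps = %g: %d variables, %d antisymmetry + %d transitivity + %d density rows\n",
    x$n, x$eps, x$n_vars, x$n_antisymmetry, x$n_transitivity, x$n_density))
  invisible(x)
}

find_python <- function() {
  cand <- getOption("netarch.python")
  if (!is.null(cand) && nzchar(cand)) return(cand)
  for (nm in c("python", "python3")) {
    p <- Sys.which(nm)
    if (nzchar(p)) return(unname(p))
  }
  NULL
}

solve_lp_highs <- function(p, eps_vec, transitivity = "cutting",
                           want_x = FALSE, tol = 1e-6, max_rounds = 40L) {
  python <- find_python()
  if (is.null(python)) {
    stop("no python interpreter found for the HiGHS backend; set options(netarch.python = ...) or use backend = 'simplex'",
         call. = FALSE)
  }
  script <- system.file("python", "lp_bound_solve.py", package = "netarch",
                        mustWork = TRUE)
  inp <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, out)), add = TRUE)
  jsonlite::write_json(
    list(n = nrow(p), p = p, eps = I(eps_vec), transitivity = transitivity,
         tol = tol, max_rounds = max_rounds, want_x = want_x),
    inp, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  status <- system2(python, c(shQuote(script), shQuote(inp), shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) || !file.exists(out)) {
    stop("LP backend failed:\n", paste(status, collapse = "\n"), call. = FALSE)
  }
  res <- jsonlite::read_json(out, simplifyVector = TRUE)
  if (!identical(res$status, "ok")) {
    stop("LP solver reported ", res$status, call. = FALSE)
  }
  res
}

solve_lp_simplex <- function(p, eps, want_x = FALSE) {
  if (!requireNamespace("boot", quietly = TRUE)) {
    stop("the pure-R backend needs the 'boot' package", call. = FALSE)
  }
  n <- nrow(p)
  if (n > 12L) {
    stop("pure-R simplex backend is dense; use the HiGHS backend for n > 12",
         call. = FALSE)
  }
  id <- matrix(NA_integer_, n, n)
  off <- which(row(id) != col(id))
  id[off] <- seq_along(off)
  nv <- length(off) + 1L
  t_col <- nv
  npairs <- choose(n, 2)
  obj <- c(p[off], 0)
  rows <- list()
  # antisymmetry (and implied y <= t)
  for (u in seq_len(n - 1L)) {
    for (v in seq.int(u + 1L, n)) {
      r <- numeric(nv)
      r[id[u, v]] <- 1; r[id[v, u]] <- 1; r[t_col] <- -1
      rows[[length(rows) + 1L]] <- r
    }
  }
  # full transitivity
  for (u in seq_len(n)) for (v in seq_len(n)) for (w in seq_len(n)) {
    if (u == v || v == w || u == w) next
    r <- numeric(nv)
    r[id[u, v]] <- 1; r[id[v, w]] <- 1; r[id[u, w]] <- -1; r[t_col] <- -1
    rows[[length(rows) + 1L]] <- r
  }
  # cap on t (keeps the epsilon = 0 corner bounded; harmless, see vignette)
  r <- numeric(nv); r[t_col] <- 1
  rows[[length(rows) + 1L]] <- r
  A1 <- do.call(rbind, rows)
  b1 <- c(rep(0, length(rows) - 1L), 4 * max(npairs, 1))
  # density: sum(y) - eps*npairs*t >= 0
  A2 <- matrix(0, 1L, nv)
  A2[1L, seq_along(off)] <- 1
  A2[1L, t_col] <- -eps * npairs
  # normalization sum(y) = 1
  A3 <- matrix(0, 1L, nv)
  A3[1L, seq_along(off)] <- 1
  sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = 0,
                       A3 = A3, b3 = 1, maxi = TRUE,
                       n.iter = 50L * (nv + nrow(A1)))
  if (sol$solved < 0) stop("simplex backend: infeasible LP", call. = FALSE)
  soln <- unname(sol$soln)
  tval <- soln[t_col]
  x <- matrix(0, n, n)
  if (want_x && tval > 0) x[off] <- soln[seq_along(off)] / tval
  list(bounds = unname(sol$value), t = tval, x = if (want_x) list(as.vector(t(x))),
       rounds = 1L)
}

#' Solve the LP relaxation for one density floor
#'
#' Applies the Charnes-Cooper substitution `y = t x`, `sum(y) = 1` to the
#' fractional objective of [build_lp()] and solves the resulting LP.  The
#' default backend is HiGHS through the system Python's scipy, with
#' transitivity rows added as cutting planes; a dense pure-R simplex backend
#' (`boot::simplex`, full transitivity) is available for small instances and
#' cross-checks.
#'
#' @param inst An `lp_instance` from [build_lp()].
#' @param backend `"auto"`, `"highs"` or `"simplex"`.
#' @param transitivity `"cutting"` or `"full"` (HiGHS backend only).
#' @param want_x Also return the optimizing fractional `x` matrix.
#' @param tol Cutting-plane violation tolerance.
#' @return List with `value` (the bound, in `[0, 1]` up to solver tolerance),
#'   `x` (matrix or `NULL`), `t`, `backend` and `rounds`.
#' @examples
#' P <- matrix(0.5, 3, 3); diag(P) <- 0
#' solve_bound(build_lp(P, eps = 0.5), backend = "simplex")$value  # 0.5
#' @export
solve_bound <- function(inst, backend = c("auto", "highs", "simplex"),
                        transitivity = c("cutting", "full"),
                        want_x = TRUE, tol = 1e-6) {
  stopifnot(inherits(inst, "lp_instance"))
  backend <- match.arg(backend)
  transitivity <- match.arg(transitivity)
  if (backend == "auto") {
    backend <- if (inst$n <= 8L || is.null(find_python())) "simplex" else "highs"
    if (backend == "simplex" && inst$n > 12L) backend <- "highs"
  }
  if (backend == "highs") {
    res <- solve_lp_highs(inst$p, inst$eps, transitivity = transitivity,
                          want_x = want_x, tol = tol)
    x <- if (want_x) matrix(res$x[1L, ], inst$n, inst$n, byrow = TRUE)
    list(value = res$bounds[1L], x = x, t = res$t[1L], backend = "highs",
         rounds = res$rounds[1L])
  } else {
    res <- solve_lp_simplex(inst$p, inst$eps, want_x = want_x)
    x <- if (want_x) matrix(res$x[[1L]], inst$n, inst$n, byrow = TRUE)
    list(value = res$bounds, x = x, t = res$t, backend = "simplex",
         rounds = res$rounds)
  }
}

#' Upper bound on the optimal precision curve of a snapshot
#'
#' Recovers the snapshot's DAG by peeling, estimates the posterior pair-order
#' probabilities, and solves the LP relaxation at each density floor of
#' `eps_grid`.  The resulting curve is non-increasing in the floor and upper
#' bounds the (density, precision) point of every partial-order estimator on
#' this snapshot.
#'
#' @param h A `snapshot`.
#' @param eps_grid Density floors (default `seq(0.1, 1, by = 0.1)`).
#' @param pairprob_method `"mcmc"` (default) or `"exact"` (small n only).
#' @param k_steps Walk length for the MCMC estimate.
#' @param seed Optional seed (drives the MCMC walk).
#' @param max_n Refuse snapshots larger than this (the LP has ~n^3
#'   constraints; default 60).
#' @param backend,transitivity Passed to [solve_bound()]; the default single
#'   HiGHS call shares cutting planes across the whole grid.
#' @return A `bound_curve` tibble with columns `eps` and `bound`; attributes
#'   keep the DAG, the probability matrix and the fractional solutions.
#' @examples
#' \donttest{
#' h <- simulate_pa(n = 20, m = 2, seed = 1) |> permute_snapshot(seed = 2)
#' bound_curve(h, eps_grid = c(0.2, 0.8), k_steps = 2e4, seed = 3)
#' }
#' @export
bound_curve <- function(h, eps_grid = seq(0.1, 1, by = 0.1),
                        pairprob_method = c("mcmc", "exact"), k_steps = 1e5,
                        seed = NULL, max_n = 60L,
                        backend = c("highs", "simplex"),
                        transitivity = c("cutting", "full")) {
  stopifnot(inherits(h, "snapshot"))
  pairprob_method <- match.arg(pairprob_method)
  backend <- match.arg(backend)
  transitivity <- match.arg(transitivity)
  if (h$n > max_n) {
    stop(sprintf("n = %d too large for the LP bound (cap %d)", h$n, max_n),
         call. = FALSE)
  }
  dag <- peel(h)
  pp <- if (pairprob_method == "exact") exact_pair_probs(dag) else
    mcmc_pair_probs(dag, k_steps = k_steps, seed = seed, h = h)
  p <- pair_prob_matrix(pp)
  eps_grid <- sort(eps_grid)
  if (backend == "highs") {
    res <- solve_lp_highs(p, eps_grid, transitivity = transitivity,
                          want_x = TRUE)
    bounds <- res$bounds
    xs <- lapply(seq_along(eps_grid), function(i)
      matrix(res$x[i, ], h$n, h$n, byrow = TRUE))
  } else {
    sols <- lapply(eps_grid, function(e)
      solve_bound(build_lp(p, eps = e), backend = "simplex"))
    bounds <- vapply(sols, `[[`, numeric(1L), "value")
    xs <- lapply(sols, `[[`, "x")
  }
  out <- tibble::tibble(eps = eps_grid, bound = bounds)
  structure(out, class = c("bound_curve", class(out)),
            dag = dag, probs = p, x = xs, method = pairprob_method,
            k_steps = if (pairprob_method == "mcmc") k_steps else NA_real_)
}

#' Precision/density points of the three estimators on one snapshot
#'
#' Convenience companion to [bound_curve()]: scores the perfect-precision,
#' Peeling and Peeling+ orders on a snapshot with known ground truth.
#'
#' @param h A `snapshot` with `arrival` attached.
#' @return Tibble with columns `estimator`, `density`, `precision`, `recall`.
#' @export
snapshot_estimator_points <- function(h) {
  stopifnot(inherits(h, "snapshot"))
  if (is.null(h$arrival)) stop("snapshot has no ground truth", call. = FALSE)
  dag <- peel(h)
  orders <- list(perfect = perfect_precision_order(dag),
                 peel = peeling_order(dag),
                 `peel+` = peeling_plus_order(h, dag))
  purrr::imap_dfr(orders, function(o, nm) {
    s <- score_order(o, h$arrival)
    tibble::tibble(estimator = nm, density = s$density,
                   precision = s$precision, recall = s$recall)
  })
}

#' Evaluate the integer objective of a partial order under LP coefficients
#'
#' Computes `sum(p_uv) / K` over the order's comparable pairs - the value the
#' LP relaxation must dominate whenever the order meets the density floor.
#'
#' @param order A `partial_order`.
#' @param p Full reciprocal probability matrix.
#' @return A single number (or `NaN` for an empty order).
#' @export
integer_objective <- function(order, p) {
  pr <- tidy(order)
  if (nrow(pr) == 0L) return(NaN)
  sum(p[cbind(pr$before, pr$after)]) / nrow(pr)
}
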