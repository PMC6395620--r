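# Fenwick-tree count of #{i < j : x[i] > x[j]} for a positive-integer
# sequence x (values 1..L).  O(n log L); used to score bin orders without
# materializing ~n^2/2 comparable pairs.
count_pairs_earlier_greater <- function(x) {
  L <- max(x)
  tree <- integer(L)
  inv <- 0
  seen <- 0L
  for (val in x) {
    i <- val
    s <- 0L
    while (i > 0L) {
      s <- s + tree[i]
      i <- i - bitwAnd(i, -i)
    }
    inv <- inv + (seen - s)       # seen values strictly greater than val
    i <- val
    while (i <= L) {
      tree[i] <- tree[i] + 1L
      i <- i + bitwAnd(i, -i)
    }
    seen <- seen + 1L
  }
  inv
}

# #{i < j : x[i] < x[j]} with strict inequality for arbitrary numeric x
# (no NAs): complement of ties and inversions.
count_pairs_earlier_smaller <- function(x) {
  k <- length(x)
  if (k < 2L) return(0)
  d <- match(x, sort(unique(x)))
  ties <- sum(choose(tabulate(d), 2))
  choose(k, 2) - ties - count_pairs_earlier_greater(d)
}

#' Score a partial order against the true arrival order
#'
#' A comparable pair "u before v" is correct iff `arrival[u] < arrival[v]`.
#' Returns the three ratios of the archaeology problem: density
#' `K / choose(n, 2)`, precision `correct / K`, and recall
#' `correct / choose(n, 2)`; `recall = precision * density` whenever `K > 0`.
#' Bin-based orders are scored by pair counting (no materialization), so
#' snapshots with thousands of nodes score in milliseconds.
#'
#' @param order A `partial_order`.
#' @param arrival Integer vector, `arrival[u]` = true arrival index of node
#'   `u`; must be a bijection onto `1..n` (e.g. the `arrival` field of a
#'   permuted snapshot).
#' @return A one-row tibble with columns `n`, `K`, `n_correct`, `density`,
#'   `precision`, `recall`.  If `K = 0` precision is `NaN` with a warning.
#' @examples
#' h <- simulate_pa(n = 40, m = 2, seed = 1) |> permute_snapshot(seed = 2)
#' score_order(peeling_order(peel(h)), h$arrival)
#' @export
score_order <- function(order, arrival) {
  stopifnot(inherits(order, "partial_order"))
  n <- order$n
  arrival <- as.integer(arrival)
  if (length(arrival) != n || !setequal(arrival, seq_len(n))) {
    stop("`arrival` must be a bijection onto 1..n", call. = FALSE)
  }
  npairs <- choose(n, 2)
  K <- order$K
  correct <-
    if (order$kind == "pairs") {
      b <- order$before
      sum(arrival[b$u] < arrival[b$v])
    } else {
      ord <- base::order(arrival)                 # oldest node first
      lv <- order$level[ord]
      cross <- count_pairs_earlier_greater(lv)    # older node in older bin
      within <- 0
      if (order$kind == "bins_anl") {
        for (b in unique(lv)) {
          members <- ord[lv == b]
          a <- order$anl[members]                 # already in arrival order
          a <- a[!is.na(a)]
          within <- within + count_pairs_earlier_smaller(a)
        }
      }
      cross + within
    }
  if (K == 0) {
    warning("order has no comparable pairs; precision undefined", call. = FALSE)
    precision <- NaN
  } else {
    precision <- correct / K
  }
  tibble::tibble(n = n, K = K, n_correct = as.numeric(correct),
                 density = K / npairs,
                 precision = precision,
                 recall = correct / npairs)
}

#' Total or tied ranking as a partial order
#'
#' Converts a guessed age ranking into a `partial_order`: "u before v" iff
#' `rank[u] < rank[v]` (smaller rank = older); tied ranks are incomparable.
#' Useful for baselines such as a uniformly random total order.
#'
#' @param rank Numeric vector of guessed arrival ranks, one per node.
#' @return A `partial_order` of kind `"bins"`.
#' @export
ranking_order <- function(rank) {
  stopifnot(is.numeric(rank), length(rank) >= 1L)
  d <- match(rank, sort(unique(rank)))
  level <- max(d) + 1L - d                        # older = higher level
  sizes <- tabulate(level)
  K <- (sum(as.numeric(sizes))^2 - sum(as.numeric(sizes)^2)) / 2
  new_partial_order(length(rank), "bins", level = level, K = K)
}

resolve_estimator <- function(estimator) {
  if (is.function(estimator)) return(estimator)
  switch(match.arg(estimator, c("peel", "peel+", "perfect")),
         peel = function(h, dag) peeling_order(dag),
         `peel+` = function(h, dag) peeling_plus_order(h, dag),
         perfect = function(h, dag) perfect_precision_order(dag))
}

#' Monte-Carlo estimate of an estimator's expected scores
#'
#' Repeats simulate -> permute -> peel -> estimate -> score and reports the
#' mean and standard error of precision, recall and density over replicates.
#' The density reported is the per-replicate mean.
#'
#' @param spec A [model_spec()].
#' @param estimator `"peel"`, `"peel+"`, `"perfect"`, or a function
#'   `(h, dag) -> partial_order`.
#' @param reps Number of replicate simulations (default 10).
#' @param seed Optional seed for the whole experiment (one RNG stream).
#' @return An object of class `estimator_score` holding the per-replicate
#'   tibble (`$scores`) and a summary; see [glance.estimator_score()].
#' @examples
#' \donttest{
#' es <- estimate_estimator_score(model_spec("pa", n = 300, m = 3),
#'                                "peel", reps = 3, seed = 1)
#' glance(es)
#' }
#' @export
estimate_estimator_score <- function(spec, estimator = "peel", reps = 10,
                                     seed = NULL) {
  stopifnot(inherits(spec, "model_spec"), reps >= 1)
  fn <- resolve_estimator(estimator)
  est_name <- if (is.function(estimator)) "custom" else estimator
  scores <- with_seed_(seed, {
    purrr::map(seq_len(reps), function(r) {
      tryCatch({
        g <- simulate_model(spec)
        h <- permute_snapshot(g)
        dag <- peel(h)
        s <- score_order(fn(h, dag), h$arrival)
        s$rep <- r
        s
      }, error = function(e) {
        warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    })
  })
  ok <- !vapply(scores, is.null, logical(1L))
  if (mean(ok) < 0.9) {
    stop(sprintf("estimator failed on %d of %d replicates", sum(!ok), reps),
         call. = FALSE)
  }
  scores <- dplyr::bind_rows(scores[ok])
  structure(
    list(scores = tibble::as_tibble(scores), spec = spec,
         estimator = est_name, reps = reps, seed = seed),
    class = "estimator_score"
  )
}

#' @export
tidy.estimator_score <- function(x, ...) x$scores

#' Summarize a Monte-Carlo estimator experiment
#'
#' @param x An `estimator_score` from [estimate_estimator_score()].
#' @param ... Unused.
#' @return One-row tibble with means and standard errors of precision
#'   (theta), recall (rho) and density (delta).
#' @export
glance.estimator_score <- function(x, ...) {
  s <- x$scores
  se <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  tibble::tibble(
    model = x$spec$model, estimator = x$estimator, n = x$spec$n,
    reps = nrow(s),
    theta = mean(s$precision), theta_se = se(s$precision),
    rho = mean(s$recall), rho_se = se(s$recall),
    delta = mean(s$density), delta_se = se(s$density))
}

#' @export
print.estimator_score <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<estimator_score> %s on %s(n = %d), %d replicates\n  theta = %.4f (se %.4f), rho = %.4f (se %.4f), delta = %.4f (se %.4f)\n",
    x$estimator, x$spec$model, x$spec$n, g$reps,
    g$theta, g$theta_se, g$rho, g$rho_se, g$delta, g$delta_se))
  invisible(x)
}
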