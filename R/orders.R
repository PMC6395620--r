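new_partial_order <- function(n, kind, level = NULL, anl = NULL,
                              before = NULL, K, labels = NULL,
                              raw_arc_pairs = NA_integer_) {
  structure(
    list(n = as.integer(n), kind = kind,
         level = if (!is.null(level)) as.integer(level) else NULL,
         anl = anl,
         before = before,
         K = as.numeric(K),
         raw_arc_pairs = raw_arc_pairs,
         labels = labels %||% as.character(seq_len(n))),
    class = "partial_order"
  )
}

#' @export
print.partial_order <- function(x, ...) {
  cat(sprintf("<partial_order> (%s) on %d nodes: K = %s comparable pairs, density = %.4g\n",
              x$kind, x$n, format(x$K, big.mark = ","), order_density(x)))
  invisible(x)
}

#' Density of a partial order
#'
#' Number of comparable pairs `K` divided by `choose(n, 2)`.
#'
#' @param order A `partial_order`.
#' @return A number in `[0, 1]`.
#' @export
order_density <- function(order) {
  stopifnot(inherits(order, "partial_order"))
  if (order$n < 2L) return(0)
  order$K / choose(order$n, 2)
}

#' @export
glance.partial_order <- function(x, ...) {
  tibble::tibble(n = x$n, kind = x$kind, K = x$K, density = order_density(x))
}

#' Comparable pairs of a partial order as a tibble
#'
#' Materializes the relation as ordered pairs `(before, after)` meaning
#' "`before` arrived earlier than `after`".  Refuses above `max_pairs` since
#' bin-based orders on large graphs can hold ~n^2/2 pairs.
#'
#' @param x A `partial_order`.
#' @param max_pairs Materialization cap (default `1e7`).
#' @param ... Unused.
#' @return A tibble with integer columns `before` and `after`.
#' @export
tidy.partial_order <- function(x, max_pairs = 1e7, ...) {
  if (x$K > max_pairs) {
    stop(sprintf("order has %.3g comparable pairs; raise `max_pairs` to materialize",
                 x$K), call. = FALSE)
  }
  if (x$kind == "pairs") {
    return(tibble::tibble(before = x$before$u, after = x$before$v))
  }
  lv <- x$level
  idx <- order(lv, decreasing = TRUE)            # oldest bins first
  n <- x$n
  b <- integer(0); a <- integer(0)
  # cross-bin pairs: each node is "before" every node in a strictly lower bin
  for (v in seq_len(n)) {
    later <- which(lv < lv[v])
    if (x$kind == "bins_anl") {
      same <- which(lv == lv[v] & !is.na(x$anl) & !is.na(x$anl[v]) &
                      x$anl > x$anl[v])
      later <- c(later, same)
    }
    if (length(later)) {
      b <- c(b, rep.int(v, length(later))); a <- c(a, later)
    }
  }
  tibble::tibble(before = b, after = a)
}

#' Perfect-precision (maximum-density precision-1) order
#'
#' Declares "u before v" whenever u is reachable from v along the DAG's
#' younger -> older arcs, i.e. the transitive closure of arc reversal.  On a
#' fixed-m preferential-attachment snapshot every such pair is correct with
#' probability one, so the order has precision exactly 1.  The raw arc count
#' (comparable pairs counted without closure) is kept as a diagnostic in
#' `raw_arc_pairs`.
#'
#' @param dag A `recovered_dag` (must be acyclic).
#' @return A `partial_order` of kind `"pairs"`.
#' @examples
#' h <- simulate_pa(n = 25, m = 2, seed = 1) |> permute_snapshot(seed = 2)
#' perfect_precision_order(peel(h))
#' @export
perfect_precision_order <- function(dag) {
  stopifnot(inherits(dag, "recovered_dag"))
  if (nrow(dag$arcs) > 0L) {
    g <- igraph::graph_from_edgelist(cbind(dag$arcs$younger, dag$arcs$older),
                                     directed = TRUE)
    if (!igraph::is_dag(g)) stop("cycle detected in recovered DAG", call. = FALSE)
  }
  reach <- dag_reachability(dag)
  idx <- which(reach, arr.ind = TRUE)     # [v, u]: u older, reachable from v
  before <- tibble::tibble(u = as.integer(idx[, 2L]), v = as.integer(idx[, 1L]))
  raw <- nrow(unique(dag$arcs[c("younger", "older")]))
  new_partial_order(dag$n, "pairs", before = before, K = nrow(before),
                    labels = dag$labels, raw_arc_pairs = raw)
}

#' Peeling (bin) order
#'
#' Bins removed earlier contain younger nodes: "u before v" iff
#' `level(u) > level(v)`.  Pairs inside one bin are incomparable, so
#' `K = sum_{i<j} |bin_i| |bin_j|`.
#'
#' @param dag A `recovered_dag` with peel levels.
#' @return A `partial_order` of kind `"bins"`.
#' @export
peeling_order <- function(dag) {
  stopifnot(inherits(dag, "recovered_dag"))
  if (is.null(dag$level)) stop("peel levels required", call. = FALSE)
  sizes <- tabulate(dag$level, dag$n_bins)
  K <- (sum(as.numeric(sizes))^2 - sum(as.numeric(sizes)^2)) / 2
  new_partial_order(dag$n, "bins", level = dag$level, K = K,
                    labels = dag$labels)
}

#' Peeling+ order: break within-bin ties by average neighbor level
#'
#' Keeps all cross-bin relations of [peeling_order()] and, inside each bin,
#' additionally orders nodes by their average neighbor level `anl(u)` (mean
#' peel level over the node's neighbor multiset in the snapshot, self-loops
#' excluded).  A high average neighbor level indicates youth, so within a bin
#' "u before v" iff `anl(u) < anl(v)`.  Exact ties, and nodes whose `anl` is
#' undefined (no non-loop neighbor), stay incomparable.
#'
#' @param h The `snapshot` the DAG was peeled from (provides the neighbor
#'   multisets).
#' @param dag The `recovered_dag` returned by [peel()] on `h`.
#' @return A `partial_order` of kind `"bins_anl"` with the `anl` vector
#'   attached.
#' @export
peeling_plus_order <- function(h, dag) {
  stopifnot(inherits(h, "snapshot"), inherits(dag, "recovered_dag"))
  if (is.null(dag$level)) stop("peel levels required", call. = FALSE)
  n <- h$n
  e <- h$edges
  keep <- e$u != e$v
  u <- e$u[keep]; v <- e$v[keep]
  lsum <- numeric(n)
  cnt <- integer(n)
  lv <- dag$level
  su <- tabulate(u, n); sv <- tabulate(v, n)
  cnt <- su + sv
  lsum <- as.numeric(
    rowsum_vec(c(u, v), c(lv[v], lv[u]), n))
  anl <- ifelse(cnt > 0L, lsum / cnt, NA_real_)
  base <- peeling_order(dag)
  # additional within-bin comparable pairs: per bin, pairs with distinct anl
  extra <- 0
  for (b in seq_len(dag$n_bins)) {
    members <- which(lv == b)
    if (length(members) < 2L) next
    a <- anl[members]
    a <- a[!is.na(a)]
    if (length(a) < 2L) next
    tie_counts <- table(a)
    extra <- extra + choose(length(a), 2) - sum(choose(tie_counts, 2))
  }
  new_partial_order(n, "bins_anl", level = lv, anl = anl,
                    K = base$K + extra, labels = dag$labels)
}

# sum of `w` grouped by integer index `idx` into a length-n vector
rowsum_vec <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Check the strict-partial-order axioms
#'
#' Validates irreflexivity, antisymmetry and transitivity of a
#' `partial_order`.  Bin-based orders satisfy the axioms by construction;
#' pair-based relations are checked explicitly (quadratic in `K`, intended
#' for tests and small instances).
#'
#' @param order A `partial_order`.
#' @return `TRUE` (invisibly) or an error describing the violated axiom.
#' @export
validate_partial_order <- function(order) {
  stopifnot(inherits(order, "partial_order"))
  if (order$kind != "pairs") return(invisible(TRUE))
  b <- order$before
  if (any(b$u == b$v)) stop("irreflexivity violated", call. = FALSE)
  key <- paste(b$u, b$v)
  rkey <- paste(b$v, b$u)
  if (anyDuplicated(key)) stop("duplicate pairs in relation", call. = FALSE)
  if (any(rkey %in% key)) stop("antisymmetry violated", call. = FALSE)
  # transitivity via boolean matrix product
  n <- order$n
  if (n > 2000L) stop("validate_partial_order: n too large", call. = FALSE)
  M <- matrix(FALSE, n, n)
  M[cbind(b$u, b$v)] <- TRUE
  M2 <- (M %*% M) > 0
  if (any(M2 & !M)) stop("transitivity violated", call. = FALSE)
  invisible(TRUE)
}
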