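new_recovered_dag <- function(n, younger, older, level, dropped_same_bin,
                              source = "peeling", labels = NULL) {
  structure(
    list(n = as.integer(n),
         arcs = tibble::tibble(younger = as.integer(younger),
                               older = as.integer(older)),
         level = if (!is.null(level)) as.integer(level) else NULL,
         n_bins = if (!is.null(level)) max(level) else NA_integer_,
         dropped_same_bin = as.integer(dropped_same_bin),
         source = source,
         labels = labels %||% as.character(seq_len(n))),
    class = "recovered_dag"
  )
}

#' @export
print.recovered_dag <- function(x, ...) {
  cat(sprintf("<recovered_dag> %d nodes, %d arcs (younger -> older)%s\n",
              x$n, nrow(x$arcs),
              if (is.null(x$level)) "" else
                sprintf(", %d peel bins, %d unoriented same-bin edges",
                        x$n_bins, x$dropped_same_bin)))
  invisible(x)
}

#' @export
tidy.recovered_dag <- function(x, ...) x$arcs

#' @export
glance.recovered_dag <- function(x, ...) {
  tibble::tibble(n = x$n, arcs = nrow(x$arcs), bins = x$n_bins,
                 dropped_same_bin = x$dropped_same_bin)
}

#' Peel a snapshot into its age-oriented DAG and bins
#'
#' Repeatedly collects all nodes at the current minimum degree into a bin,
#' orients each of their edges towards the still-remaining (hence older)
#' endpoint, and removes them, until the graph is empty.  The bin index
#' (`level`, 1 = removed first = youngest) and the oriented arc multiset are
#' returned.  Edges between two nodes removed in the same bin, and
#' self-loops, cannot be oriented and are dropped (counted in
#' `dropped_same_bin`).  For a fixed-m preferential-attachment snapshot every
#' round removes exactly the degree-m nodes and the recovered arcs equal the
#' relabeled true DAG.
#'
#' @param h A `snapshot`.
#' @param mode `"min_degree"` (default) peels all nodes at the current
#'   minimum degree each round and applies to any graph; `"fixed_m"`
#'   additionally asserts that the current minimum never drops below the
#'   snapshot's global minimum degree m, the fixed-m regime in which peeling
#'   is an exact recovery.
#' @return A `recovered_dag` with fields `arcs` (tibble `younger`, `older`,
#'   one row per multi-edge), `level` (integer per node) and
#'   `dropped_same_bin`.
#' @examples
#' h <- simulate_pa(n = 30, m = 2, seed = 1) |> permute_snapshot(seed = 2)
#' d <- peel(h)
#' d$n_bins
#' @export
peel <- function(h, mode = c("min_degree", "fixed_m")) {
  stopifnot(inherits(h, "snapshot"))
  mode <- match.arg(mode)
  n <- h$n
  if (n < 1L || (nrow(h$edges) == 0L && n == 0L)) {
    stop("cannot peel an empty graph", call. = FALSE)
  }
  eu <- h$edges$u
  ev <- h$edges$v
  ne <- length(eu)
  deg <- tabulate(c(eu, ev), n)
  m0 <- if (ne > 0L) min(deg) else 0L
  # incidence: node -> indices of incident edges (self-loops listed twice,
  # deduplicated on use)
  inc <- split(rep.int(seq_len(ne), 2L), factor(c(eu, ev), levels = seq_len(n)))
  alive_edge <- rep.int(TRUE, max(ne, 1L))
  alive_node <- rep.int(TRUE, n)
  level <- integer(n)
  in_bin <- logical(n)
  arcs_y <- vector("list", 64L)
  arcs_o <- vector("list", 64L)
  dropped <- 0L
  r <- 0L
  n_alive <- n
  while (n_alive > 0L) {
    r <- r + 1L
    dmin <- min(deg[alive_node])
    if (mode == "fixed_m" && dmin < m0) {
      stop(sprintf(
        "fixed_m peeling: minimum degree dropped to %d below the snapshot minimum %d; use mode = 'min_degree'",
        dmin, m0), call. = FALSE)
    }
    bin <- which(alive_node & deg == dmin)
    level[bin] <- r
    in_bin[bin] <- TRUE
    eids <- unique(unlist(inc[bin], use.names = FALSE))
    if (length(eids)) {
      eids <- eids[alive_edge[eids]]
    }
    if (length(eids)) {
      u <- eu[eids]; v <- ev[eids]
      su <- in_bin[u]; sv <- in_bin[v]
      both <- su & sv                      # same-bin edges and self-loops
      one <- xor(su, sv)
      dropped <- dropped + sum(both & u != v)
      if (any(one)) {
        younger <- ifelse(su[one], u[one], v[one])
        older <- ifelse(su[one], v[one], u[one])
        if (r > length(arcs_y)) {
          length(arcs_y) <- 2L * r
          length(arcs_o) <- 2L * r
        }
        arcs_y[[r]] <- younger
        arcs_o[[r]] <- older
        deg <- deg - tabulate(older, n)
      }
      alive_edge[eids] <- FALSE
    }
    alive_node[bin] <- FALSE
    in_bin[bin] <- FALSE
    n_alive <- n_alive - length(bin)
  }
  new_recovered_dag(n, unlist(arcs_y) %||% integer(), unlist(arcs_o) %||% integer(),
                    level = level, dropped_same_bin = dropped,
                    source = "peeling", labels = h$labels)
}

# Canonical sort of an arc multiset, for equality comparison in tests and
# diagnostics.
sorted_arcs <- function(dag) {
  a <- dag$arcs
  a[order(a$younger, a$older), , drop = FALSE]
}

#' Relabel a DAG's nodes
#'
#' Applies a permutation to the node labels of a `recovered_dag`
#' (`perm[old] = new`), e.g. to map the true DAG of a grown graph onto the
#' labels of its permuted snapshot.
#'
#' @param dag A `recovered_dag`.
#' @param perm Integer permutation of `1..n`.
#' @return A `recovered_dag` on the new labels.
#' @export
relabel_dag <- function(dag, perm) {
  stopifnot(inherits(dag, "recovered_dag"), length(perm) == dag$n)
  level <- NULL
  if (!is.null(dag$level)) {
    level <- integer(dag$n)
    level[perm] <- dag$level
  }
  new_recovered_dag(dag$n, perm[dag$arcs$younger], perm[dag$arcs$older],
                    level = level, dropped_same_bin = dag$dropped_same_bin,
                    source = dag$source)
}

# Reachability closure of a recovered DAG: logical matrix reach[v, u] = TRUE
# iff u is reachable from v along younger -> older arcs (v younger than u
# with certainty).  Dense; guarded for memory.
dag_reachability <- function(dag, max_n = 4000L) {
  n <- dag$n
  if (n > max_n) {
    stop(sprintf("reachability closure needs a dense n x n matrix; n = %d exceeds %d",
                 n, max_n), call. = FALSE)
  }
  reach <- matrix(FALSE, n, n)
  a <- dag$arcs
  if (nrow(a) == 0L) return(reach)
  out <- split(a$older, factor(a$younger, levels = seq_len(n)))
  ord <- as.integer(igraph::topo_sort(
    igraph::graph_from_edgelist(cbind(a$younger, a$older), directed = TRUE),
    mode = "out"))
  # process youngest-last: a node's reach is its targets plus their reach
  for (v in rev(ord)) {
    tg <- out[[v]]
    if (length(tg) == 0L) next
    tg <- unique(tg)
    if (length(tg) == 1L) {
      reach[v, ] <- reach[v, ] | reach[tg, ]
    } else {
      reach[v, ] <- reach[v, ] | (colSums(reach[tg, , drop = FALSE]) > 0L)
    }
    reach[v, tg] <- TRUE
  }
  reach
}
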