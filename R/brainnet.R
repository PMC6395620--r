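#' Read a region x region correlation matrix
#'
#' Plain-text numeric matrix, comma- or whitespace-separated, with an
#' optional header row of region labels (detected when the first line is
#' non-numeric).
#'
#' @param path File path.
#' @return A symmetric numeric matrix with dimnames set to the region labels.
#' @export
read_correlation_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty matrix file", call. = FALSE)
  split1 <- strsplit(trimws(lines[1L]), "[,\t ]+")[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(split1)))
  labels <- if (has_header) split1 else NULL
  body <- lines[if (has_header) -1L else seq_along(lines)]
  rows <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[,\t ]+")[[1L]]))
    if (anyNA(v)) stop("non-numeric entry in matrix body", call. = FALSE)
    v
  })
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  labels <- labels %||% paste0("R", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  check_correlation(m)
  m
}

check_correlation <- function(c) {
  if (!is.matrix(c) || nrow(c) != ncol(c) || nrow(c) < 2L) {
    stop("correlation input must be a square matrix of size >= 2", call. = FALSE)
  }
  if (any(!is.finite(c))) stop("non-finite correlation entries", call. = FALSE)
  if (max(abs(c - t(c))) > 1e-8) {
    stop("correlation matrix must be symmetric (within 1e-8)", call. = FALSE)
  }
  invisible(c)
}

cor_edges <- function(c, use_abs = FALSE) {
  n <- nrow(c)
  idx <- which(upper.tri(c), arr.ind = TRUE)
  w <- c[idx]
  if (use_abs) w <- abs(w)
  tibble::tibble(u = idx[, "row"], v = idx[, "col"], w = w)
}

edge_snapshot <- function(n, u, v, labels) {
  ord <- order(u, v)
  new_snapshot(n, u[ord], v[ord], labels = labels)
}

#' Build a brain network: maximum spanning tree plus k nearest neighbors
#'
#' A spanning tree maximizing total correlation is built on the complete
#' weighted graph of the matrix, then each region's `k` highest-correlation
#' neighbors are added (an edge is kept if either endpoint ranks the other in
#' its top k).  The result is a connected simple graph.
#'
#' @param c Correlation matrix (symmetric; see [read_correlation_matrix()]).
#' @param k Number of nearest neighbors per region (default 10, as used for
#'   connectome matrices).
#' @param use_abs Rank and span by `|correlation|` instead of the signed
#'   value.
#' @return A `snapshot` carrying the region labels.
#' @export
graph_mst_knn <- function(c, k = 10L, use_abs = FALSE) {
  check_correlation(c)
  n <- nrow(c)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k >= n) {
    warning("k >= n - 1: result is the complete graph", call. = FALSE)
    e <- cor_edges(c, use_abs)
    return(edge_snapshot(n, e$u, e$v, labels = rownames(c)))
  }
  e <- cor_edges(c, use_abs)
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  tree <- igraph::mst(g, weights = -e$w)   # igraph minimizes; negate for max
  te <- igraph::as_edgelist(tree)
  picks <- matrix(0L, 0L, 2L)
  w <- if (use_abs) abs(c) else c
  diag(w) <- -Inf
  for (u in seq_len(n)) {
    top <- order(w[u, ], decreasing = TRUE)[seq_len(k)]
    picks <- rbind(picks, cbind(u, top))
  }
  all_u <- c(as.integer(te[, 1L]), pmin(picks[, 1L], picks[, 2L]))
  all_v <- c(as.integer(te[, 2L]), pmax(picks[, 1L], picks[, 2L]))
  uu <- pmin(all_u, all_v)
  vv <- pmax(all_u, all_v)
  keep <- !duplicated(cbind(uu, vv))
  edge_snapshot(n, uu[keep], vv[keep], labels = rownames(c))
}

#' Build a brain network by thresholding to connectivity
#'
#' Finds the largest threshold `tau` such that the graph with all edges of
#' correlation `>= tau` is connected (ties at `tau` included), by binary
#' search over the sorted edge weights.  By the bottleneck property of
#' spanning trees this `tau` equals the smallest edge weight on the maximum
#' spanning tree.
#'
#' @inheritParams graph_mst_knn
#' @return A `snapshot`; the chosen threshold is in attribute `tau`.
#' @export
graph_threshold_connected <- function(c, use_abs = FALSE) {
  check_correlation(c)
  n <- nrow(c)
  e <- cor_edges(c, use_abs)
  ws <- sort(unique(e$w), decreasing = TRUE)
  connected_at <- function(tau) {
    keep <- e$w >= tau
    if (sum(keep) < n - 1L) return(FALSE)
    g <- igraph::graph_from_data_frame(e[keep, c("u", "v")], directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    igraph::is_connected(g)
  }
  lo <- 1L
  hi <- length(ws)
  if (connected_at(ws[1L])) {
    hi <- 1L
  } else {
    # invariant: not connected at ws[lo], connected at ws[hi]
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (connected_at(ws[mid])) hi <- mid else lo <- mid
    }
  }
  tau <- ws[hi]
  keep <- e$w >= tau
  out <- edge_snapshot(n, e$u[keep], e$v[keep], labels = rownames(c))
  attr(out, "tau") <- tau
  out
}

#' Rank brain regions by peeling bins
#'
#' Peels the network and reports each region's bin with the convention that
#' bin 1 holds the oldest nodes (the highest peel level), matching the
#' oldest-first numbering used when mapping arrival batches onto the cortex.
#'
#' @param g A `snapshot` (e.g. from [graph_mst_knn()]).
#' @return A tibble with columns `region`, `level` (peel round, 1 = removed
#'   first) and `bin` (1 = oldest), sorted oldest first.
#' @export
rank_regions <- function(g) {
  stopifnot(inherits(g, "snapshot"))
  dag <- peel(g)
  bin <- dag$n_bins + 1L - dag$level
  tibble::tibble(region = g$labels, level = dag$level, bin = bin) |>
    dplyr::arrange(bin, region)
}
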