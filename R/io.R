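#' Read an edge list into a snapshot
#'
#' Whitespace- or tab-separated, two columns per line, `#` comments and blank
#' lines ignored.  Duplicate lines are kept as multi-edges.  Node labels may
#' be arbitrary strings; they are mapped to contiguous internal ids `1..n`
#' with the label table stored on the snapshot.
#'
#' @param path Edge-list file.
#' @param truth Optional path to a ground-truth file with lines
#'   `label<TAB>arrival_index`; attaches the arrival order for evaluation.
#' @return A `snapshot`.
#' @export
read_edge_list <- function(path, truth = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  body <- trimws(lines[keep])
  lineno <- which(keep)
  if (!length(body)) stop("empty edge-list file: ", path, call. = FALSE)
  toks <- strsplit(body, "[\t ]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected two columns",
                 lineno[bad[1L]], path), call. = FALSE)
  }
  a <- vapply(toks, `[[`, character(1L), 1L)
  b <- vapply(toks, `[[`, character(1L), 2L)
  labels <- sort_labels(unique(c(a, b)))
  h <- new_snapshot(length(labels), match(a, labels), match(b, labels),
                    labels = labels)
  if (!is.null(truth)) {
    tt <- read_truth(truth, labels)
    h$arrival <- tt
  }
  h
}

# numeric-looking labels sort numerically, others lexically
sort_labels <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(x)
}

read_truth <- function(path, labels) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[\t ]+")
  if (any(lengths(toks) != 2L)) stop("malformed ground-truth file", call. = FALSE)
  lab <- vapply(toks, `[[`, character(1L), 1L)
  idx <- as.integer(vapply(toks, `[[`, character(1L), 2L))
  if (!setequal(lab, labels)) {
    stop("ground-truth labels do not match the edge list", call. = FALSE)
  }
  arrival <- idx[match(labels, lab)]
  if (!setequal(arrival, seq_along(labels))) {
    stop("ground-truth arrival indices must be a bijection 1..n", call. = FALSE)
  }
  arrival
}

#' Write a snapshot (or grown graph) as a tab-separated edge list
#'
#' One line `u<TAB>v` per multi-edge, using the snapshot's labels.  For a
#' `grown_graph` (or a snapshot with ground truth) the true arrival order can
#' be written alongside as `label<TAB>arrival_index`.
#'
#' @param x A `snapshot` or `grown_graph`.
#' @param path Output edge-list path.
#' @param truth_path Optional path for the ground-truth file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path, truth_path = NULL) {
  if (inherits(x, "grown_graph")) x <- as_snapshot(x)
  stopifnot(inherits(x, "snapshot"))
  lab <- x$labels
  writeLines(paste(lab[x$edges$u], lab[x$edges$v], sep = "\t"), path)
  if (!is.null(truth_path)) {
    if (is.null(x$arrival)) stop("no ground truth to write", call. = FALSE)
    writeLines(paste(lab, x$arrival, sep = "\t"), truth_path)
  }
  invisible(path)
}

#' Write a partial order to disk
#'
#' `bins` mode writes `node<TAB>level` (requires a bin-based order); `pairs`
#' mode writes one `older<TAB>younger` line per comparable pair, i.e. `K`
#' lines.
#'
#' @param order A `partial_order`.
#' @param path Output path.
#' @param mode `"bins"` or `"pairs"`.
#' @param labels Optional labels (defaults to the order's).
#' @param force Allow pairs mode beyond 1e7 pairs.
#' @return `path`, invisibly.
#' @export
write_partial_order <- function(order, path, mode = c("bins", "pairs"),
                                labels = NULL, force = FALSE) {
  stopifnot(inherits(order, "partial_order"))
  mode <- match.arg(mode)
  lab <- labels %||% order$labels
  if (mode == "bins") {
    if (is.null(order$level)) {
      stop("bins mode needs a bin-based order", call. = FALSE)
    }
    writeLines(paste(lab, order$level, sep = "\t"), path)
  } else {
    if (order$K > 1e7 && !force) {
      stop("refusing to write > 1e7 pairs without force = TRUE", call. = FALSE)
    }
    pr <- tidy(order, max_pairs = Inf)
    writeLines(paste(lab[pr$before], lab[pr$after], sep = "\t"), path)
  }
  invisible(path)
}

#' Read a bin-based partial order written by [write_partial_order()]
#'
#' @param path File of `node<TAB>level` lines.
#' @return A `partial_order` of kind `"bins"`.
#' @export
read_partial_order_bins <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[\t ]+")
  if (any(lengths(toks) != 2L)) stop("malformed bins file", call. = FALSE)
  lab <- vapply(toks, `[[`, character(1L), 1L)
  lev <- as.integer(vapply(toks, `[[`, character(1L), 2L))
  ord <- order(match(lab, sort_labels(lab)))
  lev <- lev[ord]
  lab <- lab[ord]
  sizes <- tabulate(lev)
  K <- (sum(as.numeric(sizes))^2 - sum(as.numeric(sizes)^2)) / 2
  new_partial_order(length(lev), "bins", level = lev, K = K, labels = lab)
}

#' Write a run configuration file
#'
#' Serializes a named list as `key=value` lines so that stochastic runs can
#' record their full parameterization (model, seeds, paths) next to their
#' outputs; [read_run_config()] round-trips it.
#'
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v) paste(format(v, trim = TRUE), collapse = ","),
                 character(1L))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- paste(x[-1L], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, `[[`, character(1L), 1L))
}
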