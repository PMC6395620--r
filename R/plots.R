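#' Plot a bound curve with optional estimator points
#'
#' Draws the LP upper bound on precision against the density floor; estimator
#' points (e.g. from [snapshot_estimator_points()]) can be overlaid to show
#' how close the heuristics come to the optimal tradeoff.
#'
#' @param object A `bound_curve`.
#' @param points Optional tibble with columns `density`, `precision` and
#'   `estimator`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bound_curve <- function(object, points = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$eps, y = .data$bound)) +
    ggplot2::geom_step(direction = "vh", colour = "grey30") +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = expression("density floor " * epsilon),
                  y = expression("precision bound " * theta^"*"),
                  title = "LP upper bound on the precision/density tradeoff") +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points,
      ggplot2::aes(x = .data$density, y = .data$precision,
                   colour = .data$estimator),
      inherit.aes = FALSE, size = 2.5)
  }
  p
}

#' Plot replicate scores of an estimator experiment
#'
#' Precision against density per replicate, with the replicate mean marked.
#'
#' @param object An `estimator_score`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.estimator_score <- function(object, ...) {
  s <- object$scores
  g <- glance(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$density, y = .data$precision)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = data.frame(density = g$delta, precision = g$theta),
                        colour = "red", size = 3, shape = 4) +
    ggplot2::labs(
      x = expression(delta), y = expression(theta),
      title = sprintf("%s estimator on %s(n = %d), %d replicates",
                      object$estimator, object$spec$model, object$spec$n,
                      g$reps)) +
    ggplot2::theme_minimal()
}

#' Plot the peel-level profile of a snapshot
#'
#' Bin sizes by peel level; youngest bins (level 1) are removed first.
#'
#' @param dag A `recovered_dag` with levels.
#' @return A ggplot object.
#' @export
plot_peel_profile <- function(dag) {
  stopifnot(inherits(dag, "recovered_dag"))
  if (is.null(dag$level)) stop("peel levels required", call. = FALSE)
  df <- dplyr::count(tibble::tibble(level = dag$level), .data$level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "peel level (1 = youngest bin)", y = "nodes in bin") +
    ggplot2::theme_minimal()
}
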