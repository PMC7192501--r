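#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a concordance result
#'
#' @param x a `concordance_result`.
#' @param ... unused.
#' @return Tibble of per-pair mean data differences (`from`, `to`, `delta`).
#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) x$delta

#' One-row summary of a concordance result
#'
#' @param x a `concordance_result`.
#' @param ... unused.
#' @return Tibble with `data_type`, `f_pos`, `n_pairs`, `p_value`, `n_perm`.
#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  tibble::tibble(data_type = x$data_type, f_pos = x$f_pos,
                 n_pairs = x$n_pairs, p_value = x$p_value,
                 n_perm = x$n_perm)
}

#' Histogram of mean data differences over ordered pairs
#'
#' @param object a `concordance_result`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot concordance_result
#' @export
autoplot.concordance_result <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$delta, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression(hat(delta)[ij]),
      y = "ordered pairs",
      title = sprintf("%s: f>0 = %.3f (p = %.3g)", object$data_type,
                      object$f_pos, object$p_value))
}

#' Tidy an order DAG
#'
#' @param x an `order_dag`.
#' @param ... unused.
#' @return Tibble with one row per node: `node`, `level`, `n_reactions`,
#'   `members` (comma-separated).
#' @method tidy order_dag
#' @export
tidy.order_dag <- function(x, ...) {
  tibble::tibble(
    node = x$nodes$node,
    level = x$nodes$level,
    n_reactions = lengths(x$nodes$members),
    members = vapply(x$nodes$members, paste, character(1), collapse = ","))
}

#' One-row summary of an order DAG
#'
#' @param x an `order_dag`.
#' @param ... unused.
#' @return Tibble with node/edge/level/reaction counts.
#' @method glance order_dag
#' @export
glance.order_dag <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = igraph::ecount(x$graph),
    n_levels = if (nrow(x$nodes)) max(x$nodes$level) + 1L else 0L,
    n_reactions = sum(lengths(x$nodes$members)),
    condition = x$condition %||% NA_character_)
}

#' Reactions-per-level bar chart of an order DAG
#'
#' @param object an `order_dag`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot order_dag
#' @export
autoplot.order_dag <- function(object, ...) {
  ggplot2::ggplot(level_histogram(object),
                  ggplot2::aes(x = factor(.data$level),
                               y = .data$n_reactions)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "hierarchy level (0 = roots)", y = "reactions",
                  title = "Flux order DAG level occupancy")
}
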