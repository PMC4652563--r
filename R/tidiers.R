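#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the edges of a gene set network
#'
#' @param x A `gsn`.
#' @param tests Return all tested pairs instead of only significant edges.
#' @param ... Unused.
#' @return Tibble of edges (`gs1`, `gs2`, `n`, `K`, `k`, `N`, `p`, `q`).
#' @method tidy gsn
#' @export
tidy.gsn <- function(x, tests = FALSE, ...) {
  if (tests) x$tests else x$edges
}

#' One-row summary of a gene set network
#'
#' @param x A `gsn`.
#' @param ... Unused.
#' @return Tibble with `kind`, `directed`, `n_nodes`, `n_edges`,
#'   `n_tested`, `alpha`, `universe_size`, `regulation_count`.
#' @method glance gsn
#' @export
glance.gsn <- function(x, ...) {
  tibble(
    kind = x$kind, directed = x$directed,
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_tested = nrow(x$tests), alpha = x$alpha,
    universe_size = x$universe_size,
    regulation_count = x$regulation_count
  )
}

#' Plot a gene set network
#'
#' Fruchterman-Reingold layout with node size proportional to degree and
#' edge transparency proportional to -log10(q). Deterministic for a fixed
#' `seed`.
#'
#' @param object A `gsn`.
#' @param seed Layout seed.
#' @param label Draw node labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gsn
#' @export
autoplot.gsn <- function(object, seed = 1L, label = FALSE, ...) {
  g <- as_igraph_gsn(object)
  old <- get_rng_state()
  set.seed(seed)
  on.exit(restore_rng_state(old), add = TRUE)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(set = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                  degree = igraph::degree(g))
  ed <- object$edges
  if (nrow(ed) > 0L) {
    ed <- ed |>
      left_join(select(nodes, "set", x1 = "x", y1 = "y"),
                by = c(gs1 = "set")) |>
      left_join(select(nodes, "set", x2 = "x", y2 = "y"),
                by = c(gs2 = "set"))
  }
  p <- ggplot2::ggplot()
  if (nrow(ed) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2),
      colour = "grey50", alpha = 0.6,
      arrow = if (object$directed) {
        ggplot2::arrow(length = ggplot2::unit(1.8, "mm"))
      } else {
        NULL
      }
    )
  }
  p <- p + ggplot2::geom_point(
    data = nodes,
    ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
    colour = "steelblue"
  )
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$set),
      vjust = -1, size = 3
    )
  }
  p + ggplot2::theme_void() +
    ggplot2::labs(size = "degree",
                  title = sprintf("%s network (%d nodes, %d edges)",
                                  object$kind, nrow(nodes), nrow(object$edges)))
}

#' Bar chart of node centralities
#'
#' @param net A `gsn`.
#' @param measure One of `"dc"`, `"closeness"`, `"betweenness"`.
#' @param top_n Show the `top_n` highest-ranked nodes.
#' @return A ggplot object.
#' @export
plot_centrality <- function(net, measure = c("dc", "closeness", "betweenness"),
                            top_n = 20) {
  measure <- match.arg(measure)
  rep <- centrality_report(net)
  rep <- rep |>
    arrange(dplyr::desc(.data[[measure]])) |>
    head(top_n) |>
    mutate(set = factor(.data$set, levels = rev(.data$set)))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data[[measure]], y = .data$set)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = measure, y = NULL) +
    ggplot2::theme_minimal()
}
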