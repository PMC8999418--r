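#' Plot a classified disease network
#'
#' Draws the augmented network with the field's node-color convention:
#' directly connected input genes white, bridged genes yellow, intermediates
#' green, unbridgeable genes gray. Layout is Fruchterman–Reingold (seeded,
#' so the figure is reproducible).
#'
#' @param object A completed `gene_classification`.
#' @param network The `ppi_network` to draw, typically
#'   [assemble_augmented_network()]'s result.
#' @param layout_seed Integer seed for the layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_classification
#' @export
autoplot.gene_classification <- function(object, network,
                                         layout_seed = 42L, ...) {
  stopifnot(is_ppi_network(network))
  nodes <- annotate_nodes(network, object, NULL)
  g <- as_igraph(network)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  nodes$x <- xy[match(nodes$name, igraph::V(g)$name), 1]
  nodes$y <- xy[match(nodes$name, igraph::V(g)$name), 2]
  e <- network$edges |>
    mutate(
      x = nodes$x[match(.data$from, nodes$name)],
      y = nodes$y[match(.data$from, nodes$name)],
      xend = nodes$x[match(.data$to, nodes$name)],
      yend = nodes$y[match(.data$to, nodes$name)]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linewidth = .data$confidence),
      color = "gray60", alpha = 0.6, show.legend = FALSE
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1)) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$role),
      shape = 21, size = 3, color = "black"
    ) +
    ggplot2::scale_fill_manual(values = role_colors) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "role")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Heatmap of inter/intragroup connectivity
#'
#' Lower-triangular heatmap of PPI counts between localization groups, the
#' tabular companion of the annotated group map.
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot connectivity_matrix
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$group_a),
                                  y = factor(.data$group_b),
                                  fill = .data$n_edges)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_edges)) +
    ggplot2::scale_fill_gradient(low = "white", high = "orange") +
    ggplot2::labs(x = "group", y = "group", fill = "PPIs") +
    ggplot2::theme_minimal()
}

#' Assignment progress across propagation rounds
#'
#' Bar chart of how many genes each round of label propagation assigned,
#' split by localization group — a quick view of how far the seed groups had
#' to be extrapolated.
#'
#' @param object A `localization_assignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot localization_assignment
#' @export
autoplot.localization_assignment <- function(object, ...) {
  d <- object$assignment
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$iteration),
                                  fill = factor(.data$group))) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Set1") +
    ggplot2::labs(x = "propagation round (0 = seeds)", y = "genes assigned",
                  fill = "group") +
    ggplot2::theme_minimal()
}
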