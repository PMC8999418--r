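role_colors <- c(
  direct = "white", bridged = "yellow", unbridgeable = "gray",
  intermediate = "green", pending = "gray", other = "lightgray"
)
group_colors <- c("red", "blue", "green", "purple")

#' Export an annotated network
#'
#' Writes a network with node roles (direct / bridged / unbridgeable /
#' intermediate, colored white / yellow / gray / green), localization
#' groups, and per-endpoint edge colors. Because PPIs are bidirectional an
#' edge carries one color attribute per endpoint (`color_from` /
#' `color_to`), each determined by that endpoint's group: red, blue, green,
#' purple for groups 1–4.
#'
#' @param network A `ppi_network` (typically the augmented network).
#' @param classification Optional `gene_classification` supplying node
#'   roles.
#' @param assignment Optional `localization_assignment` supplying node
#'   groups.
#' @param path Output path.
#' @param format `"graphml"`, `"dot"` or `"tsv"` (edge list with
#'   attributes).
#' @return `path`, invisibly.
#' @export
write_annotated_network <- function(network, classification = NULL,
                                    assignment = NULL, path,
                                    format = c("graphml", "dot", "tsv")) {
  stopifnot(is_ppi_network(network))
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(paste0(
                       "unknown format ", sQuote(format[1]))))

  nodes <- annotate_nodes(network, classification, assignment)
  edges <- annotate_edges(network, nodes)

  switch(format,
    graphml = {
      g <- igraph::graph_from_data_frame(
        as.data.frame(edges), directed = FALSE,
        vertices = as.data.frame(nodes)
      )
      igraph::write_graph(g, path, format = "graphml")
    },
    dot = write_dot_file(nodes, edges, path),
    tsv = {
      readr::write_tsv(edges, path)
      readr::write_tsv(nodes, sub("(\\.[A-Za-z]+)?$", ".nodes\\1", path,
                                  perl = TRUE))
    }
  )
  invisible(path)
}

annotate_nodes <- function(network, classification, assignment) {
  nodes <- tibble(name = network$nodes)
  role <- setNames(rep("direct", length(network$nodes)), network$nodes)
  if (!is.null(classification)) {
    cl <- tidy(classification)
    role[] <- "other"  # network nodes outside the input list and bridges
    role[cl$gene[cl$gene %in% names(role)]] <-
      cl$role[cl$gene %in% names(role)]
  }
  nodes$role <- unname(role[nodes$name])
  nodes$color <- unname(role_colors[nodes$role])
  grp <- rep(NA_integer_, nrow(nodes))
  if (!is.null(assignment)) {
    a <- assignment$assignment
    grp <- a$group[match(nodes$name, a$gene)]
  }
  nodes$group <- grp
  nodes
}

annotate_edges <- function(network, nodes) {
  e <- network$edges
  grp <- setNames(nodes$group, nodes$name)
  ecol <- function(g) ifelse(is.na(g) | g > length(group_colors),
                             "gray", group_colors[pmin(g, length(group_colors))])
  tibble(
    from = e$from, to = e$to, confidence = e$confidence,
    color_from = ecol(grp[e$from]),
    color_to = ecol(grp[e$to])
  )
}

write_dot_file <- function(nodes, edges, path) {
  q <- function(x) paste0('"', x, '"')
  lines <- c(
    "graph ppi {",
    paste0(
      "  ", q(nodes$name),
      " [role=", q(nodes$role),
      ", color=", q(nodes$color),
      ifelse(is.na(nodes$group), "",
             paste0(", group=", nodes$group)),
      "];"
    ),
    if (nrow(edges) > 0) paste0(
      "  ", q(edges$from), " -- ", q(edges$to),
      " [confidence=", format(edges$confidence, digits = 6, trim = TRUE),
      ", color_from=", q(edges$color_from),
      ", color_to=", q(edges$color_to), "];"
    ),
    "}"
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read back an annotated GraphML network
#'
#' Companion to [write_annotated_network()] for round-tripping: returns the
#' node and edge tables with their attributes.
#'
#' @param path A GraphML file written by this package.
#' @return List with `nodes` and `edges` tibbles.
#' @export
read_annotated_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices"))
  edges <- as_tibble(igraph::as_data_frame(g, what = "edges"))
  if (nrow(nodes) > 0) nodes <- arrange(nodes, .data$name)
  if (nrow(edges) > 0) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    cf <- edges$color_from[swap]
    edges$color_from[swap] <- edges$color_to[swap]
    edges$color_to[swap] <- cf
    edges <- arrange(edges, .data$from, .data$to)
  }
  list(nodes = nodes, edges = edges)
}
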