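#' Build a confidence-weighted PPI network
#'
#' Constructs a simple undirected graph from an edge table. Edges below the
#' confidence threshold are excluded; duplicate rows for the same unordered
#' pair (STRING flat files list every edge in both orientations) are merged
#' keeping the maximum confidence, a conservative union of evidence channels.
#' Declared nodes without any surviving edge are retained as isolated nodes.
#'
#' @param edges Tibble with columns `gene_a`, `gene_b`, `confidence`
#'   (as produced by [read_edge_table()]).
#' @param threshold Minimum confidence retained, in `[0, 1]`. Default 0.400,
#'   STRING's conventional "medium confidence" cutoff.
#' @param nodes Optional character vector of node symbols to retain even if
#'   isolated; endpoints of surviving edges are always included.
#' @return A `ppi_network` object: list with `nodes` (sorted character
#'   vector), `edges` (tibble `from`, `to`, `confidence` with `from < to`
#'   lexicographically) and `threshold`.
#' @examples
#' edges <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "A"),
#'                         confidence = c(0.5, 0.7))
#' build_ppi_network(edges, threshold = 0.4)
#' @export
build_ppi_network <- function(edges, threshold = 0.4, nodes = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  edges <- as_tibble(edges)
  req <- c("gene_a", "gene_b", "confidence")
  if (!all(req %in% names(edges))) {
    abort("edge table must have columns gene_a, gene_b, confidence")
  }
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    abort("edge confidences must lie in [0, 1]")
  }
  a <- normalize_gene_symbols(edges$gene_a)
  b <- normalize_gene_symbols(edges$gene_b)
  if (any(a == b)) abort("self-loops are not allowed in a PPI network")

  declared <- sort(unique(c(a, b, if (!is.null(nodes)) normalize_gene_symbols(nodes))))

  keep <- edges$confidence >= threshold
  from <- pmin(a[keep], b[keep])
  to <- pmax(a[keep], b[keep])
  merged <- tibble(from = from, to = to, confidence = edges$confidence[keep])
  if (nrow(merged) > 0) {
    merged <- merged |>
      group_by(.data$from, .data$to) |>
      summarise(confidence = max(.data$confidence), .groups = "drop") |>
      arrange(.data$from, .data$to)
  }

  structure(
    list(nodes = declared, edges = merged, threshold = threshold),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (confidence >= ", format(x$threshold), ")\n", sep = "")
  invisible(x)
}

is_ppi_network <- function(x) inherits(x, "ppi_network")

#' Number of nodes and edges of a PPI network
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return A one-row tibble with `n_nodes`, `n_edges`, `threshold`.
#' @method glance ppi_network
#' @export
glance.ppi_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         threshold = x$threshold)
}

#' Edge table of a PPI network
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `confidence` (`from < to`).
#' @method tidy ppi_network
#' @export
tidy.ppi_network <- function(x, ...) {
  x$edges
}

#' Neighbors of a gene with interaction confidences
#'
#' @param network A `ppi_network`.
#' @param gene A single gene symbol (normalized on entry).
#' @return Tibble with columns `neighbor` and `confidence`, sorted by
#'   neighbor symbol; zero rows for an isolated gene.
#' @export
ppi_neighbors <- function(network, gene) {
  stopifnot(is_ppi_network(network))
  gene <- normalize_gene_symbols(gene)
  stopifnot(length(gene) == 1)
  if (!gene %in% network$nodes) {
    abort(paste0("unknown gene ", sQuote(gene)))
  }
  e <- network$edges
  hit <- e$from == gene | e$to == gene
  tibble(
    neighbor = ifelse(e$from[hit] == gene, e$to[hit], e$from[hit]),
    confidence = e$confidence[hit]
  ) |>
    arrange(.data$neighbor)
}

# adjacency as a named list of named confidence vectors; internal fast path
adjacency_list <- function(network) {
  e <- network$edges
  nbr <- split(c(e$to, e$from), c(e$from, e$to))
  conf <- split(c(e$confidence, e$confidence), c(e$from, e$to))
  out <- lapply(seq_along(nbr), function(i) setNames(conf[[i]], nbr[[i]]))
  names(out) <- names(nbr)
  out
}

as_igraph <- function(network, restrict_to = NULL) {
  nodes <- network$nodes
  e <- network$edges
  if (!is.null(restrict_to)) {
    nodes <- intersect(nodes, restrict_to)
    e <- e[e$from %in% nodes & e$to %in% nodes, ]
  }
  igraph::graph_from_data_frame(
    d = data.frame(from = e$from, to = e$to, confidence = e$confidence),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
}

#' Connected components of a PPI network
#'
#' Components are computed on the whole network or, when `restrict_to` is
#' given, on the subgraph induced by those nodes only (edges with one
#' endpoint outside the restriction do not contribute). Components are
#' ordered deterministically: descending size, ties broken by the
#' lexicographically smallest member, so reports are byte-reproducible.
#'
#' @param network A `ppi_network`.
#' @param restrict_to Optional character vector of nodes; must be a subset of
#'   the network's nodes.
#' @return Tibble with columns `gene` and `component` (1-based rank in the
#'   deterministic order); zero rows for an empty restriction.
#' @export
network_components <- function(network, restrict_to = NULL) {
  stopifnot(is_ppi_network(network))
  if (!is.null(restrict_to)) {
    restrict_to <- unique(normalize_gene_symbols(restrict_to))
    missing <- setdiff(restrict_to, network$nodes)
    if (length(missing) > 0) {
      abort(paste0("restrict_to contains unknown gene(s): ",
                   paste(missing, collapse = ", ")))
    }
    if (length(restrict_to) == 0) {
      return(tibble(gene = character(), component = integer()))
    }
  }
  g <- as_igraph(network, restrict_to)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  ord <- order(-vapply(members, length, 1L),
               vapply(members, `[[`, "", 1L))
  members <- members[ord]
  tibble(
    gene = unlist(members, use.names = FALSE),
    component = rep(seq_along(members), lengths(members))
  )
}

#' Induced subgraph of a PPI network
#'
#' @param network A `ppi_network`.
#' @param nodes Character vector of nodes to keep.
#' @return A `ppi_network` on `nodes` with the induced edges, same threshold.
#' @export
induced_network <- function(network, nodes) {
  stopifnot(is_ppi_network(network))
  nodes <- unique(normalize_gene_symbols(nodes))
  e <- network$edges
  e <- e[e$from %in% nodes & e$to %in% nodes, ]
  structure(
    list(nodes = sort(nodes), edges = e, threshold = network$threshold),
    class = "ppi_network"
  )
}
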