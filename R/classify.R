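#' Classify disease genes by network connectivity
#'
#' First stage of the candidate-gene protocol. Input genes that interact
#' (at the network threshold) with at least one other input gene form the
#' directly-connected class ("group A"); the remainder are provisionally
#' disconnected and await bridge selection ([select_intermediates()]), which
#' settles them into the bridgeable class ("group B") or the unbridgeable
#' class ("group C"). The *main component* is the largest connected component
#' of the subgraph induced on the directly-connected genes (ties on size go
#' to the component holding the lexicographically smallest symbol); bridges
#' must reconnect disconnected genes to it so that the result is one disease
#' module rather than several.
#'
#' @param network A `ppi_network` from [build_ppi_network()].
#' @param genes Gene-list tibble (column `gene`) or character vector. Every
#'   gene must be a node of the network; run [apply_alias_map()] first to
#'   drop or rename unrecognized symbols.
#' @return A `gene_classification` object. Its `genes` tibble has columns
#'   `gene` and `role` (`"direct"` or, until bridge selection runs,
#'   `"pending"`); `main_component` holds the main-component members;
#'   `bridges` is empty until [select_intermediates()] completes it.
#' @examples
#' net <- build_ppi_network(
#'   tibble::tibble(gene_a = c("A", "C"), gene_b = c("B", "D"),
#'                  confidence = 0.9))
#' classify_connectivity(net, c("A", "B", "D"))
#' @export
classify_connectivity <- function(network, genes) {
  stopifnot(is_ppi_network(network))
  genes <- as_gene_vector(genes)
  genes <- genes[!duplicated(genes)]
  missing <- setdiff(genes, network$nodes)
  if (length(missing) > 0) {
    abort(paste0(
      "input gene(s) absent from the network (run apply_alias_map first): ",
      paste(missing, collapse = ", ")
    ))
  }
  gene_set <- genes
  e <- network$edges
  internal <- e[e$from %in% gene_set & e$to %in% gene_set, ]
  direct <- sort(intersect(gene_set, c(internal$from, internal$to)))
  pending <- setdiff(genes, direct)

  main_component <- character()
  if (length(direct) > 0) {
    comp <- network_components(network, restrict_to = direct)
    main_component <- comp$gene[comp$component == 1L]
  }

  structure(
    list(
      genes = tibble(
        gene = genes,
        role = ifelse(genes %in% direct, "direct", "pending")
      ),
      main_component = main_component,
      bridges = empty_bridge_tbl(),
      threshold = network$threshold,
      score_strategy = NA_character_
    ),
    class = "gene_classification"
  )
}

empty_bridge_tbl <- function() {
  tibble(
    gene = character(), bridge = character(),
    conf_to_gene = numeric(), best_conf_to_main = numeric(),
    links_to_main = integer(), score = numeric()
  )
}

#' @export
print.gene_classification <- function(x, ...) {
  g <- glance(x)
  cat("<gene_classification> ", g$n_genes, " genes: ",
      g$n_direct, " direct, ", g$n_bridged, " bridged, ",
      g$n_unbridgeable, " unbridgeable, ", g$n_pending, " pending; ",
      g$n_intermediates, " intermediate(s)\n", sep = "")
  invisible(x)
}

#' Enumerate scored bridge candidates for one disconnected gene
#'
#' A valid bridge (intermediate) for a disconnected input gene is a
#' *non-input* neighbor of that gene that also interacts with at least one
#' member of the main component — one gene standing between the isolated
#' gene and the disease module. Each candidate is scored from its two legs:
#' the confidence to the disconnected gene and its confidences into the main
#' component.
#'
#' Scoring strategies (`score_strategy`):
#' * `"two_leg_sum"` (default): confidence to the gene + best single
#'   confidence into the main component;
#' * `"all_links_sum"`: confidence to the gene + sum of all its
#'   main-component confidences (rewards hub intermediates);
#' * `"min_leg"`: the weaker of the two legs (a bottleneck score).
#'
#' Candidates are returned in descending score; ties break by more links
#' into the main component, then by lexicographically smaller symbol, so
#' selection is fully deterministic.
#'
#' @param network A `ppi_network`.
#' @param b_gene The disconnected input gene (must not be in
#'   `main_component`).
#' @param main_component Character vector, the main-component members.
#' @param input_genes Character vector of all input genes (candidates are
#'   drawn outside this set).
#' @param score_strategy One of `"two_leg_sum"`, `"all_links_sum"`,
#'   `"min_leg"`.
#' @return Tibble with columns `gene`, `bridge`, `conf_to_gene`,
#'   `best_conf_to_main`, `links_to_main`, `score`; zero rows when the gene
#'   is unbridgeable.
#' @export
enumerate_bridge_candidates <- function(network, b_gene, main_component,
                                        input_genes,
                                        score_strategy = c("two_leg_sum",
                                                           "all_links_sum",
                                                           "min_leg")) {
  stopifnot(is_ppi_network(network))
  score_strategy <- match.arg(score_strategy)
  b_gene <- normalize_gene_symbols(b_gene)
  input_genes <- normalize_gene_symbols(input_genes)
  main_component <- normalize_gene_symbols(main_component)
  if (b_gene %in% main_component) {
    abort(paste0(sQuote(b_gene), " is already in the main component"))
  }

  nbrs <- ppi_neighbors(network, b_gene)
  nbrs <- nbrs[!nbrs$neighbor %in% input_genes, ]
  if (nrow(nbrs) == 0) return(empty_bridge_tbl())

  cand <- purrr::map_dfr(seq_len(nrow(nbrs)), function(i) {
    cand_gene <- nbrs$neighbor[i]
    main_links <- ppi_neighbors(network, cand_gene)
    main_links <- main_links[main_links$neighbor %in% main_component, ]
    if (nrow(main_links) == 0) return(NULL)
    tibble(
      gene = b_gene,
      bridge = cand_gene,
      conf_to_gene = nbrs$confidence[i],
      best_conf_to_main = max(main_links$confidence),
      links_to_main = nrow(main_links),
      sum_conf_to_main = sum(main_links$confidence)
    )
  })
  if (is.null(cand) || nrow(cand) == 0) return(empty_bridge_tbl())

  # scores are rounded to 9 decimals so tie-breaking is not at the mercy of
  # last-ulp floating-point differences between equal-by-construction sums
  cand$score <- round(switch(
    score_strategy,
    two_leg_sum = cand$conf_to_gene + cand$best_conf_to_main,
    all_links_sum = cand$conf_to_gene + cand$sum_conf_to_main,
    min_leg = pmin(cand$conf_to_gene, cand$best_conf_to_main)
  ), 9)
  cand |>
    select(-"sum_conf_to_main") |>
    arrange(desc(.data$score), desc(.data$links_to_main), .data$bridge)
}

#' Select one intermediate gene per bridgeable disconnected gene
#'
#' Completes a [classify_connectivity()] result: every provisionally
#' disconnected gene with at least one valid bridge candidate becomes
#' bridged (`"bridged"`) and is paired with its single top-scoring candidate
#' — one intermediate per gene, keeping the augmented map minimal. Genes
#' with no valid candidate are unbridgeable (`"unbridgeable"`). Distinct
#' disconnected genes may share an intermediate.
#'
#' @param network A `ppi_network`.
#' @param classification A `gene_classification` from
#'   [classify_connectivity()].
#' @param score_strategy Passed to [enumerate_bridge_candidates()].
#' @return The completed `gene_classification`: roles are now `"direct"`,
#'   `"bridged"` or `"unbridgeable"`, and `bridges` holds one row per
#'   bridged gene with its selected intermediate and scores.
#' @export
select_intermediates <- function(network, classification,
                                 score_strategy = c("two_leg_sum",
                                                    "all_links_sum",
                                                    "min_leg")) {
  stopifnot(is_ppi_network(network),
            inherits(classification, "gene_classification"))
  score_strategy <- match.arg(score_strategy)
  input_genes <- classification$genes$gene
  pending <- classification$genes$gene[classification$genes$role != "direct"]

  picked <- purrr::map_dfr(sort(pending), function(g) {
    cand <- enumerate_bridge_candidates(
      network, g, classification$main_component, input_genes,
      score_strategy = score_strategy
    )
    if (nrow(cand) == 0) NULL else cand[1, ]
  })
  if (nrow(picked) == 0) picked <- empty_bridge_tbl()

  role <- classification$genes$role
  role[role != "direct"] <- ifelse(
    classification$genes$gene[role != "direct"] %in% picked$gene,
    "bridged", "unbridgeable"
  )
  classification$genes$role <- role
  classification$bridges <- picked
  classification$score_strategy <- score_strategy
  classification
}

#' Assemble the augmented disease network
#'
#' Induces the subgraph on the input genes plus the selected intermediates —
#' the "completed map" of the disease module. When no gene is unbridgeable,
#' the augmented subgraph restricted to the main component, the bridged
#' genes and their intermediates is connected; unbridgeable genes remain
#' isolated and are flagged by their role attribute in exports.
#'
#' @param network A `ppi_network`.
#' @param classification A completed `gene_classification`.
#' @return A `ppi_network` on the input genes and intermediates.
#' @export
assemble_augmented_network <- function(network, classification) {
  stopifnot(is_ppi_network(network),
            inherits(classification, "gene_classification"))
  if (any(classification$genes$role == "pending")) {
    abort("run select_intermediates() before assembling the augmented network")
  }
  induced_network(
    network,
    c(classification$genes$gene, unique(classification$bridges$bridge))
  )
}

#' Gene roles of a classification, one row per gene
#'
#' @param x A `gene_classification`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `role` (`direct` / `bridged` /
#'   `unbridgeable` / `pending` / `intermediate`), `in_main_component`,
#'   `bridge` (the selected intermediate, `NA` otherwise) and `bridge_score`.
#'   Intermediates appear as their own rows with role `"intermediate"`.
#' @method tidy gene_classification
#' @export
tidy.gene_classification <- function(x, ...) {
  base <- x$genes |>
    mutate(
      in_main_component = .data$gene %in% x$main_component,
      bridge = x$bridges$bridge[match(.data$gene, x$bridges$gene)],
      bridge_score = x$bridges$score[match(.data$gene, x$bridges$gene)]
    )
  inter <- tibble(
    gene = sort(unique(x$bridges$bridge)),
    role = "intermediate",
    in_main_component = FALSE,
    bridge = NA_character_,
    bridge_score = NA_real_
  )
  bind_rows(base, inter)
}

#' One-row summary of a classification
#'
#' @param x A `gene_classification`.
#' @param ... Unused.
#' @return Tibble with counts of each role, the number of distinct
#'   intermediates, the main-component size and the scoring strategy.
#' @method glance gene_classification
#' @export
glance.gene_classification <- function(x, ...) {
  role <- x$genes$role
  tibble(
    n_genes = nrow(x$genes),
    n_direct = sum(role == "direct"),
    n_bridged = sum(role == "bridged"),
    n_unbridgeable = sum(role == "unbridgeable"),
    n_pending = sum(role == "pending"),
    n_intermediates = length(unique(x$bridges$bridge)),
    main_component_size = length(x$main_component),
    score_strategy = x$score_strategy
  )
}
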