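#' Iteratively assign genes to localization groups by PPI-count majority
#'
#' Starting from a seed assignment of a few genes to cellular-localization
#' groups (for the retinal presets: 1 = retinal pigment epithelium, 2 =
#' photoreceptor outer segment, 3 = connecting cilium, 4 = nucleus), every
#' remaining gene is assigned to the group with which it shares the most
#' interactions among already-assigned genes. The premise is physical:
#' interacting proteins tend to reside in the same or adjacent compartments,
#' so a gene's interaction profile against located genes predicts its own
#' location.
#'
#' Rounds are batch-synchronous: within a round every unassigned gene is
#' evaluated against the assignment frozen at round start, which makes the
#' result independent of gene enumeration order. A gene with at least one
#' edge to an assigned gene takes the group with the greatest edge count;
#' a count tie falls to the greater sum of interaction confidences; a
#' residual tie defers the gene one round (the groups may have grown by
#' then) and, if it persists, resolves to the lowest tied group index with a
#' warning. Iteration stops when every gene is assigned, when a round makes
#' no progress (remaining genes have no link into any group and are reported
#' unassigned), or at `max_iterations`.
#'
#' @param network A `ppi_network`; edges are counted on this graph.
#' @param universe Character vector (or tibble with `gene` column) of genes
#'   to assign; must be a subset of the network nodes.
#' @param seeds Seed tibble with columns `gene`, `group` (see
#'   [read_seed_groups()]); seed genes must lie in `universe` and are never
#'   reassigned.
#' @param n_groups Number of groups. Defaults to the largest seeded index
#'   (at least 4 for the retinal presets if seeds use 1..4).
#' @param max_iterations Safety cap on rounds; must be >= 1.
#' @return A `localization_assignment` object whose `assignment` tibble has
#'   columns `gene`, `group`, `is_seed`, `iteration` (0 for seeds, the round
#'   number otherwise), plus `unassigned` (genes left without support) and
#'   `n_groups`.
#' @export
assign_localization <- function(network, universe, seeds,
                                n_groups = NULL, max_iterations = 100L) {
  stopifnot(is_ppi_network(network))
  if (!is.numeric(max_iterations) || max_iterations < 1) {
    abort("max_iterations must be >= 1")
  }
  universe <- unique(as_gene_vector(universe))
  missing <- setdiff(universe, network$nodes)
  if (length(missing) > 0) {
    abort(paste0("universe gene(s) absent from the network: ",
                 paste(missing, collapse = ", ")))
  }
  seeds <- as_tibble(seeds)
  stopifnot(all(c("gene", "group") %in% names(seeds)))
  seeds$gene <- normalize_gene_symbols(seeds$gene)
  seeds$group <- as.integer(seeds$group)
  bad_seed <- setdiff(seeds$gene, universe)
  if (length(bad_seed) > 0) {
    abort(paste0("seed gene(s) outside the universe: ",
                 paste(bad_seed, collapse = ", ")))
  }
  if (is.null(n_groups)) n_groups <- max(seeds$group, 4L)
  n_groups <- as.integer(n_groups)
  if (any(seeds$group < 1L | seeds$group > n_groups)) {
    abort(paste0("seed groups must lie in 1..", n_groups))
  }

  group_of <- setNames(rep(NA_integer_, length(universe)), universe)
  iter_of <- setNames(rep(NA_integer_, length(universe)), universe)
  group_of[seeds$gene] <- seeds$group
  iter_of[seeds$gene] <- 0L

  adj <- adjacency_list(network)
  deferred <- character()

  round <- 0L
  while (anyNA(group_of) && round < max_iterations) {
    round <- round + 1L
    frozen <- group_of
    todo <- sort(names(group_of)[is.na(group_of)])
    progressed <- FALSE
    newly_deferred <- character()

    for (g in todo) {
      nb <- adj[[g]]
      if (is.null(nb)) next
      nb <- nb[names(nb) %in% names(frozen)]
      grp <- frozen[names(nb)]
      ok <- !is.na(grp)
      if (!any(ok)) next
      counts <- tabulate(grp[ok], nbins = n_groups)
      best <- which(counts == max(counts))
      if (length(best) > 1) {
        conf_sum <- vapply(best, function(k) sum(nb[ok][grp[ok] == k]), 0)
        best <- best[abs(conf_sum - max(conf_sum)) < 1e-12]
      }
      if (length(best) > 1) {
        if (g %in% deferred) {
          warn(paste0(
            "assign_localization: unresolved tie for ", g,
            " between groups ", paste(best, collapse = ", "),
            "; assigned to group ", min(best)
          ))
          best <- min(best)
        } else {
          newly_deferred <- c(newly_deferred, g)
          next
        }
      }
      group_of[g] <- as.integer(best[1])
      iter_of[g] <- round
      progressed <- TRUE
    }

    deferred <- union(deferred, newly_deferred)
    if (!progressed && length(newly_deferred) == 0) break
  }

  assigned <- !is.na(group_of)
  structure(
    list(
      assignment = tibble(
        gene = names(group_of)[assigned],
        group = unname(group_of[assigned]),
        is_seed = names(group_of)[assigned] %in% seeds$gene,
        iteration = unname(iter_of[assigned])
      ) |> arrange(.data$gene),
      unassigned = sort(names(group_of)[!assigned]),
      n_groups = n_groups,
      n_rounds = round
    ),
    class = "localization_assignment"
  )
}

#' @export
print.localization_assignment <- function(x, ...) {
  cat("<localization_assignment> ", nrow(x$assignment), " genes in ",
      x$n_groups, " groups after ", x$n_rounds, " round(s); ",
      length(x$unassigned), " unassigned\n", sep = "")
  invisible(x)
}

#' Place intermediate genes with their bridged partners
#'
#' Intermediates are located with the disconnected gene they serve: each
#' inherits the group of its paired gene directly (the label is not
#' propagated further). An intermediate shared by partners in different
#' groups takes the group of the lexicographically smallest partner, with a
#' warning.
#'
#' @param assignment A `localization_assignment` covering every bridged
#'   gene.
#' @param classification A completed `gene_classification`.
#' @return The assignment with one row added (or overridden) per
#'   intermediate; inherited rows carry the partner's iteration and
#'   `is_seed = FALSE`.
#' @export
place_intermediates <- function(assignment, classification) {
  stopifnot(inherits(assignment, "localization_assignment"),
            inherits(classification, "gene_classification"))
  br <- classification$bridges
  if (nrow(br) == 0) return(assignment)
  missing <- setdiff(br$gene, assignment$assignment$gene)
  if (length(missing) > 0) {
    abort(paste0("bridged gene(s) not yet assigned to a group: ",
                 paste(missing, collapse = ", ")))
  }
  a <- assignment$assignment
  placed <- br |>
    arrange(.data$bridge, .data$gene) |>
    group_by(.data$bridge) |>
    summarise(
      partner = .data$gene[1],
      n_groups_seen = length(unique(a$group[match(.data$gene, a$gene)])),
      .groups = "drop"
    ) |>
    mutate(
      group = a$group[match(.data$partner, a$gene)],
      iteration = a$iteration[match(.data$partner, a$gene)]
    )
  shared <- placed$bridge[placed$n_groups_seen > 1]
  if (length(shared) > 0) {
    warn(paste0(
      "place_intermediates: intermediate(s) shared across groups, placed ",
      "with lexicographically smallest partner: ",
      paste(shared, collapse = ", ")
    ))
  }
  new_rows <- tibble(
    gene = placed$bridge,
    group = placed$group,
    is_seed = FALSE,
    iteration = placed$iteration
  )
  assignment$assignment <- bind_rows(
    a[!a$gene %in% new_rows$gene, ],
    new_rows
  ) |> arrange(.data$gene)
  assignment$unassigned <- setdiff(assignment$unassigned, new_rows$gene)
  assignment
}

#' Per-gene localization table
#'
#' @param x A `localization_assignment`.
#' @param ... Unused.
#' @return Tibble `gene`, `group`, `is_seed`, `iteration`; unassigned genes
#'   appear with `group = NA`.
#' @method tidy localization_assignment
#' @export
tidy.localization_assignment <- function(x, ...) {
  bind_rows(
    x$assignment,
    tibble(gene = x$unassigned, group = NA_integer_,
           is_seed = FALSE, iteration = NA_integer_)
  ) |> arrange(.data$gene)
}

#' One-row summary of a localization assignment
#'
#' @param x A `localization_assignment`.
#' @param ... Unused.
#' @return Tibble with gene counts per status and the number of rounds run.
#' @method glance localization_assignment
#' @export
glance.localization_assignment <- function(x, ...) {
  tibble(
    n_assigned = nrow(x$assignment),
    n_seeds = sum(x$assignment$is_seed),
    n_unassigned = length(x$unassigned),
    n_groups = x$n_groups,
    n_rounds = x$n_rounds
  )
}

#' Inter- and intragroup connectivity matrix
#'
#' Counts, for every unordered pair of localization groups, the interactions
#' whose endpoints fall in those groups: each edge between assigned genes is
#' counted exactly once, under the smaller group index first. Because
#' whether interactions of intermediate genes should enter the group totals
#' is a judgement call, edges with at least one intermediate endpoint are
#' additionally tallied per group in `intermediate_links` (an edge counts
#' toward every group represented among its endpoints), while `counts`
#' includes them via the intermediates' inherited groups.
#'
#' @param network A `ppi_network` (typically the augmented network).
#' @param assignment A `localization_assignment` covering every endpoint of
#'   the network's edges.
#' @param classification Optional completed `gene_classification`, used to
#'   identify intermediate genes for `intermediate_links`.
#' @return A `connectivity_matrix` object: `counts` is a symmetric
#'   `n_groups x n_groups` integer matrix; `intermediate_links` a per-group
#'   integer vector.
#' @export
connectivity_matrix <- function(network, assignment, classification = NULL) {
  stopifnot(is_ppi_network(network),
            inherits(assignment, "localization_assignment"))
  a <- assignment$assignment
  group_of <- setNames(a$group, a$gene)
  e <- network$edges
  endpoints <- unique(c(e$from, e$to))
  missing <- setdiff(endpoints, names(group_of))
  if (length(missing) > 0) {
    abort(paste0("edge endpoint(s) without a group assignment: ",
                 paste(missing, collapse = ", ")))
  }
  k <- assignment$n_groups
  counts <- matrix(0L, k, k, dimnames = list(seq_len(k), seq_len(k)))
  g1 <- group_of[e$from]
  g2 <- group_of[e$to]
  lo <- pmin(g1, g2)
  hi <- pmax(g1, g2)
  for (i in seq_along(lo)) {
    counts[lo[i], hi[i]] <- counts[lo[i], hi[i]] + 1L
  }
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]

  intermediate_links <- setNames(rep(0L, k), seq_len(k))
  intermediates <- character()
  if (!is.null(classification)) {
    intermediates <- unique(classification$bridges$bridge)
    touches <- e$from %in% intermediates | e$to %in% intermediates
    for (i in which(touches)) {
      for (grp in unique(c(g1[i], g2[i]))) {
        intermediate_links[grp] <- intermediate_links[grp] + 1L
      }
    }
  }

  structure(
    list(counts = counts, intermediate_links = intermediate_links,
         n_groups = k, intermediates = intermediates),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", x$n_groups, " groups, ",
      sum(x$counts[upper.tri(x$counts, diag = TRUE)]),
      " edges among assigned genes\n", sep = "")
  m <- x$counts
  m[upper.tri(m)] <- NA
  print(m, na.print = "-")
  if (any(x$intermediate_links > 0)) {
    cat("edges touching intermediates, per group:\n")
    print(x$intermediate_links)
  }
  invisible(x)
}

#' Long-format connectivity counts
#'
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @return Tibble `group_a`, `group_b` (`group_a <= group_b`), `n_edges`,
#'   `intragroup` — one row per unordered group pair.
#' @method tidy connectivity_matrix
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  k <- x$n_groups
  pairs <- which(upper.tri(x$counts, diag = TRUE), arr.ind = TRUE)
  tibble(
    group_a = as.integer(pairs[, "row"]),
    group_b = as.integer(pairs[, "col"]),
    n_edges = as.integer(x$counts[pairs]),
    intragroup = pairs[, "row"] == pairs[, "col"]
  ) |> arrange(.data$group_a, .data$group_b)
}
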