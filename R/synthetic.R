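#' Describe a synthetic PPI scenario
#'
#' Defines a planted-partition ("stochastic block"-style) PPI network with
#' planted disease genes, planted isolated disease genes and planted bridge
#' genes, the minimal model of the assumptions the protocol rests on:
#' localization groups are dense inside and sparse between, the known
#' disease genes form one module, and each isolated disease gene is one
#' intermediate away from that module.
#'
#' The defaults mirror the retinitis-pigmentosa study conditions at full
#' scale: 159 disease genes of which 10 are isolated, four localization
#' blocks, roughly 20% of the connected disease genes seeded with their true
#' group, and a confidence threshold of 0.400.
#'
#' Construction, given a base RNG seed:
#' * each block gets `block_sizes[b]` genes, the first
#'   `n_disease_per_block[b]` of them disease genes;
#' * background edges appear independently with probability `p_intra` inside
#'   a block and `p_inter` between blocks (isolated disease genes take part
#'   in no background edge);
#' * planted structure guarantees the study's premises irrespective of the
#'   random draw: a spanning cycle inside each block (blocks are connected),
#'   a path through each block's disease genes (they are directly
#'   connected), and — when `p_inter > 0` — one disease–disease edge between
#'   consecutive blocks (the disease module is one component);
#' * each isolated disease gene is wired to `bridges_per_isolated` dedicated
#'   bridge genes, and each bridge to `1 + bridge_extra_links` disease genes
#'   of block 1 (the main block); isolated genes and their bridges belong to
#'   block 1 in the ground truth;
#' * planted edges draw confidences from `confidence_range`, whose lower end
#'   must clear `threshold` so planted structure survives thresholding;
#'   background edges draw from `background_confidence_range` and may fall
#'   below it.
#'
#' @param n_groups Number of localization blocks (default 4).
#' @param block_sizes Genes per block, length `n_groups`.
#' @param p_intra,p_inter Within- and between-block background edge
#'   probabilities; `p_inter <= p_intra`.
#' @param n_disease_per_block Disease genes per block.
#' @param n_isolated Number of isolated disease genes.
#' @param bridges_per_isolated Planted bridges per isolated gene (default 1,
#'   which makes bridge recovery analytically forced).
#' @param bridge_extra_links Extra main-block links per bridge beyond the
#'   guaranteed one.
#' @param seed_fraction Fraction of each block's connected disease genes
#'   emitted as localization seeds, in `(0, 1]`.
#' @param confidence_range Length-2 numeric, confidence law (uniform) for
#'   planted edges; use `c(c, c)` for a fixed confidence.
#' @param background_confidence_range Confidence law for background edges.
#' @param threshold Confidence threshold the pipeline will use.
#' @param rng_seed Integer seed making the draw reproducible.
#' @return A `synthetic_scenario` list of validated parameters.
#' @export
synthetic_scenario <- function(n_groups = 4L,
                               block_sizes = c(60L, 60L, 60L, 60L),
                               p_intra = 0.25,
                               p_inter = 0.02,
                               n_disease_per_block = c(38L, 37L, 37L, 37L),
                               n_isolated = 10L,
                               bridges_per_isolated = 1L,
                               bridge_extra_links = 1L,
                               seed_fraction = 0.2,
                               confidence_range = c(0.5, 0.95),
                               background_confidence_range = c(0.15, 0.95),
                               threshold = 0.4,
                               rng_seed = 1L) {
  stopifnot(
    n_groups >= 1, length(block_sizes) == n_groups, all(block_sizes >= 1),
    length(n_disease_per_block) == n_groups,
    all(n_disease_per_block >= 0),
    p_intra >= 0, p_intra <= 1, p_inter >= 0, p_inter <= 1,
    p_inter <= p_intra,
    n_isolated >= 0, bridges_per_isolated >= 1, bridge_extra_links >= 0,
    seed_fraction > 0, seed_fraction <= 1,
    length(confidence_range) == 2,
    confidence_range[1] <= confidence_range[2],
    confidence_range[1] >= threshold, confidence_range[2] <= 1,
    threshold >= 0, threshold <= 1
  )
  if (any(n_disease_per_block > block_sizes)) {
    abort("block sizes smaller than the requested disease genes")
  }
  if (n_isolated > 0 && n_disease_per_block[1] < 1 + bridge_extra_links) {
    abort("block 1 needs enough disease genes to anchor the planted bridges")
  }
  structure(
    list(
      n_groups = as.integer(n_groups),
      block_sizes = as.integer(block_sizes),
      p_intra = p_intra, p_inter = p_inter,
      n_disease_per_block = as.integer(n_disease_per_block),
      n_isolated = as.integer(n_isolated),
      bridges_per_isolated = as.integer(bridges_per_isolated),
      bridge_extra_links = as.integer(bridge_extra_links),
      seed_fraction = seed_fraction,
      confidence_range = confidence_range,
      background_confidence_range = background_confidence_range,
      threshold = threshold,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_scenario"
  )
}

rand_conf <- function(n, range) runif(n, range[1], range[2])

#' Generate a synthetic PPI network with ground truth
#'
#' Draws the network described by a [synthetic_scenario()]. The result
#' carries the raw edge table (so files written by [write_scenario()] can be
#' re-read through the normal readers), the thresholded `ppi_network`, and
#' the planted ground truth.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A list with elements `edges` (tibble `gene_a`, `gene_b`,
#'   `confidence`), `network` (a `ppi_network` at the scenario threshold),
#'   and `truth`: `block_of` (tibble `gene`, `block`), `disease_genes`
#'   (tibble `gene`, `isolated`), `planted_bridges` (tibble `gene`,
#'   `bridge`), `seeds` (tibble `gene`, `group`).
#' @examples
#' sc <- synthetic_scenario(block_sizes = rep(12L, 4),
#'                          n_disease_per_block = rep(4L, 4),
#'                          n_isolated = 2L, rng_seed = 7L)
#' gen <- generate_scenario(sc)
#' glance(gen$network)
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  set.seed(s$rng_seed)

  blocks <- lapply(seq_len(s$n_groups), function(b) {
    sprintf("B%dG%03d", b, seq_len(s$block_sizes[b]))
  })
  disease_in_block <- lapply(seq_len(s$n_groups), function(b) {
    head(blocks[[b]], s$n_disease_per_block[b])
  })
  isolated <- if (s$n_isolated > 0) sprintf("ISO%03d", seq_len(s$n_isolated)) else character()
  bridges <- if (s$n_isolated > 0) {
    matrix(sprintf("BRG%03d", seq_len(s$n_isolated * s$bridges_per_isolated)),
           nrow = s$n_isolated, byrow = TRUE)
  } else {
    matrix(character(), nrow = 0, ncol = s$bridges_per_isolated)
  }

  edge_acc <- list()
  add_edges <- function(a, b, conf) {
    if (length(a) > 0) {
      edge_acc[[length(edge_acc) + 1L]] <<- tibble(
        gene_a = a, gene_b = b, confidence = conf
      )
    }
  }

  # background edges, block by block; isolated genes take part in none
  for (b1 in seq_len(s$n_groups)) {
    m <- blocks[[b1]]
    if (length(m) >= 2) {
      pr <- t(utils::combn(m, 2))
      pick <- rbinom(nrow(pr), 1, s$p_intra) == 1
      add_edges(pr[pick, 1], pr[pick, 2],
                rand_conf(sum(pick), s$background_confidence_range))
    }
    if (b1 < s$n_groups && s$p_inter > 0) {
      for (b2 in (b1 + 1L):s$n_groups) {
        pr <- expand.grid(a = blocks[[b1]], b = blocks[[b2]],
                          stringsAsFactors = FALSE)
        pick <- rbinom(nrow(pr), 1, s$p_inter) == 1
        add_edges(pr$a[pick], pr$b[pick],
                  rand_conf(sum(pick), s$background_confidence_range))
      }
    }
  }

  # planted structure: block-spanning cycles, disease paths, module link-up
  for (b in seq_len(s$n_groups)) {
    m <- blocks[[b]]
    if (length(m) >= 2) {
      nxt <- c(m[-1], m[1])
      keep <- seq_len(if (length(m) == 2) 1L else length(m))
      add_edges(m[keep], nxt[keep],
                rand_conf(length(keep), s$confidence_range))
    }
    d <- disease_in_block[[b]]
    if (length(d) >= 2) {
      add_edges(d[-length(d)], d[-1],
                rand_conf(length(d) - 1L, s$confidence_range))
    }
  }
  if (s$p_inter > 0 && s$n_groups >= 2) {
    for (b in seq_len(s$n_groups - 1L)) {
      d1 <- disease_in_block[[b]]
      d2 <- disease_in_block[[b + 1L]]
      if (length(d1) > 0 && length(d2) > 0) {
        add_edges(d1[length(d1)], d2[1],
                  rand_conf(1, s$confidence_range))
      }
    }
  }

  # planted bridges: isolated gene -- bridge -- main-block disease gene(s)
  anchors <- disease_in_block[[1]]
  for (i in seq_len(s$n_isolated)) {
    for (j in seq_len(s$bridges_per_isolated)) {
      br <- bridges[i, j]
      add_edges(isolated[i], br, rand_conf(1, s$confidence_range))
      n_anchor <- min(1L + s$bridge_extra_links, length(anchors))
      idx <- ((i + j - 2L + seq_len(n_anchor) - 1L) %% length(anchors)) + 1L
      add_edges(rep(br, n_anchor), anchors[idx],
                rand_conf(n_anchor, s$confidence_range))
    }
  }

  edges <- bind_rows(edge_acc)
  all_nodes <- c(unlist(blocks), isolated, as.vector(t(bridges)))
  network <- build_ppi_network(edges, threshold = s$threshold,
                               nodes = all_nodes)

  block_of <- bind_rows(
    tibble(gene = unlist(blocks),
           block = rep(seq_len(s$n_groups), s$block_sizes)),
    tibble(gene = isolated, block = 1L),
    if (nrow(bridges) > 0) {
      tibble(gene = as.vector(t(bridges)), block = 1L)
    }
  )

  disease_genes <- tibble(
    gene = c(unlist(disease_in_block), isolated),
    isolated = c(rep(FALSE, sum(s$n_disease_per_block)),
                 rep(TRUE, s$n_isolated))
  )

  planted_bridges <- if (s$n_isolated > 0) {
    tibble(gene = rep(isolated, each = s$bridges_per_isolated),
           bridge = as.vector(t(bridges)))
  } else {
    tibble(gene = character(), bridge = character())
  }

  # seeds: deterministic spread over each block's connected disease genes
  seeds <- bind_rows(lapply(seq_len(s$n_groups), function(b) {
    d <- disease_in_block[[b]]
    k <- max(1L, ceiling(length(d) * s$seed_fraction))
    if (length(d) == 0) return(NULL)
    idx <- unique(round(seq(1, length(d), length.out = k)))
    tibble(gene = d[idx], group = b)
  }))

  list(
    edges = edges,
    network = network,
    truth = list(
      block_of = block_of,
      disease_genes = disease_genes,
      planted_bridges = planted_bridges,
      seeds = seeds
    ),
    scenario = s
  )
}

#' Write a generated scenario to files consumable by the pipeline
#'
#' Emits `edges.tsv` (generic TSV dialect), `genes.txt` (disease gene list),
#' `seeds.tsv` (seed localization groups) and `truth.json` (planted ground
#' truth) into a directory, so the full protocol — including the command
#' line — can run against it.
#'
#' @param generated Result of [generate_scenario()].
#' @param dir Output directory, created if needed.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory ", sQuote(dir)))
  paths <- c(
    edges = file.path(dir, "edges.tsv"),
    genes = file.path(dir, "genes.txt"),
    seeds = file.path(dir, "seeds.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_edge_table(generated$edges, paths[["edges"]])
  readr::write_lines(
    c("# synthetic disease gene list", generated$truth$disease_genes$gene),
    paths[["genes"]]
  )
  readr::write_tsv(generated$truth$seeds, paths[["seeds"]], col_names = FALSE)
  jsonlite::write_json(
    list(
      block_of = generated$truth$block_of,
      disease_genes = generated$truth$disease_genes,
      planted_bridges = generated$truth$planted_bridges,
      seeds = generated$truth$seeds,
      scenario = unclass(generated$scenario)
    ),
    paths[["truth"]],
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
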