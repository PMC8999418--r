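#' Run the full candidate-gene discovery protocol
#'
#' Executes the whole pipeline from files: read the disease gene list and
#' scored edge table, reconcile identifiers, build the thresholded network,
#' classify connectivity, select intermediates, assemble the augmented
#' network and — when a seed file is given — propagate localization groups,
#' place intermediates with their partners and compute the connectivity
#' matrix. All artifacts plus a JSON run manifest (input paths and MD5
#' hashes, parameters, package version, counts) are written to `out_dir`.
#'
#' @param config Either a named list or a path to a YAML file with entries:
#'   `genes` (path, required), `edges` (path, required), `dialect`
#'   (`"generic_tsv"` default, or `"string_links"`), `aliases` (path,
#'   optional), `seeds` (path, optional), `threshold` (default 0.4),
#'   `score_strategy` (default `"two_leg_sum"`), `max_iterations` (default
#'   100), `out_dir` (default `"bridgenet-out"`).
#' @param out_dir Overrides the config's `out_dir` when given.
#' @return Invisibly, a list with the in-memory results (`network`,
#'   `recognition`, `classification`, `augmented`, `assignment`, `matrix`),
#'   the `manifest`, and the written `paths`.
#' @export
run_protocol <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("missing input: config file ", sQuote(config)))
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (req in c("genes", "edges")) {
    if (is.null(config[[req]])) abort(paste0("missing input: ", req))
    if (!file.exists(config[[req]])) {
      abort(paste0("missing input: ", req, " file ",
                   sQuote(config[[req]]), " not found"))
    }
  }
  dialect <- config$dialect %||% "generic_tsv"
  threshold <- config$threshold %||% 0.4
  score_strategy <- config$score_strategy %||% "two_leg_sum"
  max_iterations <- config$max_iterations %||% 100L
  out_dir <- out_dir %||% config$out_dir %||% "bridgenet-out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  gene_list <- read_gene_list(config$genes)
  edges <- read_edge_table(config$edges, dialect = dialect)
  aliases <- if (!is.null(config$aliases)) read_alias_map(config$aliases)
  network <- build_ppi_network(edges, threshold = threshold)

  recognition <- apply_alias_map(gene_list, aliases,
                                 node_universe = network$nodes)
  recognized <- recognition$gene[recognition$status != "unrecognized"]

  classification <- classify_connectivity(network, recognized)
  classification <- select_intermediates(network, classification,
                                         score_strategy = score_strategy)
  augmented <- assemble_augmented_network(network, classification)

  assignment <- NULL
  cmatrix <- NULL
  if (!is.null(config$seeds)) {
    seeds <- read_seed_groups(config$seeds)
    assignment <- assign_localization(
      network, universe = augmented$nodes, seeds = seeds,
      max_iterations = max_iterations
    )
    assignment <- place_intermediates(assignment, classification)
    cmatrix <- connectivity_matrix(augmented, assignment, classification)
  }

  paths <- write_protocol_artifacts(out_dir, recognition, classification,
                                    augmented, assignment, cmatrix)

  counts <- as.list(glance(classification))
  manifest <- list(
    tool = "bridgenet",
    version = as.character(utils::packageVersion("bridgenet")),
    inputs = lapply(
      Filter(Negate(is.null),
             config[c("genes", "edges", "aliases", "seeds")]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))
    ),
    parameters = list(
      dialect = dialect, threshold = threshold,
      score_strategy = score_strategy, max_iterations = max_iterations
    ),
    counts = c(
      list(
        n_input = nrow(recognition),
        n_recognized = length(recognized),
        n_unrecognized = sum(recognition$status == "unrecognized")
      ),
      counts[c("n_direct", "n_bridged", "n_unbridgeable",
               "n_intermediates", "main_component_size")],
      if (!is.null(assignment)) list(
        n_assigned = nrow(assignment$assignment),
        n_unassigned = length(assignment$unassigned),
        n_rounds = assignment$n_rounds
      )
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, manifest = manifest_path)

  invisible(list(
    network = network, recognition = recognition,
    classification = classification, augmented = augmented,
    assignment = assignment, matrix = cmatrix,
    manifest = manifest, paths = paths
  ))
}

write_protocol_artifacts <- function(out_dir, recognition, classification,
                                     augmented, assignment, cmatrix) {
  paths <- c(
    recognition = file.path(out_dir, "recognition.tsv"),
    classification = file.path(out_dir, "classification.tsv"),
    network = file.path(out_dir, "augmented_network.graphml")
  )
  readr::write_tsv(recognition, paths[["recognition"]])
  readr::write_tsv(tidy(classification), paths[["classification"]])
  write_annotated_network(augmented, classification, assignment,
                          paths[["network"]], format = "graphml")
  if (!is.null(assignment)) {
    paths <- c(paths,
               assignment = file.path(out_dir, "localization.tsv"),
               matrix = file.path(out_dir, "connectivity_matrix.tsv"))
    readr::write_tsv(tidy(assignment), paths[["assignment"]])
    readr::write_tsv(tidy(cmatrix), paths[["matrix"]])
  }
  paths
}
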