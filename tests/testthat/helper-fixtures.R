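# Small fixtures built in code, shared across test files.

toy_edges <- function() {
  tibble::tibble(
    gene_a = c("A", "B", "C", "X", "M", "M"),
    gene_b = c("B", "C", "A", "M", "A", "B"),
    confidence = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.45)
  )
}

# triangle A-B-C (input), isolated input X bridged by M
toy_network <- function(threshold = 0.4) {
  build_ppi_network(toy_edges(), threshold = threshold)
}

toy_genes <- function() c("A", "B", "C", "X")

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

small_scenario <- function(rng_seed = 1L, ...) {
  args <- list(
    block_sizes = rep(15L, 4),
    n_disease_per_block = c(6L, 5L, 5L, 5L),
    n_isolated = 4L,
    p_intra = 0.3,
    p_inter = 0.03,
    rng_seed = rng_seed
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_scenario, args)
}
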