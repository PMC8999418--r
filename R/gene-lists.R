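#' Normalize gene symbols
#'
#' Gene symbols are case-insensitive in common usage (databases mix forms such
#' as `TTC8a` and `TTC8`), so all identifiers entering the package are
#' uppercased and stripped of surrounding whitespace. After normalization a
#' symbol must match `[A-Z0-9_.-]+`; anything else is rejected rather than
#' silently mangled.
#'
#' @param x Character vector of raw gene symbols.
#' @return Character vector of normalized symbols, same length as `x`.
#' @examples
#' normalize_gene_symbols(c(" rho ", "Abca4"))
#' @export
normalize_gene_symbols <- function(x) {
  out <- toupper(trimws(as.character(x)))
  bad <- out[!grepl("^[A-Z0-9_.-]+$", out)]
  if (length(bad) > 0) {
    abort(paste0(
      "invalid gene symbol(s) after normalization: ",
      paste(sQuote(unique(bad)), collapse = ", ")
    ))
  }
  out
}

#' Read a disease gene list
#'
#' Reads a plain-text gene list, one symbol per line. Lines starting with `#`
#' are comments and blank lines are skipped. Symbols are normalized
#' (uppercased, trimmed) and de-duplicated keeping the first occurrence, so a
#' file containing both `RHO` and `rho` yields a single gene.
#'
#' @param path Path to the gene list file.
#' @param source_label Label recorded in the `source` column; defaults to the
#'   file name.
#' @return A tibble with columns `gene` (normalized symbol, file order
#'   preserved) and `source`. The number of dropped duplicates is reported
#'   via a message.
#' @export
read_gene_list <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("cannot read gene list: no such file ", sQuote(path)))
  }
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    abort("empty gene list")
  }
  genes <- normalize_gene_symbols(lines)
  dup <- duplicated(genes)
  if (any(dup)) {
    inform(paste0(
      "read_gene_list: dropped ", sum(dup), " duplicate symbol(s): ",
      paste(unique(genes[dup]), collapse = ", ")
    ))
  }
  tibble(gene = genes[!dup], source = source_label)
}

#' Read an alias map
#'
#' Two-column whitespace/tab-delimited file mapping alias symbols to canonical
#' symbols (the mechanism used to reconcile list identifiers with the edge
#' table's identifiers, e.g. `SC5DL -> SC5D`). Chains are collapsed at read
#' time so every target is itself canonical.
#'
#' @param path Path to the alias file. Lines starting with `#` are skipped.
#' @return A tibble with columns `alias` and `canonical`.
#' @export
read_alias_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read alias map: no such file ", sQuote(path)))
  }
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(alias = character(), canonical = character()))
  }
  parts <- strsplit(lines, "[ \t]+")
  n_col <- lengths(parts)
  if (any(n_col < 2)) {
    abort(paste0(
      "alias map needs 2 columns; line(s) ",
      paste(which(n_col < 2), collapse = ", "), " malformed"
    ))
  }
  alias <- normalize_gene_symbols(vapply(parts, `[[`, "", 1L))
  canonical <- normalize_gene_symbols(vapply(parts, `[[`, "", 2L))
  map <- setNames(canonical, alias)
  # collapse alias -> alias chains so targets are canonical
  for (i in seq_along(map)) {
    seen <- names(map)[i]
    while (map[[i]] %in% names(map) && !(map[[i]] %in% seen)) {
      seen <- c(seen, map[[i]])
      map[[i]] <- map[[map[[i]]]]
    }
  }
  dup <- duplicated(names(map))
  tibble(alias = names(map)[!dup], canonical = unname(map)[!dup])
}

#' Reconcile a gene list against an alias map and a node universe
#'
#' Classifies each input gene as `canonical` (already usable), `renamed`
#' (known under another symbol in the edge table; the canonical symbol is
#' substituted), or `unrecognized` (absent from both the alias map and the
#' edge table's node universe — such genes are excluded from downstream
#' analysis, mirroring symbols a PPI database simply does not know).
#'
#' @param genes A gene-list tibble from [read_gene_list()], or a character
#'   vector of symbols.
#' @param aliases Alias tibble from [read_alias_map()] (columns `alias`,
#'   `canonical`), or `NULL` for no aliasing.
#' @param node_universe Character vector of node symbols known to the edge
#'   table, or `NULL` to skip the membership check (every non-aliased gene
#'   then passes through as `canonical`).
#' @return A tibble with columns `input` (the original symbol), `gene` (the
#'   symbol to use downstream; `NA` when unrecognized) and `status`
#'   (`"canonical"`, `"renamed"` or `"unrecognized"`). Rows partition the
#'   input: one row per input gene, in order.
#' @examples
#' apply_alias_map(c("SC5DL", "RHO"),
#'                 tibble::tibble(alias = "SC5DL", canonical = "SC5D"),
#'                 node_universe = c("SC5D", "RHO"))
#' @export
apply_alias_map <- function(genes, aliases = NULL, node_universe = NULL) {
  genes <- as_gene_vector(genes)
  if (is.null(aliases)) {
    aliases <- tibble(alias = character(), canonical = character())
  }
  map <- setNames(aliases$canonical, aliases$alias)
  resolved <- ifelse(genes %in% names(map), unname(map[genes]), genes)
  status <- ifelse(genes %in% names(map), "renamed", "canonical")
  if (!is.null(node_universe)) {
    known <- resolved %in% node_universe
    status[!known] <- "unrecognized"
    resolved[!known] <- NA_character_
  }
  tibble(input = genes, gene = resolved, status = status)
}

#' Read a seed localization file
#'
#' Two-column whitespace/tab-delimited file assigning a subset of genes to
#' localization groups (by convention 1 = retinal pigment epithelium, 2 =
#' photoreceptor outer segment, 3 = connecting cilium, 4 = nucleus, although
#' any positive group indices are accepted).
#'
#' @param path Path to the seed file. Lines starting with `#` are skipped.
#' @param n_groups Number of localization groups; group indices outside
#'   `1..n_groups` are an error. Default 4.
#' @return A tibble with columns `gene` and `group` (integer).
#' @export
read_seed_groups <- function(path, n_groups = 4L) {
  if (!file.exists(path)) {
    abort(paste0("cannot read seed groups: no such file ", sQuote(path)))
  }
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) < 2)) {
    abort("seed group file needs 2 columns: gene, group")
  }
  gene <- normalize_gene_symbols(vapply(parts, `[[`, "", 1L))
  group <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(group) || any(group < 1L) || any(group > n_groups)) {
    abort(paste0("seed groups must be integers in 1..", n_groups))
  }
  if (anyDuplicated(gene)) {
    abort(paste0(
      "gene(s) seeded more than once: ",
      paste(unique(gene[duplicated(gene)]), collapse = ", ")
    ))
  }
  tibble(gene = gene, group = group)
}

# Accept either a tibble with a `gene` column or a bare character vector.
as_gene_vector <- function(genes) {
  if (is.data.frame(genes)) {
    if (!"gene" %in% names(genes)) {
      abort("gene table must have a `gene` column")
    }
    genes <- genes$gene
  }
  normalize_gene_symbols(genes)
}
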