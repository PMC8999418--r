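#' Read a scored PPI edge table
#'
#' Supports two dialects of undirected, confidence-scored edge tables:
#'
#' * `"generic_tsv"`: whitespace/tab-delimited, three columns
#'   `geneA geneB confidence`, scores on `[0, 1]` by default;
#' * `"string_links"`: the STRING protein-links flat-file dialect
#'   (space-delimited `protein1 protein2 combined_score`, integer scores on
#'   0–999 which are divided by 1000).
#'
#' A header line is auto-detected (third column not parseable as a number, or
#' a leading `#`). Self-loops are dropped with a warning that reports how
#' many. Rows whose score cannot be parsed as a number are rejected with a
#' warning naming the offending line numbers; a score that parses but falls
#' outside the declared scale is an error naming the line, since it means the
#' wrong `score_scale` was declared.
#'
#' Identifiers are normalized but otherwise kept verbatim; STRING files keyed
#' by protein IDs (e.g. `9606.ENSP...`) are reconciled with gene symbols via
#' [apply_alias_map()], not by hard-coded ID syntax.
#'
#' @param path Path to the edge table.
#' @param dialect `"generic_tsv"` (default) or `"string_links"`.
#' @param score_scale `"float_0_1"` or `"int_0_999"`. Defaults to the
#'   dialect's native scale.
#' @return A tibble with columns `gene_a`, `gene_b`, `confidence` (in
#'   `[0, 1]`). Duplicate rows for the same unordered pair are retained here
#'   and merged (by maximum confidence) in [build_ppi_network()]. The line
#'   numbers of rejected rows are attached as attribute `rejected_lines`.
#' @export
read_edge_table <- function(path,
                            dialect = c("generic_tsv", "string_links"),
                            score_scale = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(score_scale)) {
    score_scale <- if (dialect == "string_links") "int_0_999" else "float_0_1"
  }
  score_scale <- match.arg(score_scale, c("float_0_1", "int_0_999"))
  if (!file.exists(path)) {
    abort(paste0("cannot read edge table: no such file ", sQuote(path)))
  }

  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- trimws(lines[keep])

  is_comment <- startsWith(lines, "#")
  line_no <- line_no[!is_comment]
  lines <- lines[!is_comment]
  if (length(lines) == 0) {
    abort("empty edge table")
  }

  parts <- strsplit(lines, "[ \t]+")
  n_col <- lengths(parts)
  if (any(n_col < 3)) {
    abort(paste0(
      "edge table needs >= 3 columns; line(s) ",
      paste(line_no[n_col < 3], collapse = ", "), " malformed"
    ))
  }

  score_chr <- vapply(parts, `[[`, "", 3L)
  score <- suppressWarnings(as.numeric(score_chr))

  # header: first row whose score does not parse
  if (is.na(score[1])) {
    parts <- parts[-1]
    line_no <- line_no[-1]
    score <- score[-1]
    if (length(parts) == 0) abort("empty edge table")
  }

  rejected <- line_no[is.na(score)]
  if (length(rejected) > 0) {
    warn(paste0(
      "read_edge_table: rejected ", length(rejected),
      " row(s) with unparseable scores at line(s) ",
      paste(rejected, collapse = ", ")
    ))
    parts <- parts[!is.na(score)]
    line_no <- line_no[!is.na(score)]
    score <- score[!is.na(score)]
  }

  hi <- if (score_scale == "int_0_999") 999 else 1
  out_of_scale <- score < 0 | score > hi
  if (any(out_of_scale)) {
    abort(paste0(
      "score outside declared scale ", score_scale, " at line(s) ",
      paste(line_no[out_of_scale], collapse = ", ")
    ))
  }
  confidence <- if (score_scale == "int_0_999") score / 1000 else score

  gene_a <- normalize_gene_symbols(vapply(parts, `[[`, "", 1L))
  gene_b <- normalize_gene_symbols(vapply(parts, `[[`, "", 2L))

  self <- gene_a == gene_b
  if (any(self)) {
    warn(paste0("read_edge_table: dropped ", sum(self), " self-loop(s)"))
  }
  out <- tibble(
    gene_a = gene_a[!self],
    gene_b = gene_b[!self],
    confidence = confidence[!self]
  )
  attr(out, "rejected_lines") <- rejected
  out
}

#' Write an edge table in the generic TSV dialect
#'
#' @param edges Tibble with columns `gene_a`, `gene_b`, `confidence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  readr::write_tsv(
    edges[, c("gene_a", "gene_b", "confidence")],
    path,
    col_names = TRUE
  )
  invisible(path)
}
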