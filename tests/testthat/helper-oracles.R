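# Independent brute-force oracles used to cross-check the implementation.
# Deliberately written with plain loops and base R only (no igraph, no
# package internals) so they share no code path with what they verify.

# max-merge duplicate/reversed rows, drop below-threshold edges
oracle_merge_edges <- function(edges, threshold = 0) {
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(edges$confidence, key, max)
  a2 <- sub("\r.*", "", names(conf))
  b2 <- sub(".*\r", "", names(conf))
  keep <- conf >= threshold
  data.frame(a = a2[keep], b = b2[keep], confidence = unname(conf[keep]),
             stringsAsFactors = FALSE)
}

# union-find connected components; returns list of sorted member vectors,
# ordered by descending size then lexicographically smallest member
oracle_components <- function(merged, nodes) {
  parent <- seq_along(nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  keep <- merged$a %in% nodes & merged$b %in% nodes
  for (r in which(keep)) {
    ra <- find(idx[[merged$a[r]]])
    rb <- find(idx[[merged$b[r]]])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(nodes), find, 1L)
  comps <- split(nodes, roots)
  comps <- lapply(comps, sort)
  ord <- order(-vapply(comps, length, 1L), vapply(comps, `[[`, "", 1L))
  unname(comps[ord])
}

oracle_pair_conf <- function(merged, x, y) {
  hit <- (merged$a == x & merged$b == y) | (merged$a == y & merged$b == x)
  if (any(hit)) max(merged$confidence[hit]) else NA_real_
}

oracle_neighbors <- function(merged, g) {
  nb <- c(merged$b[merged$a == g], merged$a[merged$b == g])
  conf <- c(merged$confidence[merged$a == g], merged$confidence[merged$b == g])
  stats::setNames(conf, nb)
}

# full brute-force reimplementation of classify + bridge selection
oracle_classify_select <- function(edges, genes, threshold = 0.4,
                                   strategy = "two_leg_sum") {
  merged <- oracle_merge_edges(edges, threshold)
  all_nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  genes <- sort(unique(genes))

  direct <- character()
  for (g in genes) {
    nb <- names(oracle_neighbors(merged, g))
    if (any(nb %in% setdiff(genes, g))) direct <- c(direct, g)
  }
  main <- character()
  if (length(direct) > 0) {
    internal <- merged[merged$a %in% direct & merged$b %in% direct, ]
    main <- oracle_components(internal, direct)[[1]]
  }

  pending <- setdiff(genes, direct)
  bridges <- list()
  unbridgeable <- character()
  for (bg in pending) {
    best <- NULL
    for (v in setdiff(all_nodes, genes)) {
      leg1 <- oracle_pair_conf(merged, v, bg)
      if (is.na(leg1)) next
      main_conf <- oracle_neighbors(merged, v)
      main_conf <- main_conf[names(main_conf) %in% main]
      if (length(main_conf) == 0) next
      score <- round(switch(strategy,
        two_leg_sum = leg1 + max(main_conf),
        all_links_sum = leg1 + sum(main_conf),
        min_leg = min(leg1, max(main_conf))
      ), 9)
      cand <- list(bridge = v, score = score, links = length(main_conf))
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score &&
             (cand$links > best$links ||
                (cand$links == best$links && cand$bridge < best$bridge)))) {
        best <- cand
      }
    }
    if (is.null(best)) {
      unbridgeable <- c(unbridgeable, bg)
    } else {
      bridges[[bg]] <- best
    }
  }
  list(direct = sort(direct), main = main,
       bridged = as.character(sort(names(bridges))),
       bridges = vapply(bridges, `[[`, "", "bridge"),
       scores = vapply(bridges, `[[`, 0, "score"),
       unbridgeable = sort(unbridgeable))
}

# raw edge scan for the connectivity-matrix conservation check
oracle_edge_count_among <- function(network, assigned_genes) {
  e <- network$edges
  sum(e$from %in% assigned_genes & e$to %in% assigned_genes)
}

# seeded random scored edge table over n nodes
random_edge_table <- function(n_nodes, p_edge, seed,
                              conf_range = c(0.05, 1)) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  pick <- stats::runif(nrow(pairs)) < p_edge
  tibble::tibble(
    gene_a = pairs[pick, 1],
    gene_b = pairs[pick, 2],
    confidence = round(stats::runif(sum(pick), conf_range[1], conf_range[2]), 3)
  )
}
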