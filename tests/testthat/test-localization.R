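seeded_net <- function(edges, seeds, universe = NULL, ...) {
  net <- build_ppi_network(edges, threshold = 0.4)
  if (is.null(universe)) universe <- net$nodes
  assign_localization(net, universe, seeds, ...)
}

test_that("a gene joins the group it shares the most interactions with", {
  edges <- tibble::tibble(
    gene_a = c("G", "G", "G", "G"),
    gene_b = c("S2A", "S2B", "S2C", "S4A"),
    confidence = c(0.5, 0.5, 0.5, 0.99)
  )
  seeds <- tibble::tibble(gene = c("S2A", "S2B", "S2C", "S4A"),
                          group = c(2L, 2L, 2L, 4L))
  res <- seeded_net(edges, seeds)
  expect_equal(res$assignment$group[res$assignment$gene == "G"], 2L)
  expect_equal(res$assignment$iteration[res$assignment$gene == "G"], 1L)
})

test_that("a PPI-count tie falls to the greater confidence sum", {
  edges <- tibble::tibble(
    gene_a = c("G", "G"), gene_b = c("S1", "S3"),
    confidence = c(0.9, 0.5)
  )
  seeds <- tibble::tibble(gene = c("S1", "S3"), group = c(1L, 3L))
  res <- seeded_net(edges, seeds)
  expect_equal(res$assignment$group[res$assignment$gene == "G"], 1L)
})

test_that("a residual tie defers one round, then takes the lowest group", {
  edges <- tibble::tibble(
    gene_a = c("G", "G"), gene_b = c("S1", "S2"),
    confidence = c(0.7, 0.7)
  )
  seeds <- tibble::tibble(gene = c("S1", "S2"), group = c(1L, 2L))
  expect_warning(res <- seeded_net(edges, seeds), "unresolved tie")
  row <- res$assignment[res$assignment$gene == "G", ]
  expect_equal(row$group, 1L)
  expect_equal(row$iteration, 2L)  # round 1 deferred, round 2 forced
})

test_that("a deferral can resolve naturally once groups have grown", {
  # G ties between groups 1 and 2 in round 1; H joins group 2 in round 1
  # and breaks G's tie in round 2 without any forced choice
  edges <- tibble::tibble(
    gene_a = c("G", "G", "H", "G"),
    gene_b = c("S1", "S2", "S2", "H"),
    confidence = c(0.7, 0.7, 0.9, 0.8)
  )
  seeds <- tibble::tibble(gene = c("S1", "S2"), group = c(1L, 2L))
  expect_no_warning(res <- seeded_net(edges, seeds))
  row <- res$assignment[res$assignment$gene == "G", ]
  expect_equal(row$group, 2L)
  expect_equal(row$iteration, 2L)
})

test_that("seeds are never reassigned and support exists at assignment time", {
  gen <- generate_scenario(small_scenario(rng_seed = 31))
  net <- gen$network
  seeds <- gen$truth$seeds
  res <- assign_localization(net, net$nodes, seeds)
  a <- res$assignment
  expect_equal(
    a$group[match(seeds$gene, a$gene)], seeds$group
  )
  expect_true(all(a$iteration[match(seeds$gene, a$gene)] == 0L))
  # replay: every non-seed gene had >= 1 edge into its group among genes
  # assigned in strictly earlier rounds
  for (i in which(!a$is_seed)) {
    nb <- ppi_neighbors(net, a$gene[i])
    earlier <- a[match(nb$neighbor, a$gene), ]
    support <- !is.na(earlier$group) &
      earlier$group == a$group[i] & earlier$iteration < a$iteration[i]
    expect_true(any(support, na.rm = TRUE))
  }
})

test_that("genes with no path of support are reported unassigned", {
  edges <- tibble::tibble(gene_a = c("S1", "L1"), gene_b = c("G", "L2"),
                          confidence = 0.9)
  seeds <- tibble::tibble(gene = "S1", group = 1L)
  res <- seeded_net(edges, seeds)
  expect_setequal(res$unassigned, c("L1", "L2"))
  expect_equal(nrow(res$assignment), 2)
})

test_that("assignment is independent of universe enumeration order", {
  gen <- generate_scenario(small_scenario(rng_seed = 13))
  net <- gen$network
  res1 <- assign_localization(net, net$nodes, gen$truth$seeds)
  res2 <- assign_localization(net, rev(net$nodes), gen$truth$seeds)
  expect_identical(tidy(res1), tidy(res2))
})

test_that("seed and iteration validation errors are raised", {
  net <- toy_network()
  seeds <- tibble::tibble(gene = "NOPE", group = 1L)
  expect_error(assign_localization(net, net$nodes, seeds), "outside the universe")
  ok <- tibble::tibble(gene = "A", group = 1L)
  expect_error(assign_localization(net, net$nodes, ok, max_iterations = 0),
               "max_iterations")
})

test_that("intermediates inherit their partner's group", {
  net <- toy_network()
  cl <- select_intermediates(net, classify_connectivity(net, toy_genes()))
  seeds <- tibble::tibble(gene = c("A", "B", "C", "X"),
                          group = c(1L, 1L, 2L, 3L))
  res <- assign_localization(net, toy_genes(), seeds)
  placed <- place_intermediates(res, cl)
  expect_equal(placed$assignment$group[placed$assignment$gene == "M"], 3L)
  expect_false(placed$assignment$is_seed[placed$assignment$gene == "M"])
})

test_that("a shared intermediate follows its lexicographically smallest partner", {
  edges <- tibble::tibble(
    gene_a = c("A", "X", "Y", "M"),
    gene_b = c("B", "M", "M", "A"),
    confidence = c(0.9, 0.6, 0.7, 0.8)
  )
  net <- build_ppi_network(edges)
  genes <- c("A", "B", "X", "Y")
  cl <- select_intermediates(net, classify_connectivity(net, genes))
  seeds <- tibble::tibble(gene = genes, group = c(1L, 1L, 2L, 3L))
  res <- assign_localization(net, genes, seeds)
  expect_warning(placed <- place_intermediates(res, cl), "shared across groups")
  expect_equal(placed$assignment$group[placed$assignment$gene == "M"], 2L)
})

test_that("an unassigned bridged partner is an error", {
  net <- toy_network()
  cl <- select_intermediates(net, classify_connectivity(net, toy_genes()))
  seeds <- tibble::tibble(gene = c("A", "B"), group = c(1L, 2L))
  res <- assign_localization(net, c("A", "B", "C"), seeds)  # X not in universe
  expect_error(place_intermediates(res, cl), "X")
})

test_that("the connectivity matrix counts each edge once, by group pair", {
  edges <- tibble::tibble(
    gene_a = c("G1", "G2A", "G2A"),
    gene_b = c("G2A", "G2B", "G4"),
    confidence = 0.9
  )
  net <- build_ppi_network(edges)
  seeds <- tibble::tibble(gene = c("G1", "G2A", "G2B", "G4"),
                          group = c(1L, 2L, 2L, 4L))
  res <- assign_localization(net, net$nodes, seeds)
  m <- connectivity_matrix(net, res)
  expect_equal(m$counts[1, 2], 1L)
  expect_equal(m$counts[2, 2], 1L)
  expect_equal(m$counts[2, 4], 1L)
  expect_equal(sum(m$counts[upper.tri(m$counts, diag = TRUE)]), 3L)
  expect_true(isSymmetric(unname(m$counts)))
})

test_that("an empty edge set gives a zero matrix", {
  net <- build_ppi_network(
    tibble::tibble(gene_a = "A", gene_b = "B", confidence = 0.2),
    threshold = 0.4
  )
  seeds <- tibble::tibble(gene = c("A", "B"), group = c(1L, 2L))
  res <- assign_localization(net, net$nodes, seeds)
  m <- connectivity_matrix(net, res)
  expect_true(all(m$counts == 0L))
})

test_that("matrix totals equal a raw edge scan, intermediates tallied per group", {
  gen <- generate_scenario(small_scenario(rng_seed = 77))
  net <- gen$network
  genes <- gen$truth$disease_genes$gene
  cl <- select_intermediates(net, classify_connectivity(net, genes))
  aug <- assemble_augmented_network(net, cl)
  res <- assign_localization(net, aug$nodes, gen$truth$seeds)
  res <- place_intermediates(res, cl)
  m <- connectivity_matrix(aug, res, cl)

  # conservation against a brute-force scan of the raw augmented edge list
  expect_equal(sum(m$counts[upper.tri(m$counts, diag = TRUE)]),
               oracle_edge_count_among(aug, res$assignment$gene))

  # brute-force double loop over edges reproduces every cell
  want <- matrix(0L, res$n_groups, res$n_groups)
  grp <- stats::setNames(res$assignment$group, res$assignment$gene)
  for (i in seq_len(nrow(aug$edges))) {
    g1 <- grp[[aug$edges$from[i]]]
    g2 <- grp[[aug$edges$to[i]]]
    want[min(g1, g2), max(g1, g2)] <- want[min(g1, g2), max(g1, g2)] + 1L
  }
  expect_equal(m$counts[upper.tri(m$counts, diag = TRUE)],
               want[upper.tri(want, diag = TRUE)])

  # intermediate links: per group, edges touching an intermediate endpoint
  inter <- unique(cl$bridges$bridge)
  want_il <- stats::setNames(rep(0L, res$n_groups), seq_len(res$n_groups))
  for (i in seq_len(nrow(aug$edges))) {
    if (aug$edges$from[i] %in% inter || aug$edges$to[i] %in% inter) {
      for (g in unique(c(grp[[aug$edges$from[i]]], grp[[aug$edges$to[i]]]))) {
        want_il[g] <- want_il[g] + 1L
      }
    }
  }
  expect_equal(m$intermediate_links, want_il)

  # an endpoint without an assignment is an error listing the gene
  res_partial <- assign_localization(net, setdiff(aug$nodes, "ISO001"),
                                     gen$truth$seeds)
  expect_error(connectivity_matrix(aug, res_partial, cl), "ISO001")
})
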