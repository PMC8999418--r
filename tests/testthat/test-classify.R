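test_that("directly connected input genes are separated from pending ones", {
  net <- build_ppi_network(tibble::tibble(
    gene_a = "A", gene_b = "B", confidence = 0.9
  ), nodes = "C")
  cl <- classify_connectivity(net, c("A", "B", "C"))
  expect_equal(cl$genes$role, c("direct", "direct", "pending"))
  expect_equal(cl$main_component, c("A", "B"))

  tri <- build_ppi_network(tibble::tibble(
    gene_a = c("A", "B", "C"), gene_b = c("B", "C", "A"), confidence = 0.8
  ))
  cl2 <- classify_connectivity(tri, c("A", "B", "C"))
  expect_true(all(cl2$genes$role == "direct"))
})

test_that("input genes missing from the network are reported by name", {
  net <- toy_network()
  expect_error(classify_connectivity(net, c("A", "ZZZ", "QQQ")),
               "ZZZ, QQQ")
})

test_that("main component ties resolve to the lexicographically smallest gene", {
  # two 2-gene components: {P,Q} and {A,B}; tie on size -> the one with A
  net <- build_ppi_network(tibble::tibble(
    gene_a = c("P", "A"), gene_b = c("Q", "B"), confidence = 0.9
  ))
  cl <- classify_connectivity(net, c("P", "Q", "A", "B"))
  expect_equal(cl$main_component, c("A", "B"))
})

test_that("a sole valid candidate is scored from its two legs", {
  net <- toy_network()
  cl <- classify_connectivity(net, toy_genes())
  cand <- enumerate_bridge_candidates(net, "X", cl$main_component, toy_genes())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$bridge, "M")
  # conf(X,M) + best over main of conf(M, .): 0.6 + max(0.5, 0.45)
  expect_equal(cand$score, 0.6 + 0.5)
  expect_equal(cand$links_to_main, 2L)
})

test_that("candidates must be non-input genes with a link into the main component", {
  # Y's only neighbor is input gene X (outside main) -> no candidates
  net <- build_ppi_network(tibble::tibble(
    gene_a = c("A", "X"), gene_b = c("B", "Y"), confidence = 0.9
  ))
  cl <- classify_connectivity(net, c("A", "B", "X", "Y"))
  expect_equal(nrow(enumerate_bridge_candidates(net, "Y", cl$main_component,
                                                c("A", "B", "X", "Y"))), 0)
  # M links X only to X itself, never to the main component -> invalid
  net2 <- build_ppi_network(tibble::tibble(
    gene_a = c("A", "X"), gene_b = c("B", "M"), confidence = 0.9
  ))
  cl2 <- classify_connectivity(net2, c("A", "B", "X"))
  expect_equal(nrow(enumerate_bridge_candidates(net2, "X", cl2$main_component,
                                                c("A", "B", "X"))), 0)
})

test_that("candidate ranking is deterministic: score, links to main, symbol", {
  edges <- tibble::tibble(
    gene_a = c("A", "B", "X", "X", "X", "M1", "M2", "M2", "M3"),
    gene_b = c("B", "C", "M1", "M2", "M3", "A", "A", "B", "C"),
    confidence = c(0.9, 0.9, 0.5, 0.5, 0.7, 0.6, 0.3, 0.3, 0.4)
  )
  net <- build_ppi_network(edges, threshold = 0.2)
  genes <- c("A", "B", "C", "X")
  cl <- classify_connectivity(net, genes)
  cand <- enumerate_bridge_candidates(net, "X", cl$main_component, genes)
  # M1: 0.5+0.6, M3: 0.7+0.4 tie at 1.1; M3 wins? links M1=1, M2=2, M3=1
  # tie between M1 (1.1, 1 link) and M3 (1.1, 1 link) -> lexicographic M1
  expect_equal(cand$bridge, c("M1", "M3", "M2"))
  expect_equal(cand$score, c(1.1, 1.1, 0.8))
})

test_that("selection completes the classification and may share intermediates", {
  net <- toy_network()
  cl <- select_intermediates(net, classify_connectivity(net, toy_genes()))
  expect_equal(cl$genes$role[cl$genes$gene == "X"], "bridged")
  expect_equal(cl$bridges$bridge, "M")
  expect_equal(glance(cl)$n_unbridgeable, 0)

  # two isolated genes whose only valid candidate is the same hub
  edges <- tibble::tibble(
    gene_a = c("A", "X", "Y", "M"),
    gene_b = c("B", "M", "M", "A"),
    confidence = c(0.9, 0.6, 0.7, 0.8)
  )
  net2 <- build_ppi_network(edges)
  cl2 <- select_intermediates(net2, classify_connectivity(net2, c("A", "B", "X", "Y")))
  expect_equal(sort(cl2$bridges$gene), c("X", "Y"))
  expect_equal(unique(cl2$bridges$bridge), "M")
  expect_equal(glance(cl2)$n_intermediates, 1)
})

test_that("genes with no valid candidate become unbridgeable", {
  net <- build_ppi_network(
    tibble::tibble(gene_a = "A", gene_b = "B", confidence = 0.9),
    nodes = "X"
  )
  cl <- select_intermediates(net, classify_connectivity(net, c("A", "B", "X")))
  expect_equal(cl$genes$role[cl$genes$gene == "X"], "unbridgeable")
  expect_equal(nrow(cl$bridges), 0)
})

test_that("selected bridges touch their gene and the main component at threshold", {
  for (seed in c(2, 5, 9)) {
    gen <- generate_scenario(small_scenario(rng_seed = seed))
    net <- gen$network
    genes <- gen$truth$disease_genes$gene
    cl <- select_intermediates(net, classify_connectivity(net, genes))
    roles <- cl$genes$role
    expect_equal(sum(roles == "direct") + sum(roles == "bridged") +
                   sum(roles == "unbridgeable"), length(genes))
    for (i in seq_len(nrow(cl$bridges))) {
      b <- cl$bridges$bridge[i]
      nb <- ppi_neighbors(net, b)
      expect_true(cl$bridges$gene[i] %in% nb$neighbor)
      expect_true(any(nb$neighbor %in% cl$main_component))
      expect_true(all(nb$confidence >= net$threshold))
    }
  }
})

test_that("classification and selection agree with brute-force enumeration", {
  for (seed in 1:25) {
    edges <- random_edge_table(30, 0.08, seed)
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    if (length(nodes) < 8) next
    genes <- nodes[seq(1, length(nodes), by = 3)]
    net <- build_ppi_network(edges, 0.3, nodes = nodes)
    cl <- select_intermediates(net, classify_connectivity(net, genes))
    want <- oracle_classify_select(edges, genes, threshold = 0.3)
    expect_equal(sort(cl$genes$gene[cl$genes$role == "direct"]), want$direct)
    expect_equal(sort(cl$main_component), sort(want$main))
    expect_equal(cl$bridges$gene, want$bridged)
    expect_equal(unname(cl$bridges$bridge), unname(want$bridges[want$bridged]))
    expect_equal(sort(cl$genes$gene[cl$genes$role == "unbridgeable"]),
                 want$unbridgeable)
  }
})

test_that("identical inputs give byte-identical classifications", {
  gen <- generate_scenario(small_scenario(rng_seed = 42))
  run <- function() {
    cl <- select_intermediates(
      gen$network,
      classify_connectivity(gen$network, gen$truth$disease_genes$gene)
    )
    tidy(cl)
  }
  expect_identical(run(), run())
})

test_that("the augmented network reconnects every bridged gene", {
  gen <- generate_scenario(small_scenario(rng_seed = 8))
  net <- gen$network
  genes <- gen$truth$disease_genes$gene
  cl <- select_intermediates(net, classify_connectivity(net, genes))
  aug <- assemble_augmented_network(net, cl)
  expect_setequal(aug$nodes, c(genes, unique(cl$bridges$bridge)))
  comp <- network_components(aug)
  main_plus <- c(cl$main_component, cl$bridges$gene, cl$bridges$bridge)
  expect_equal(length(unique(comp$component[comp$gene %in% main_plus])), 1L)
})
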