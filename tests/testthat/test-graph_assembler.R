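test_that("flat graph has one node per gene and d = 5 + k + 2", {
  st3 <- tiny_study(k_variant = 3L)   # ROSMAP-like block inventory
  g3 <- build_flat_graph(st3)
  expect_identical(g3$d, 10L)
  st1 <- tiny_study(k_variant = 1L)   # single binary-mutation block
  g1 <- build_flat_graph(st1)
  expect_identical(g1$d, 8L)
  expect_identical(nrow(g3$nodes), length(st3$genes))
  expect_true(all(g3$nodes$node_type == "gene"))
  # undirected A-B edge materializes both directions
  expect_identical(sum(g3$A != 0), 2L)
  # feature columns are ordered methyl regions, variants, rna, protein
  expect_identical(g3$feature_names[1:5],
                   paste0("methyl_", c("upstream", "distal_promoter",
                                       "proximal_promoter", "core_promoter",
                                       "downstream")))
  expect_identical(utils::tail(g3$feature_names, 2), c("rnaseq", "proteomics"))
})

test_that("multi-level graph replicates the 7-node, 6-edge motif per gene", {
  st <- tiny_study(genes = c("A", "B", "C"),
                   edges = data.frame(from = "A", to = "B", directed = FALSE))
  g <- build_multilevel_graph(st)
  n <- length(st$genes)
  p <- 2L  # one undirected PPI edge -> two directed
  expect_identical(nrow(g$nodes), 7L * n)
  expect_identical(sum(g$A != 0), 6L * n + p)

  # single-gene skeleton: 7 nodes, 6 edges
  st1 <- tiny_study(genes = "A",
                    edges = data.frame(from = character(),
                                       to = character(),
                                       directed = logical()))
  g1 <- build_multilevel_graph(st1)
  expect_identical(nrow(g1$nodes), 7L)
  expect_identical(sum(g1$A != 0), 6L)

  # every PPI edge endpoint is a protein node
  ei <- adjacency_to_edge_index(g)
  types <- g$nodes$node_type
  intra <- types[ei[, 1] + 1L] != "protein" | types[ei[, 2] + 1L] != "protein"
  ppi <- ei[!intra, , drop = FALSE]
  expect_identical(nrow(ppi), p)
  expect_true(all(types[ppi + 1L] == "protein"))

  # each gene's intra-motif wiring is identical (region_i->gene->protein)
  motifs <- lapply(seq_len(n), function(i) {
    idx <- (i - 1L) * 7L + 1:7
    g$A[idx, idx]
  })
  for (m in motifs[-1]) expect_identical(m, motifs[[1]])
  expect_identical(sum(motifs[[1]]), 6L)
  # directed flow: regions feed the gene node, the gene node the protein
  expect_identical(unname(motifs[[1]][1:5, 6]), rep(1L, 5))
  expect_identical(motifs[[1]][6, 7], 1L)

  # mirrored internal edges double the intra-gene count
  g_ui <- build_multilevel_graph(st, undirected_internal = TRUE)
  expect_identical(sum(g_ui$A != 0), 12L * n + p)
})

test_that("node assembly conserves every harmonized cell exactly once", {
  st <- tiny_study(genes = c("A", "B", "C"))
  # flat mode: the feature matrix is exactly the stacked block columns
  gf <- build_flat_graph(st)
  for (s in st$samples) {
    cells <- unlist(lapply(st$blocks, function(b) unname(b$values[, s])))
    expect_identical(sort(unname(as.vector(gf$features[[s]]))),
                     sort(unname(cells)))
  }
  # multi-level mode: each feature column lives on exactly one node type,
  # carries that block's values per gene, and is zero everywhere else
  gm <- build_multilevel_graph(st)
  d <- gm$d
  owners <- c(paste0("region_", 1:5), rep("gene", d - 6L), "protein")
  for (s in st$samples) {
    f <- gm$features[[s]]
    for (j in seq_len(d)) {
      own <- gm$nodes$node_type == owners[j]
      carried <- f[own, j]
      expect_identical(unname(carried),
                       unname(st$blocks[[gm$feature_names[j]]]$values[
                         gm$nodes$gene[own], s]))
      expect_true(all(f[!own, j] == 0))
    }
  }
})

test_that("adjacency and edge index convert losslessly", {
  A <- matrix(0L, 2, 2); A[1, 2] <- 1L
  ei <- adjacency_to_edge_index(A)
  expect_identical(unname(ei), matrix(c(0L, 1L), 1))
  expect_identical(adjacency_to_edge_index(matrix(0L, 3, 3)),
                   matrix(integer(), 0L, 2L,
                          dimnames = list(NULL, c("source", "target"))))
  set.seed(31)
  for (n in c(1L, 5L, 12L)) {
    A <- matrix(rbinom(n * n, 1, 0.3), n, n)
    storage.mode(A) <- "integer"
    ei <- adjacency_to_edge_index(A)
    expect_identical(nrow(ei), sum(A != 0))
    expect_identical(edge_index_to_adjacency(ei, n), A)
    # row-major order: sorted by (source, target)
    expect_false(is.unsorted(ei[, 1]))
  }
  expect_error(edge_index_to_adjacency(matrix(c(0L, 5L), 1), 3), "range")
})
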