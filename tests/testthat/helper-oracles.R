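# Independent brute-force oracles and tiny in-code fixtures. These
# deliberately use different code paths (tapply / explicit double loops)
# than the package internals they check.

oracle_group_mean <- function(values, groups) {
  ug <- sort(unique(groups), method = "radix")
  out <- sapply(colnames(values), function(s) {
    r <- tapply(values[, s], groups, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
    r[ug]
  })
  out <- matrix(out, nrow = length(ug), dimnames = list(ug, colnames(values)))
  out
}

oracle_group_sum <- function(values, groups) {
  ug <- sort(unique(groups), method = "radix")
  out <- sapply(colnames(values), function(s) {
    tapply(values[, s], groups, function(v) sum(v, na.rm = TRUE))[ug]
  })
  matrix(out, nrow = length(ug), dimnames = list(ug, colnames(values)))
}

# All-pairs interval overlap scan (closed intervals, same chromosome).
oracle_overlaps <- function(segments, reference) {
  hits <- list()
  for (i in seq_len(nrow(segments))) {
    for (j in seq_len(nrow(reference))) {
      if (segments$chrom[i] == reference$chrom[j] &&
          segments$start_bp[i] <= reference$end_bp[j] &&
          segments$end_bp[i] >= reference$start_bp[j]) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), 0L, 2L))
  do.call(rbind, hits)
}

# Direct interval-membership classification, written independently of
# classify_region(): explicit per-bin comparisons on the upstream magnitude.
oracle_region <- function(d) {
  vapply(d, function(x) {
    if (x >= 0 && x <= 3000) return("downstream")
    if (x < 0) {
      u <- -x
      if (u <= 50) return("core_promoter")
      if (u <= 250) return("proximal_promoter")
      if (u <= 3000) return("distal_promoter")
      if (u <= 6000) return("upstream")
    }
    "out_of_range"
  }, character(1L))
}

make_table <- function(row_ids, sample_ids, values, kind = "rnaseq",
                       namespace = "gene_symbol") {
  omics_table(matrix(values, nrow = length(row_ids),
                     dimnames = list(NULL, sample_ids)),
              kind, namespace, row_ids = row_ids, sample_ids = sample_ids)
}

make_glm <- function(genes, samples, values, kind = "rnaseq") {
  gene_level_matrix(matrix(values, nrow = length(genes),
                           dimnames = list(genes, samples)), kind = kind)
}

# Minimal harmonized study built from hand-made blocks, for graph tests.
tiny_study <- function(genes = c("A", "B", "C"), samples = c("s1", "s2"),
                       k_variant = 3L,
                       edges = data.frame(from = "A", to = "B",
                                          directed = FALSE)) {
  regions <- c("upstream", "distal_promoter", "proximal_promoter",
               "core_promoter", "downstream")
  ng <- length(genes); ns <- length(samples)
  blocks <- list()
  val <- 0
  nxt <- function() {
    val <<- val + 1
    matrix(seq_len(ng * ns) / 10 + val, ng, ns,
           dimnames = list(genes, samples))
  }
  for (r in regions) {
    blocks[[paste0("methyl_", r)]] <- gene_level_matrix(nxt(),
                                                        kind = "methylation")
  }
  vkinds <- if (k_variant == 3L) c("cnv_DEL", "cnv_DUP", "cnv_mCNV")
            else "mutation_binary"
  for (vk in vkinds) blocks[[vk]] <- gene_level_matrix(nxt(), kind = vk)
  blocks$rnaseq <- gene_level_matrix(nxt(), kind = "rnaseq")
  blocks$proteomics <- gene_level_matrix(nxt(), kind = "proteomics")
  net <- regulatory_network(edges, nodes = sort(unique(c(genes, edges$from,
                                                         edges$to)),
                                                method = "radix"))
  intersect_with_network(union_and_pad(blocks), net)
}

# Small crosswalk mirroring the published alias example.
tiny_sample_map <- function() {
  df <- data.frame(
    individual_id = c("R1822146", "R3143439", "R6879714"),
    mwas_id = c("PT-M5AF", "PT-BZBT", "PT-3PTN"),
    mrna_id = c("575_120521_2", "502_120515_1", "660_120530_1"),
    stringsAsFactors = FALSE)
  class(df) <- c("sample_id_map", "data.frame")
  df
}

# Full comparison of a pipeline result against generation-time ground truth.
expect_matches_truth <- function(res, tr) {
  expect_identical(res$study$samples, tr$samples)
  expect_identical(res$study$genes, tr$genes)
  expect_identical(res$counts$M, tr$M)
  expect_identical(res$counts$n, tr$n)
  expect_identical(res$graph$d, tr$d)
  expect_identical(nrow(res$graph$nodes), tr$n_nodes_multilevel)
  expect_identical(sum(res$graph$A != 0), tr$n_edges_multilevel)
  for (nm in names(tr$blocks)) {
    b <- res$study$blocks[[nm]]
    expect_false(is.null(b))
    expect_identical(unname(b$values), unname(tr$blocks[[nm]]$values))
    expect_identical(unname(b$mask), unname(tr$blocks[[nm]]$mask))
  }
  expect_identical(unname(res$dataset$Y),
                   unname(tr$labels[res$study$samples]))
  for (cn in names(tr$counts)) {
    expect_identical(res$counts[[cn]], tr$counts[[cn]])
  }
  expect_identical(sort(as.integer(table(res$dataset$folds))),
                   as.integer(tr$fold_sizes))
  expect_identical(attr(res$clinical, "dropped_features"),
                   tr$dropped_clinical)
}
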