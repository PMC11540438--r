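# Per-sample multi-omics signaling graph assembly.
#
# Flat mode: one node per gene, PPI edges, feature width
#   d = 5 methylation regions + k variation blocks + rnaseq + proteomics.
# Multi-level mode: per gene a 7-node motif — five promoter-region nodes,
# one gene (transcription) node, one protein node — wired
# region_i -> gene -> protein, with PPI edges between protein nodes. Every
# node's feature row is width d with zeros outside its own columns so one
# tensor serves all node types.
#
# Undirected PPI edges are materialized as two directed edges; node and
# feature-column order is deterministic (genes lexicographic, regions in
# scheme order).

# Partition the harmonized blocks into roles, in feature-column order.
.block_roles <- function(study) {
  nms <- names(study$blocks)
  methyl <- paste0("methyl_", .region_names)
  stopifnot(all(methyl %in% nms))
  variant <- nms[vapply(study$blocks,
                        function(b) is_variation_kind(b$kind), TRUE)]
  rna <- nms[vapply(study$blocks, function(b) b$kind == "rnaseq", TRUE)]
  prot <- nms[vapply(study$blocks, function(b) b$kind == "proteomics", TRUE)]
  stopifnot(length(rna) == 1L, length(prot) == 1L, length(variant) >= 1L)
  list(methyl = methyl, variant = sort_c(variant), rna = rna, prot = prot)
}

.feature_names <- function(roles) {
  c(roles$methyl, roles$variant, roles$rna, roles$prot)
}

.ppi_adjacency <- function(A, study, node_of_gene) {
  e <- study$network$edges
  if (nrow(e)) {
    fi <- node_of_gene[e$from]
    ti <- node_of_gene[e$to]
    for (k in seq_len(nrow(e))) {
      A[fi[k], ti[k]] <- 1L
      if (!e$directed[k]) A[ti[k], fi[k]] <- 1L
    }
  }
  A
}

.new_mos_graph <- function(nodes, A, d, feature_names, features, mode) {
  structure(list(nodes = nodes, A = A, d = d, feature_names = feature_names,
                 features = features, mode = mode),
            class = "mos_graph")
}

#' @export
print.mos_graph <- function(x, ...) {
  cat(sprintf("<mos_graph> mode=%s: %d nodes, %d edges, d=%d, %d samples\n",
              x$mode, nrow(x$nodes), sum(x$A != 0), x$d, length(x$features)))
  invisible(x)
}

#' Build the flat (one node per gene) graph
#'
#' @param study A `harmonized_study`.
#' @return A `mos_graph` with n nodes of type `gene`, adjacency from the
#'   induced PPI edges, feature columns ordered
#'   `[methyl_1..5, variant_1..k, rnaseq, proteomics]` and one n-by-d feature
#'   matrix per sample.
#' @export
build_flat_graph <- function(study) {
  stopifnot(inherits(study, "harmonized_study"))
  roles <- .block_roles(study)
  fn <- .feature_names(roles)
  d <- length(fn)
  n <- length(study$genes)
  nodes <- data.frame(node_id = seq_len(n) - 1L, gene = study$genes,
                      node_type = "gene", stringsAsFactors = FALSE)
  node_of_gene <- stats::setNames(seq_len(n), study$genes)
  A <- matrix(0L, n, n)
  A <- .ppi_adjacency(A, study, node_of_gene)
  features <- lapply(study$samples, function(s) {
    f <- vapply(fn, function(b) study$blocks[[b]]$values[, s], numeric(n))
    f <- matrix(f, nrow = n, dimnames = list(NULL, fn))
    f
  })
  names(features) <- study$samples
  .new_mos_graph(nodes, A, d, fn, features, "flat")
}

#' Build the multi-level (region / gene / protein) graph
#'
#' Each gene contributes a fixed 7-node motif: five promoter-region nodes
#' carrying that region's methylation value, a gene node carrying variation
#' and rnaseq features, and a protein node carrying the protein abundance.
#' Intra-gene edges run region_i -> gene and gene -> protein (6 directed
#' edges per gene; mirrored when `undirected_internal`); PPI edges connect
#' protein nodes. Node count is 7 n.
#'
#' @param study A `harmonized_study`.
#' @param undirected_internal Mirror the intra-gene edges (default FALSE).
#' @return A `mos_graph` with typed nodes `region_1..region_5`, `gene`,
#'   `protein`.
#' @export
build_multilevel_graph <- function(study, undirected_internal = FALSE) {
  stopifnot(inherits(study, "harmonized_study"))
  roles <- .block_roles(study)
  fn <- .feature_names(roles)
  d <- length(fn)
  n <- length(study$genes)
  n_nodes <- 7L * n
  types <- c(paste0("region_", 1:5), "gene", "protein")
  nodes <- data.frame(node_id = seq_len(n_nodes) - 1L,
                      gene = rep(study$genes, each = 7L),
                      node_type = rep(types, times = n),
                      stringsAsFactors = FALSE)
  base <- (seq_len(n) - 1L) * 7L           # 0-based motif offsets per gene
  gene_node <- base + 6L                   # 1-based row indices below
  prot_node <- base + 7L
  A <- matrix(0L, n_nodes, n_nodes)
  for (g in seq_len(n)) {
    for (r in 1:5) A[base[g] + r, gene_node[g]] <- 1L
    A[gene_node[g], prot_node[g]] <- 1L
  }
  if (undirected_internal) A <- A | t(A)
  storage.mode(A) <- "integer"
  node_of_protein <- stats::setNames(prot_node, study$genes)
  A <- .ppi_adjacency(A, study, node_of_protein)
  col_of <- stats::setNames(seq_along(fn), fn)
  gene_cols <- col_of[c(roles$variant, roles$rna)]
  features <- lapply(study$samples, function(s) {
    f <- matrix(0, n_nodes, d, dimnames = list(NULL, fn))
    for (r in 1:5) {
      f[base + r, col_of[roles$methyl[r]]] <-
        study$blocks[[roles$methyl[r]]]$values[, s]
    }
    for (b in c(roles$variant, roles$rna)) {
      f[gene_node, col_of[b]] <- study$blocks[[b]]$values[, s]
    }
    f[prot_node, col_of[roles$prot]] <- study$blocks[[roles$prot]]$values[, s]
    f
  })
  names(features) <- study$samples
  .new_mos_graph(nodes, A, d, fn, features, "multilevel")
}

#' Convert an adjacency matrix to edge-index form
#'
#' One row (source, target) per nonzero of A, 0-based, in row-major scan
#' order; E = number of nonzeros.
#'
#' @param graph A `mos_graph`, or a square 0/1 matrix.
#' @return Integer matrix of shape (E, 2) with columns `source`, `target`.
#' @export
adjacency_to_edge_index <- function(graph) {
  A <- if (inherits(graph, "mos_graph")) graph$A else graph
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  pos <- which(t(A) != 0)                  # column-major on t(A) = row-major on A
  src <- (pos - 1L) %/% n
  tgt <- (pos - 1L) %% n
  out <- cbind(source = as.integer(src), target = as.integer(tgt))
  if (!nrow(out)) out <- matrix(integer(), 0L, 2L,
                                dimnames = list(NULL, c("source", "target")))
  out
}

#' Rebuild an adjacency matrix from an edge index
#' @param edge_index Integer matrix (E, 2), 0-based.
#' @param n_nodes Number of nodes.
#' @return Square 0/1 integer matrix.
#' @export
edge_index_to_adjacency <- function(edge_index, n_nodes) {
  A <- matrix(0L, n_nodes, n_nodes)
  if (nrow(edge_index)) {
    if (any(edge_index < 0L) || any(edge_index >= n_nodes)) {
      stop("edge index out of range for ", n_nodes, " nodes")
    }
    A[cbind(edge_index[, 1L] + 1L, edge_index[, 2L] + 1L)] <- 1L
  }
  A
}

#' Write the node map, edge index and per-sample feature matrices
#' @param graph A `mos_graph`.
#' @param out_dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_graph <- function(graph, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nm <- file.path(out_dir, "node_map.csv")
  utils::write.csv(graph$nodes, nm, row.names = FALSE)
  ei <- file.path(out_dir, "edge_index.csv")
  utils::write.csv(as.data.frame(adjacency_to_edge_index(graph)), ei,
                   row.names = FALSE)
  fdir <- file.path(out_dir, "features")
  dir.create(fdir, showWarnings = FALSE)
  fp <- vapply(names(graph$features), function(s) {
    p <- file.path(fdir, paste0(s, ".csv"))
    utils::write.csv(as.data.frame(graph$features[[s]]), p, row.names = FALSE)
    p
  }, character(1L))
  invisible(c(nm, ei, fp))
}
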