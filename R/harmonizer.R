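# Cross-omics harmonization: reference-catalog filtering, union gene index
# with per-omics fill values (0 for methylation/rnaseq/proteomics, -1 for
# variation), and intersection with the regulatory network to fix the final
# gene set.

#' Keep only genes present in the reference catalog
#'
#' @param matrix_ A [gene_level_matrix].
#' @param reference A `reference_genome`; matching is by symbol,
#'   case-sensitive.
#' @return The matrix restricted to reference genes; errors if no gene
#'   survives.
#' @export
filter_by_reference <- function(matrix_, reference) {
  stopifnot(inherits(matrix_, "gene_level_matrix"))
  if (!nrow(reference)) stop("empty reference catalog")
  keep <- matrix_$genes %in% reference$gene_symbol
  if (!any(keep)) stop("no gene of the matrix is in the reference catalog")
  gene_level_matrix(matrix_$values[keep, , drop = FALSE], kind = matrix_$kind,
                    mask = matrix_$mask[keep, , drop = FALSE])
}

#' Reindex all gene-level blocks onto the cross-omics union gene set
#'
#' The union of all block gene sets (lexicographic) becomes the shared index.
#' Cells a block never measured — and any remaining missing cells — are
#' filled with the block's declared fill value: -1 for variation blocks, 0
#' for methylation, rnaseq and proteomics; masks mark them imputed.
#'
#' @param blocks Named list of [gene_level_matrix] blocks, all
#'   reference-filtered and sharing one sample order.
#' @return The blocks reindexed onto the union gene set; attribute `n_union`
#'   is its size.
#' @export
union_and_pad <- function(blocks) {
  stopifnot(length(blocks) >= 1L)
  union_genes <- sort_c(unique(unlist(lapply(blocks, function(b) b$genes))))
  samples <- blocks[[1L]]$samples
  for (b in blocks) stopifnot(identical(b$samples, samples))
  out <- lapply(blocks, function(b) {
    fill <- fill_value_for(b$kind)
    vals <- matrix(fill, length(union_genes), length(samples),
                   dimnames = list(union_genes, samples))
    mask <- matrix(FALSE, length(union_genes), length(samples),
                   dimnames = list(union_genes, samples))
    if (length(b$genes)) {
      i <- match(b$genes, union_genes)
      v <- b$values
      m <- b$mask & !is.na(v)
      v[!m] <- fill
      vals[i, ] <- v
      mask[i, ] <- m
    }
    gene_level_matrix(vals, kind = b$kind, mask = mask)
  })
  attr(out, "n_union") <- length(union_genes)
  out
}

#' Intersect the harmonized gene set with the regulatory network
#'
#' The final gene list is the lexicographically ordered intersection of the
#' union gene index with the network node set; the network is restricted to
#' its induced subgraph (edges with both endpoints surviving).
#'
#' @param blocks Output of [union_and_pad()].
#' @param network A [regulatory_network].
#' @param counts Optional named list of upstream stage counts to carry in the
#'   provenance record.
#' @return A `harmonized_study`: `genes` (size n), `samples` (size M),
#'   `blocks`, `network` (induced) and `counts`.
#' @export
intersect_with_network <- function(blocks, network, counts = list()) {
  union_genes <- blocks[[1L]]$genes
  final_genes <- sort_c(intersect(union_genes, network$nodes))
  if (!length(final_genes)) {
    stop("no harmonized gene overlaps the regulatory network")
  }
  e <- network$edges
  e <- e[e$from %in% final_genes & e$to %in% final_genes, , drop = FALSE]
  rownames(e) <- NULL
  blocks <- lapply(blocks, function(b) {
    i <- match(final_genes, b$genes)
    gene_level_matrix(b$values[i, , drop = FALSE], kind = b$kind,
                      mask = b$mask[i, , drop = FALSE])
  })
  counts$n_union <- length(union_genes)
  counts$n <- length(final_genes)
  counts$M <- length(blocks[[1L]]$samples)
  counts$E_induced <- nrow(e)
  structure(list(genes = final_genes, samples = blocks[[1L]]$samples,
                 blocks = blocks,
                 network = regulatory_network(e, nodes = final_genes),
                 counts = counts),
            class = "harmonized_study")
}

#' @export
print.harmonized_study <- function(x, ...) {
  cat(sprintf("<harmonized_study> %d genes x %d samples; blocks: %s; %d induced edges\n",
              length(x$genes), length(x$samples),
              paste(names(x$blocks), collapse = ", "),
              nrow(x$network$edges)))
  invisible(x)
}

#' Write harmonized blocks, gene list, induced edges and provenance counts
#' @param study A `harmonized_study`.
#' @param out_dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_harmonized <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(study$blocks)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_omics_table(study$blocks[[nm]], p, id_header = "gene")
    paths <- c(paths, p)
  }
  gl <- file.path(out_dir, "gene_list.txt")
  writeLines(study$genes, gl)
  el <- file.path(out_dir, "induced_edges.tsv")
  write_network(study$network, el)
  pv <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(study$counts, pv, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, gl, el, pv))
}
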