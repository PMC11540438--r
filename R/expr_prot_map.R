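# Transcriptomics and proteomics row-identifier normalization: Ensembl
# version stripping, protein-accession stripping, ID-to-symbol mapping and
# duplicate-symbol collapse by mean, then zero imputation of nulls.
# Fixed order: strip -> map to symbol -> dedup mean -> impute nulls.

#' Strip a trailing numeric version from a gene ID
#'
#' `ENSG00000167578.11` becomes `ENSG00000167578`; the suffix is removed only
#' when everything after the final "." is digits, so IDs like `GENE.ALPHA`
#' pass through unchanged.
#'
#' @param versioned_id Character vector.
#' @return Character vector of stable IDs.
#' @export
strip_ensembl_version <- function(versioned_id) {
  sub("\\.[0-9]+$", "", as.character(versioned_id))
}

#' Strip a protein accession tag to the gene symbol
#'
#' Keeps the substring before the first `|` (`VAMP1|P23763` becomes `VAMP1`);
#' tags without `|` pass through. An empty symbol yields NA so callers can
#' drop the row.
#'
#' @param protein_tag Character vector.
#' @return Character vector of gene symbols, NA where the symbol is empty.
#' @export
strip_protein_accession <- function(protein_tag) {
  sym <- sub("\\|.*$", "", as.character(protein_tag))
  sym <- trimws(sym)
  sym[!nzchar(sym)] <- NA_character_
  sym
}

#' Normalize a transcriptomics table's row IDs to stable gene IDs
#' @param table An [omics_table] in the `versioned_gene_id` namespace.
#' @return The table with version suffixes stripped (row count unchanged),
#'   namespace relabelled.
#' @export
normalize_transcript_ids <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  out <- table
  out$row_ids <- strip_ensembl_version(table$row_ids)
  out$row_namespace <- "versioned_gene_id"
  out
}

#' Normalize a proteomics table's row tags to gene symbols
#' @param table An [omics_table] in the `protein_tag` namespace.
#' @return The table with accession tags stripped; rows whose symbol is empty
#'   are dropped with a warning.
#' @export
normalize_protein_tags <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  sym <- strip_protein_accession(table$row_ids)
  bad <- is.na(sym)
  if (any(bad)) {
    warning(sum(bad), " protein row(s) with empty gene symbol dropped")
  }
  omics_table(table$values[!bad, , drop = FALSE], table$kind, "gene_symbol",
              row_ids = sym[!bad], sample_ids = table$sample_ids)
}

#' Map stable gene IDs to symbols through an ID-mapping table
#'
#' Rows whose ID is absent from the map are dropped and counted. Two source
#' IDs mapping to the same symbol both survive here (deduplicated by
#' [dedup_mean()]).
#'
#' @param table An [omics_table] whose row IDs are stable gene IDs.
#' @param id_map Data frame with columns `source_id` (unique) and
#'   `gene_symbol`.
#' @return The table with rows renamed to symbols.
#' @export
map_ids_to_symbols <- function(table, id_map) {
  stopifnot(inherits(table, "omics_table"))
  if (anyDuplicated(id_map$source_id)) stop("id_map source_id must be unique")
  idx <- match(table$row_ids, id_map$source_id)
  hit <- !is.na(idx)
  if (!any(hit)) {
    warning("no row ID found in the mapping table; empty table returned")
  }
  if (any(!hit)) {
    message(sum(!hit), " unmapped row(s) dropped")
  }
  if (!any(hit)) {
    # keep an explicit empty table (0 genes) rather than erroring: the
    # harmonizer will reject it if it matters
    vals <- table$values[0, , drop = FALSE]
    return(structure(list(kind = table$kind, row_namespace = "gene_symbol",
                          row_ids = character(), sample_ids = table$sample_ids,
                          values = vals), class = "omics_table"))
  }
  omics_table(table$values[hit, , drop = FALSE], table$kind, "gene_symbol",
              row_ids = id_map$gene_symbol[idx[hit]],
              sample_ids = table$sample_ids)
}

#' Collapse duplicate gene symbols by mean
#'
#' Arithmetic mean over observed values per (gene, sample); a duplicate group
#' that is all-missing in a sample stays missing (zero-imputed later by
#' [impute_nulls_zero()]). Idempotent.
#'
#' @param table An [omics_table] in the `gene_symbol` namespace.
#' @return A [gene_level_matrix] with unique gene symbols.
#' @export
dedup_mean <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  if (!length(table$row_ids)) {
    vals <- matrix(NA_real_, 0L, length(table$sample_ids),
                   dimnames = list(character(), table$sample_ids))
    return(gene_level_matrix(vals, kind = table$kind))
  }
  gene_level_matrix(group_rows_mean(table$values, table$row_ids),
                    kind = table$kind)
}

#' Replace missing cells with 0, marking them imputed
#' @param x A [gene_level_matrix].
#' @return The matrix with every NA replaced by 0.0 and mask set to imputed
#'   there.
#' @export
impute_nulls_zero <- function(x) {
  stopifnot(inherits(x, "gene_level_matrix"))
  miss <- is.na(x$values)
  x$values[miss] <- 0
  x$mask[miss] <- FALSE
  x
}
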