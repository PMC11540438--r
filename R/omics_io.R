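# Readers, writers and validated containers for every external table the
# pipeline consumes: raw omics matrices, probe annotation, reference gene
# catalog, regulatory network edge lists, clinical table and the sample-ID
# crosswalk.
#
# CSV dialect: comma-separated UTF-8, first column = row ID, header row =
# sample IDs; files ending in .tsv/.txt are read tab-separated. Missing-value
# tokens accepted on read: empty string, "NA", "NaN", "null"
# (case-insensitive); all become NA internally.

.omics_kinds <- c("methylation", "mutation_binary", "cnv_segments",
                  "rnaseq", "proteomics")
.row_namespaces <- c("probe_id", "gene_symbol", "versioned_gene_id",
                     "protein_tag", "segment")

#' Construct a raw omics table
#'
#' A dense rows-by-samples numeric matrix with a declared omics kind and
#' row-identifier namespace. Row IDs may repeat (duplicate gene rows are a
#' real feature of the inputs and are collapsed downstream); sample IDs must
#' be unique.
#'
#' @param values Numeric matrix, rows are features, columns are samples.
#' @param kind One of `"methylation"`, `"mutation_binary"`, `"cnv_segments"`,
#'   `"rnaseq"`, `"proteomics"`.
#' @param row_namespace One of `"probe_id"`, `"gene_symbol"`,
#'   `"versioned_gene_id"`, `"protein_tag"`, `"segment"`.
#' @param row_ids,sample_ids Character vectors; default to the matrix
#'   dimnames.
#' @return An object of class `omics_table` with fields `kind`,
#'   `row_namespace`, `row_ids`, `sample_ids`, `values`.
#' @export
omics_table <- function(values, kind, row_namespace,
                        row_ids = rownames(values),
                        sample_ids = colnames(values)) {
  kind <- match.arg(kind, .omics_kinds)
  row_namespace <- match.arg(row_namespace, .row_namespaces)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  row_ids <- trimws(as.character(row_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty omics table: no ", if (nrow(values) == 0L) "rows" else "samples")
  }
  if (length(row_ids) != nrow(values)) {
    stop("row_ids length (", length(row_ids), ") != number of rows (",
         nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length != number of columns")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(NULL, sample_ids)
  structure(list(kind = kind, row_namespace = row_namespace,
                 row_ids = row_ids, sample_ids = sample_ids,
                 values = values),
            class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("<omics_table> kind=%s namespace=%s: %d rows x %d samples\n",
              x$kind, x$row_namespace, length(x$row_ids),
              length(x$sample_ids)))
  invisible(x)
}

#' Gene-level matrix with a measured/imputed mask
#'
#' Genes-by-samples matrix produced by mapping/aggregation. `mask` is TRUE
#' where a cell was measured (aggregated from observed input) and FALSE where
#' it was filled by a padding rule.
#'
#' @param values Numeric matrix with unique gene symbols as rownames.
#' @param kind Character tag carried through for fill-value selection
#'   (variation blocks pad with -1, all others with 0).
#' @param mask Logical matrix, same shape; defaults to `!is.na(values)`.
#' @return An object of class `gene_level_matrix` with fields `genes`,
#'   `samples`, `values`, `mask`, `kind`.
#' @export
gene_level_matrix <- function(values, kind, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) > 0L && is.null(rownames(values))) {
    stop("gene_level_matrix needs gene rownames")
  }
  if (anyDuplicated(rownames(values))) stop("gene symbols must be unique")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  stopifnot(identical(dim(mask), dim(values)))
  dimnames(mask) <- dimnames(values)
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values, mask = mask, kind = kind),
            class = "gene_level_matrix")
}

#' @export
print.gene_level_matrix <- function(x, ...) {
  cat(sprintf("<gene_level_matrix> kind=%s: %d genes x %d samples (%d imputed cells)\n",
              x$kind, length(x$genes), length(x$samples), sum(!x$mask)))
  invisible(x)
}

# Whether a block kind carries genetic-variation semantics (pad -1, not 0).
is_variation_kind <- function(kind) {
  kind %in% c("mutation_binary", "cnv_segments", "cnv_DEL", "cnv_DUP",
              "cnv_mCNV", "variation")
}

fill_value_for <- function(kind) if (is_variation_kind(kind)) -1 else 0

.sep_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

.read_table_chr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = .sep_for(path), header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = "\"", comment.char = "", stringsAsFactors = FALSE)
}

#' Read a raw omics matrix from CSV/TSV
#'
#' First column holds row IDs, header holds sample IDs. Non-numeric cells
#' (including the missing-value tokens) become NA.
#'
#' @param path File path.
#' @inheritParams omics_table
#' @return An [omics_table].
#' @export
read_omics_table <- function(path, kind, row_namespace) {
  df <- .read_table_chr(path)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty omics table in ", path)
  row_ids <- trimws(df[[1L]])
  sample_ids <- colnames(df)[-1L]   # before subsetting: [.data.frame
                                    # uniquifies duplicate headers
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals <- matrix(as_missing_numeric(vals), nrow = nrow(df),
                 dimnames = list(NULL, sample_ids))
  omics_table(vals, kind, row_namespace, row_ids = row_ids,
              sample_ids = sample_ids)
}

# Full-precision decimal rendering so numeric round trips are bit-exact.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Write an omics table to CSV/TSV
#'
#' Numeric cells are written at full double precision, so a read-write-read
#' round trip reproduces values bit-exactly.
#'
#' @param x An [omics_table] or [gene_level_matrix].
#' @param path Output path (`.csv` or `.tsv`).
#' @param id_header Name of the row-ID column in the header.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(x, path, id_header = "row_id") {
  vals <- matrix(fmt_num(x$values), nrow = nrow(x$values),
                 dimnames = dimnames(x$values))
  ids <- if (inherits(x, "gene_level_matrix")) x$genes else x$row_ids
  df <- data.frame(ids, vals, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_header, colnames(vals))
  utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a CpG-probe annotation table
#'
#' Expects columns for the probe ID, the closest-TSS gene symbol and the
#' signed distance to that TSS in bp (negative = upstream under the default
#' convention). Duplicated probe rows keep the first occurrence with a
#' warning.
#'
#' @param path File path.
#' @param probe_col,gene_col,distance_col Column names.
#' @return A `probe_annotation` data frame with columns `probe_id`, `gene`,
#'   `distance_bp`.
#' @export
read_probe_annotation <- function(path, probe_col = "probe_id",
                                  gene_col = "closest_tss_gene",
                                  distance_col = "distance_bp") {
  df <- .read_table_chr(path)
  if (nrow(df) == 0L) stop("empty probe annotation in ", path)
  for (col in c(probe_col, gene_col)) {
    if (!col %in% colnames(df)) stop("missing column '", col, "' in ", path)
  }
  if (!distance_col %in% colnames(df)) {
    stop("missing distance column '", distance_col, "' in ", path)
  }
  ann <- data.frame(probe_id = trimws(df[[probe_col]]),
                    gene = trimws(df[[gene_col]]),
                    distance_bp = as.integer(round(as_missing_numeric(df[[distance_col]]))),
                    stringsAsFactors = FALSE)
  dup <- duplicated(ann$probe_id)
  if (any(dup)) {
    warning(sum(dup), " duplicated probe row(s) in annotation; keeping first occurrence")
    ann <- ann[!dup, , drop = FALSE]
  }
  rownames(ann) <- NULL
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Read a reference gene catalog
#'
#' Ensembl-like table of (gene_symbol, stable gene ID, chrom, start, end,
#' strand) used for annotation filtering and CNV interval assignment.
#'
#' @param path File path with columns `gene_symbol`, `gene_id`, `chrom`,
#'   `start_bp`, `end_bp`, `strand`.
#' @return A `reference_genome` data frame.
#' @export
read_reference_genome <- function(path) {
  df <- .read_table_chr(path)
  need <- c("gene_symbol", "gene_id", "chrom", "start_bp", "end_bp", "strand")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("reference catalog missing columns: ",
                         paste(miss, collapse = ", "))
  ref <- data.frame(gene_symbol = trimws(df$gene_symbol),
                    gene_id = trimws(df$gene_id),
                    chrom = trimws(df$chrom),
                    start_bp = as.integer(df$start_bp),
                    end_bp = as.integer(df$end_bp),
                    strand = trimws(df$strand),
                    stringsAsFactors = FALSE)
  if (any(ref$start_bp > ref$end_bp)) stop("reference catalog has start_bp > end_bp")
  if (anyDuplicated(ref$gene_symbol)) {
    stop("reference catalog gene symbols must be unique")
  }
  class(ref) <- c("reference_genome", "data.frame")
  ref
}

#' Construct a regulatory network
#' @param edges Data frame with character columns `from`, `to` and a logical
#'   `directed` column.
#' @param nodes Node symbols; defaults to the union of edge endpoints.
#' @return An object of class `regulatory_network` with fields `nodes` and
#'   `edges`.
#' @export
regulatory_network <- function(edges, nodes = NULL) {
  edges <- data.frame(from = trimws(as.character(edges$from)),
                      to = trimws(as.character(edges$to)),
                      directed = as.logical(edges$directed),
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort_c(unique(c(edges$from, edges$to)))
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("edge endpoints missing from node set")
  }
  # Dedup: undirected edges compare as unordered pairs, directed as ordered.
  key <- ifelse(edges$directed,
                paste(edges$from, edges$to, sep = "\r>"),
                paste(pmin(edges$from, edges$to),
                      pmax(edges$from, edges$to), sep = "\r-"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              if (all(x$edges$directed)) "directed" else "undirected"))
  invisible(x)
}

#' Read a regulatory-network edge list
#'
#' Two-column (undirected) or three-column (third column = 1/0 directed flag)
#' whitespace- or tab-delimited lines, no header. Duplicate edges are
#' deduplicated; undirected duplicates match in either orientation.
#'
#' @param path File path.
#' @param source_format `"edge_list_2col"` or `"edge_list_3col_directed"`.
#' @return A [regulatory_network].
#' @export
read_network <- function(path,
                         source_format = c("edge_list_2col",
                                           "edge_list_3col_directed")) {
  source_format <- match.arg(source_format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty network file: ", path)
  want <- if (source_format == "edge_list_2col") 2L else 3L
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, 1L) != want)
  if (length(bad)) {
    stop("malformed network line ", bad[1L], " in ", path,
         ": expected ", want, " columns")
  }
  m <- do.call(rbind, parts)
  directed <- if (want == 3L) as.integer(m[, 3L]) != 0L else rep(FALSE, nrow(m))
  regulatory_network(data.frame(from = m[, 1L], to = m[, 2L],
                                directed = directed,
                                stringsAsFactors = FALSE))
}

#' Write a regulatory network as an edge list
#' @param network A [regulatory_network].
#' @param path Output path.
#' @param three_col Write the directed flag as a third column. Defaults to
#'   TRUE when any edge is directed.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, three_col = any(network$edges$directed)) {
  e <- network$edges
  out <- if (three_col) {
    paste(e$from, e$to, as.integer(e$directed), sep = "\t")
  } else {
    paste(e$from, e$to, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a clinical table
#'
#' First column is the sample ID (unique); remaining columns are clinical
#' features, kept as character with missing tokens normalized to NA (numeric
#' interpretation is deferred to label extraction / filtering).
#'
#' @param path File path.
#' @return A `clinical_table` data frame whose first column is `sample_id`.
#' @export
read_clinical <- function(path) {
  df <- .read_table_chr(path)
  if (nrow(df) == 0L) stop("empty clinical table in ", path)
  colnames(df)[1L] <- "sample_id"
  df$sample_id <- trimws(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  for (j in seq_along(df)[-1L]) df[[j]] <- normalize_missing(df[[j]])
  rownames(df) <- NULL
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a sample-ID crosswalk
#'
#' Maps per-omics sample aliases to one stable individual ID. The first
#' column must be `individual_id` (unique); every other column is an alias
#' namespace (e.g. `mwas_id`, `mrna_id`, `cnvdata_id`).
#'
#' @param path File path.
#' @return A `sample_id_map` data frame.
#' @export
read_sample_id_map <- function(path) {
  df <- .read_table_chr(path)
  if (!"individual_id" %in% colnames(df)) {
    stop("sample map needs an 'individual_id' column")
  }
  df$individual_id <- trimws(df$individual_id)
  if (anyDuplicated(df$individual_id)) stop("individual_id must be unique")
  for (j in seq_along(df)) df[[j]] <- normalize_missing(df[[j]])
  for (col in setdiff(colnames(df), "individual_id")) {
    vals <- df[[col]][!is.na(df[[col]])]
    if (anyDuplicated(vals)) {
      stop("alias column '", col, "' maps one alias to multiple individuals")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("sample_id_map", "data.frame")
  df
}
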