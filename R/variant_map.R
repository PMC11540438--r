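# Genetic variation to gene level. Two input styles:
#   * gene-level binary mutation matrices (0 wild-type / 1 nonsilent), where
#     duplicate gene rows are collapsed by mean, and
#   * CNV segment tables (chrom/start/end + DEL/DUP/mCNV type + per-sample
#     values), where segments are assigned to every overlapping reference
#     gene and summed per (gene, sample, type).
# Variation matrices pad unmeasured cells with -1, keeping 0 a valid measured
# value (no-mutation) distinct from "not measured".

.cnv_types <- c("DEL", "DUP", "mCNV")

#' Read a CNV segment table
#'
#' CSV/TSV with columns `chrom`, `start_bp`, `end_bp`, `variation_type`
#' (DEL/DUP/mCNV) followed by one numeric column per sample.
#'
#' @param path File path.
#' @return A `cnv_segment_table` data frame; sample columns are recorded in
#'   attribute `sample_ids`.
#' @export
read_cnv_segments <- function(path) {
  df <- .read_table_chr(path)
  need <- c("chrom", "start_bp", "end_bp", "variation_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("segment table missing columns: ",
                         paste(miss, collapse = ", "))
  samples <- setdiff(colnames(df), need)
  if (!length(samples)) stop("segment table has no sample columns")
  out <- data.frame(chrom = trimws(df$chrom),
                    start_bp = as.integer(df$start_bp),
                    end_bp = as.integer(df$end_bp),
                    variation_type = trimws(df$variation_type),
                    stringsAsFactors = FALSE)
  if (any(out$start_bp > out$end_bp)) stop("segment with start_bp > end_bp")
  bad <- setdiff(unique(out$variation_type), .cnv_types)
  if (length(bad)) stop("unknown variation type(s): ", paste(bad, collapse = ", "))
  for (s in samples) out[[s]] <- as_missing_numeric(df[[s]])
  attr(out, "sample_ids") <- samples
  class(out) <- c("cnv_segment_table", "data.frame")
  out
}

#' Collapse duplicate gene rows of a binary mutation matrix by mean
#'
#' Rows must be gene symbols with values in \{0, 1\} (or missing); other
#' values are kept with a warning. Duplicated genes are averaged over the
#' observed values, so collapsed cells may be fractional.
#'
#' @param mutations An [omics_table] of kind `"mutation_binary"` in the
#'   `gene_symbol` namespace.
#' @return A [gene_level_matrix] of kind `"mutation_binary"` with unique genes.
#' @export
aggregate_binary_mutations <- function(mutations) {
  stopifnot(inherits(mutations, "omics_table"),
            mutations$row_namespace == "gene_symbol")
  v <- mutations$values
  odd <- !is.na(v) & !(v %in% c(0, 1))
  if (any(odd)) {
    warning(sum(odd), " mutation value(s) outside {0,1,missing}; kept as-is")
  }
  gene_level_matrix(group_rows_mean(v, mutations$row_ids),
                    kind = "mutation_binary")
}

#' Assign CNV segments to overlapping reference genes
#'
#' A segment maps to every reference gene it overlaps by at least 1 bp on the
#' same chromosome (closed 1-based intervals, strand ignored). Segments
#' overlapping no gene are dropped and counted; segments on chromosomes
#' absent from the reference are dropped with a warning. Overlap search uses
#' GenomicRanges.
#'
#' @param segments A `cnv_segment_table`.
#' @param reference A `reference_genome`.
#' @param nearest_only If TRUE keep only the gene with the largest overlap
#'   per segment (default FALSE: all overlapped genes).
#' @return The segment table with a `gene` column, one row per
#'   (segment, overlapped gene); attribute `n_dropped` counts unassigned
#'   segments.
#' @export
assign_gene_by_interval <- function(segments, reference, nearest_only = FALSE) {
  stopifnot(inherits(segments, "cnv_segment_table"))
  samples <- attr(segments, "sample_ids")
  off_chrom <- !(segments$chrom %in% unique(reference$chrom))
  if (any(off_chrom)) {
    warning(sum(off_chrom), " segment(s) on chromosome(s) absent from the ",
            "reference dropped: ",
            paste(unique(segments$chrom[off_chrom]), collapse = ", "))
  }
  seg <- segments[!off_chrom, , drop = FALSE]
  if (!nrow(seg)) {
    out <- cbind(seg[0, , drop = FALSE], gene = character())
    attr(out, "sample_ids") <- samples
    attr(out, "n_dropped") <- nrow(segments)
    class(out) <- c("cnv_segment_table", "data.frame")
    return(out)
  }
  seg_gr <- GenomicRanges::GRanges(
    seqnames = seg$chrom,
    ranges = IRanges::IRanges(start = seg$start_bp, end = seg$end_bp))
  ref_gr <- GenomicRanges::GRanges(
    seqnames = reference$chrom,
    ranges = IRanges::IRanges(start = reference$start_bp,
                              end = reference$end_bp))
  hits <- GenomicRanges::findOverlaps(seg_gr, ref_gr, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (nearest_only && length(qi)) {
    ow <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(seg_gr)[qi], IRanges::ranges(ref_gr)[si]))
    keep <- unlist(lapply(split(seq_along(qi), qi),
                          function(ii) ii[which.max(ow[ii])]))
    qi <- qi[keep]; si <- si[keep]
  }
  out <- seg[qi, , drop = FALSE]
  out$gene <- reference$gene_symbol[si]
  rownames(out) <- NULL
  attr(out, "sample_ids") <- samples
  attr(out, "n_dropped") <- nrow(segments) - length(unique(qi))
  class(out) <- c("cnv_segment_table", "data.frame")
  out
}

#' Sum gene-assigned CNV segments per variation type
#'
#' cell(gene, sample, type) = sum of that gene's same-type segment values
#' (missing segment values contribute nothing). Always returns the three
#' per-type blocks DEL, DUP, mCNV; a type with no records yields an empty
#' block before unification.
#'
#' @param annotated A `cnv_segment_table` with a `gene` column.
#' @return Named list of three [gene_level_matrix] blocks (`cnv_DEL`,
#'   `cnv_DUP`, `cnv_mCNV` kinds).
#' @export
aggregate_cnv_by_type <- function(annotated) {
  stopifnot("gene" %in% colnames(annotated))
  samples <- attr(annotated, "sample_ids")
  blocks <- list()
  for (ty in .cnv_types) {
    sel <- annotated$variation_type == ty
    if (!any(sel)) {
      vals <- matrix(NA_real_, 0L, length(samples),
                     dimnames = list(character(), samples))
    } else {
      vals <- group_rows_sum(
        as.matrix(annotated[sel, samples, drop = FALSE]),
        annotated$gene[sel])
    }
    blocks[[paste0("cnv_", ty)]] <- gene_level_matrix(vals,
                                                      kind = paste0("cnv_", ty))
  }
  blocks
}

#' Unify variation blocks onto the union gene set with -1 padding
#'
#' All per-type blocks (or the single mutation block) are reindexed onto the
#' lexicographic union of their gene sets; cells for genes missing from a
#' block get -1 with mask = imputed. Measured cells (including measured 0s)
#' are unchanged.
#'
#' @param matrices Named list of variation [gene_level_matrix] blocks.
#' @return The list reindexed onto the shared gene set.
#' @export
unify_variant_genes <- function(matrices) {
  union_genes <- sort_c(unique(unlist(lapply(matrices, function(b) b$genes))))
  lapply(matrices, function(b) {
    samples <- b$samples
    vals <- matrix(-1, length(union_genes), length(samples),
                   dimnames = list(union_genes, samples))
    mask <- matrix(FALSE, length(union_genes), length(samples),
                   dimnames = list(union_genes, samples))
    if (length(b$genes)) {
      i <- match(b$genes, union_genes)
      v <- b$values
      m <- b$mask & !is.na(v)
      v[!m] <- -1
      vals[i, ] <- v
      mask[i, ] <- m
    }
    gene_level_matrix(vals, kind = b$kind, mask = mask)
  })
}
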