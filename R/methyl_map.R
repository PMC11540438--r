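# CpG-probe methylation to gene level: five TSS-anchored promoter regions,
# mean aggregation per (gene, region), zero-padded union of region gene sets.
#
# Window: -6 kb to +3 kb around the TSS. Upstream magnitudes bin as
# core (0,50], proximal (50,250], distal (250,3000], upstream (3000,6000];
# downstream covers [0,+3000], so a probe at the TSS itself (distance 0) is
# downstream. Half-open upstream bins make the five regions a partition of
# the window; anything outside is out_of_range and excluded.

.region_names <- c("upstream", "distal_promoter", "proximal_promoter",
                   "core_promoter", "downstream")

#' Five-region promoter scheme around the TSS
#'
#' @param upstream_negative Sign convention of annotation distances: TRUE
#'   (default) means negative = upstream of the TSS.
#' @return A `region_scheme` object listing the five regions and their
#'   signed-distance intervals (bp).
#' @export
region_scheme <- function(upstream_negative = TRUE) {
  structure(list(
    regions = .region_names,
    # upstream-magnitude breaks for the four upstream bins
    upstream_breaks = c(core_promoter = 50L, proximal_promoter = 250L,
                        distal_promoter = 3000L, upstream = 6000L),
    downstream_max = 3000L,
    upstream_negative = upstream_negative
  ), class = "region_scheme")
}

#' Classify a signed TSS distance into a promoter region
#'
#' Vectorized. Returns one of the five region labels or `"out_of_range"` for
#' each distance; every in-window distance maps to exactly one region.
#'
#' @param distance_bp Integer vector of signed distances to the closest TSS.
#' @param scheme A [region_scheme()].
#' @return Character vector of region labels.
#' @export
classify_region <- function(distance_bp, scheme = region_scheme()) {
  d <- as.numeric(distance_bp)
  if (!scheme$upstream_negative) d <- -d
  out <- rep("out_of_range", length(d))
  down <- !is.na(d) & d >= 0 & d <= scheme$downstream_max
  out[down] <- "downstream"
  up <- !is.na(d) & d < 0
  u <- -d
  b <- scheme$upstream_breaks
  out[up & u <= b["core_promoter"]] <- "core_promoter"
  out[up & u > b["core_promoter"] & u <= b["proximal_promoter"]] <- "proximal_promoter"
  out[up & u > b["proximal_promoter"] & u <= b["distal_promoter"]] <- "distal_promoter"
  out[up & u > b["distal_promoter"] & u <= b["upstream"]] <- "upstream"
  out
}

#' Aggregate probe methylation to gene level per promoter region
#'
#' Probes are joined to the annotation, classified into the five regions, and
#' averaged per (gene, region, sample), ignoring missing probe values.
#' Unannotated and out-of-range probes are dropped and counted. Each region
#' block contains only genes with at least one in-region probe; gene sets are
#' unified later by [unify_region_genes()].
#'
#' @param methylation An [omics_table] of kind `"methylation"` with probe rows.
#' @param annotation A `probe_annotation`.
#' @param scheme A [region_scheme()].
#' @return A `regionized_methylation` object: list of five
#'   [gene_level_matrix] blocks (named by region) plus a `disposition` data
#'   frame logging every probe's region or drop reason.
#' @export
aggregate_region_means <- function(methylation, annotation,
                                   scheme = region_scheme()) {
  stopifnot(inherits(methylation, "omics_table"))
  idx <- match(methylation$row_ids, annotation$probe_id)
  disposition <- data.frame(
    probe_id = methylation$row_ids,
    gene = ifelse(is.na(idx), NA_character_, annotation$gene[idx]),
    distance_bp = ifelse(is.na(idx), NA_integer_, annotation$distance_bp[idx]),
    stringsAsFactors = FALSE)
  disposition$region <- ifelse(
    is.na(idx), "unannotated",
    classify_region(disposition$distance_bp, scheme))
  keep <- !is.na(idx) & disposition$region %in% .region_names
  if (!any(keep)) stop("no probe survives annotation and range filtering")
  blocks <- list()
  for (r in .region_names) {
    sel <- keep & disposition$region == r
    if (!any(sel)) {
      vals <- matrix(NA_real_, 0L, length(methylation$sample_ids),
                     dimnames = list(character(), methylation$sample_ids))
    } else {
      vals <- group_rows_mean(methylation$values[sel, , drop = FALSE],
                              disposition$gene[sel])
    }
    blocks[[r]] <- gene_level_matrix(vals, kind = "methylation")
  }
  structure(list(blocks = blocks, disposition = disposition,
                 n_dropped = sum(!keep)),
            class = "regionized_methylation")
}

#' @export
print.regionized_methylation <- function(x, ...) {
  n <- vapply(x$blocks, function(b) length(b$genes), 1L)
  cat("<regionized_methylation> genes per region: ",
      paste(sprintf("%s=%d", names(n), n), collapse = ", "),
      sprintf(" (%d probes dropped)\n", x$n_dropped))
  invisible(x)
}

#' Unify region gene sets with zero padding
#'
#' Reindexes all five region blocks onto the union of their gene sets
#' (lexicographic). Cells for genes absent from a region — and cells whose
#' probes were all missing — are set to 0.0 with mask = imputed; measured
#' cells are never altered. The union size is the harmonized methylation row
#' count (attribute `n_union`).
#'
#' @param regionized A `regionized_methylation` from
#'   [aggregate_region_means()].
#' @return A `regionized_methylation` whose five blocks share one gene index.
#' @export
unify_region_genes <- function(regionized) {
  blocks <- regionized$blocks
  union_genes <- sort_c(unique(unlist(lapply(blocks, function(b) b$genes))))
  samples <- blocks[[1L]]$samples
  blocks <- lapply(blocks, function(b) {
    vals <- matrix(0, length(union_genes), length(samples),
                   dimnames = list(union_genes, samples))
    mask <- matrix(FALSE, length(union_genes), length(samples),
                   dimnames = list(union_genes, samples))
    if (length(b$genes)) {
      i <- match(b$genes, union_genes)
      v <- b$values
      m <- b$mask & !is.na(v)
      v[!m] <- 0
      vals[i, ] <- v
      mask[i, ] <- m
    }
    gene_level_matrix(vals, kind = "methylation", mask = mask)
  })
  out <- structure(list(blocks = blocks, disposition = regionized$disposition,
                        n_dropped = regionized$n_dropped),
                   class = "regionized_methylation")
  attr(out, "n_union") <- length(union_genes)
  out
}

#' Write the five region-level matrices and the probe-disposition log
#' @param regionized A `regionized_methylation`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_regionized <- function(regionized, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (r in names(regionized$blocks)) {
    p <- file.path(out_dir, paste0("methylation_", r, ".csv"))
    write_omics_table(regionized$blocks[[r]], p, id_header = "gene")
    paths <- c(paths, p)
  }
  dl <- file.path(out_dir, "probe_disposition.csv")
  utils::write.csv(regionized$disposition, dl, row.names = FALSE)
  invisible(c(paths, dl))
}
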