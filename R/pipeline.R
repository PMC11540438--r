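# End-to-end orchestration: raw tables -> alias resolution -> sample
# alignment -> per-omics gene-level mapping -> reference filter -> union +
# padding -> network intersection -> mos-graph -> exportable dataset.

#' Rewrite a CNV segment table's sample columns to individual IDs
#'
#' Same contract as [resolve_aliases()] but for the per-sample value columns
#' of a segment table.
#'
#' @param segments A `cnv_segment_table`.
#' @param id_map A `sample_id_map`.
#' @param alias_column Alias namespace of the segment sample columns.
#' @return The segment table with sample columns renamed; unmapped columns
#'   dropped with a message.
#' @export
resolve_segment_aliases <- function(segments, id_map, alias_column) {
  stopifnot(inherits(segments, "cnv_segment_table"))
  if (!alias_column %in% colnames(id_map)) {
    stop("alias column '", alias_column, "' not in sample map")
  }
  samples <- attr(segments, "sample_ids")
  lut <- id_map$individual_id
  names(lut) <- id_map[[alias_column]]
  lut <- lut[!is.na(names(lut))]
  hit <- samples %in% names(lut)
  if (!any(hit)) stop("no segment sample maps through '", alias_column, "'")
  if (any(!hit)) {
    message(sum(!hit), " segment sample(s) without a crosswalk entry dropped")
  }
  new_ids <- unname(lut[samples[hit]])
  if (anyDuplicated(new_ids)) stop("ambiguous segment sample aliases")
  meta <- c("chrom", "start_bp", "end_bp", "variation_type",
            intersect("gene", colnames(segments)))
  out <- segments[, c(meta, samples[hit]), drop = FALSE]
  colnames(out) <- c(meta, new_ids)
  attr(out, "sample_ids") <- new_ids
  class(out) <- c("cnv_segment_table", "data.frame")
  out
}

.restrict_omics <- function(table, samples) {
  omics_table(table$values[, match(samples, table$sample_ids), drop = FALSE],
              table$kind, table$row_namespace, row_ids = table$row_ids,
              sample_ids = samples)
}

.restrict_segments <- function(segments, samples) {
  meta <- setdiff(colnames(segments), attr(segments, "sample_ids"))
  out <- segments[, c(meta, samples), drop = FALSE]
  attr(out, "sample_ids") <- samples
  class(out) <- c("cnv_segment_table", "data.frame")
  out
}

#' Run the full study pipeline on in-memory inputs
#'
#' Executes every stage in order: alias resolution through the sample
#' crosswalk, intersection of omics and clinical sample sets (lexicographic
#' order), clinical feature filtering (> `max_missing_fraction` missing),
#' label extraction with label-missing samples dropped, per-omics gene-level
#' mapping (five-region methylation means; CNV interval assignment and
#' per-type sums or binary-mutation means; transcript/protein ID
#' normalization with duplicate means and zero imputation), reference-catalog
#' filtering, cross-omics union with declared fill values, regulatory-network
#' intersection, graph assembly and dataset packaging.
#'
#' @param inputs Named list: `methylation`, `rnaseq`, `proteomics`
#'   ([omics_table]s), `probe_annotation`, either `cnv_segments` or
#'   `mutation` (per `variant_mode`), `id_map` (source_id/gene_symbol),
#'   `clinical`, `sample_map`, `reference`, `network`, `label_column`,
#'   `class_map`, alias column names (`methyl_alias`, `rna_alias`,
#'   `prot_alias`, `variant_alias`) and optionally `scheme`.
#' @param mode Graph mode, `"multilevel"` (default) or `"flat"`.
#' @param k,seed Fold count and shuffle seed for [make_folds()].
#' @param max_missing_fraction Clinical feature filter threshold.
#' @return List with `study` (`harmonized_study`), `graph` (`mos_graph`),
#'   `dataset` (`graph_dataset`), `labels`, `clinical` and `counts`.
#' @export
run_study_pipeline <- function(inputs, mode = c("multilevel", "flat"),
                               k = 5L, seed = 42L,
                               max_missing_fraction = 0.30) {
  mode <- match.arg(mode)
  sm <- inputs$sample_map
  scheme <- inputs$scheme %||% region_scheme()
  variant_mode <- inputs$variant_mode %||%
    (if (!is.null(inputs$cnv_segments)) "cnv" else "mutation")

  meth <- resolve_aliases(inputs$methylation, sm,
                          inputs$methyl_alias %||% "mwas_id")
  rna <- resolve_aliases(inputs$rnaseq, sm, inputs$rna_alias %||% "mrna_id")
  prot <- resolve_aliases(inputs$proteomics, sm,
                          inputs$prot_alias %||% "projid")
  if (variant_mode == "cnv") {
    seg <- resolve_segment_aliases(inputs$cnv_segments, sm,
                                   inputs$variant_alias %||% "cnvdata_id")
    variant_samples <- attr(seg, "sample_ids")
  } else {
    mut <- resolve_aliases(inputs$mutation, sm,
                           inputs$variant_alias %||% "cnvdata_id")
    variant_samples <- mut$sample_ids
  }

  sets <- list(meth$sample_ids, rna$sample_ids, prot$sample_ids,
               variant_samples, inputs$clinical$sample_id)
  common <- sort_c(Reduce(intersect, sets))
  if (!length(common)) stop("empty sample intersection across omics and clinical")

  clin <- inputs$clinical[match(common, inputs$clinical$sample_id), ,
                          drop = FALSE]
  rownames(clin) <- NULL
  class(clin) <- c("clinical_table", "data.frame")
  clin <- filter_clinical_features(clin, max_missing_fraction)
  labels <- extract_labels(clin, inputs$label_column, inputs$class_map)
  final_samples <- labels$sample_id
  if (!length(final_samples)) stop("no sample carries a usable label")
  M <- length(final_samples)

  meth <- .restrict_omics(meth, final_samples)
  rna <- .restrict_omics(rna, final_samples)
  prot <- .restrict_omics(prot, final_samples)

  counts <- list(n_e0 = length(meth$row_ids), n_t0 = length(rna$row_ids),
                 n_p0 = length(prot$row_ids),
                 M_common = length(common), M = M)

  regionized <- unify_region_genes(
    aggregate_region_means(meth, inputs$probe_annotation, scheme))
  methyl_blocks <- regionized$blocks
  names(methyl_blocks) <- paste0("methyl_", names(methyl_blocks))
  counts$n_e1 <- attr(regionized, "n_union")

  if (variant_mode == "cnv") {
    seg <- .restrict_segments(seg, final_samples)
    counts$n_g0 <- nrow(seg)
    annotated <- assign_gene_by_interval(seg, inputs$reference)
    variant_blocks <- unify_variant_genes(aggregate_cnv_by_type(annotated))
  } else {
    mut <- .restrict_omics(mut, final_samples)
    counts$n_g0 <- length(mut$row_ids)
    variant_blocks <- unify_variant_genes(
      list(mutation = aggregate_binary_mutations(mut)))
  }
  counts$n_g1 <- length(variant_blocks[[1L]]$genes)

  rna_glm <- impute_nulls_zero(dedup_mean(
    map_ids_to_symbols(normalize_transcript_ids(rna), inputs$id_map)))
  prot_glm <- impute_nulls_zero(dedup_mean(normalize_protein_tags(prot)))
  counts$n_t1 <- length(rna_glm$genes)
  counts$n_p1 <- length(prot_glm$genes)

  blocks <- c(methyl_blocks, variant_blocks,
              list(rnaseq = rna_glm, proteomics = prot_glm))
  blocks <- lapply(blocks, filter_by_reference,
                   reference = inputs$reference)
  counts$n_e2 <- length(blocks[["methyl_upstream"]]$genes)
  counts$n_g2 <- length(blocks[[names(variant_blocks)[1L]]]$genes)
  counts$n_t2 <- length(blocks$rnaseq$genes)
  counts$n_p2 <- length(blocks$proteomics$genes)

  padded <- union_and_pad(blocks)
  counts$n3 <- attr(padded, "n_union")
  counts$n_reg <- length(inputs$network$nodes)
  counts$E_reg <- nrow(inputs$network$edges)

  study <- intersect_with_network(padded, inputs$network, counts)
  graph <- if (mode == "multilevel") build_multilevel_graph(study)
           else build_flat_graph(study)
  dataset <- build_graph_dataset(study, graph, labels, k = k, seed = seed)
  list(study = study, graph = graph, dataset = dataset, labels = labels,
       clinical = clin, counts = study$counts)
}

#' Run the pipeline from a YAML configuration of file paths
#'
#' The config names every input file and its role; relative paths resolve
#' against the config's directory. See the packaged example written by
#' [write_study()] for the schema.
#'
#' @param config_path Path to a YAML config.
#' @param ... Passed on to [run_study_pipeline()] (`mode`, `k`, `seed`, ...).
#' @return As [run_study_pipeline()].
#' @export
run_pipeline_config <- function(config_path, ...) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  p <- function(rel) if (startsWith(rel, "/")) rel else file.path(base, rel)
  variant_mode <- cfg$variant$mode %||% "cnv"
  inputs <- list(
    methylation = read_omics_table(p(cfg$methylation$path), "methylation",
                                   "probe_id"),
    methyl_alias = cfg$methylation$alias_column %||% "mwas_id",
    probe_annotation = read_probe_annotation(p(cfg$probe_annotation$path)),
    rnaseq = read_omics_table(p(cfg$rnaseq$path), "rnaseq",
                              "versioned_gene_id"),
    rna_alias = cfg$rnaseq$alias_column %||% "mrna_id",
    id_map = utils::read.csv(p(cfg$id_map$path), stringsAsFactors = FALSE,
                             colClasses = "character"),
    proteomics = read_omics_table(p(cfg$proteomics$path), "proteomics",
                                  "protein_tag"),
    prot_alias = cfg$proteomics$alias_column %||% "projid",
    clinical = read_clinical(p(cfg$clinical$path)),
    sample_map = read_sample_id_map(p(cfg$sample_map$path)),
    reference = read_reference_genome(p(cfg$reference$path)),
    network = read_network(p(cfg$network$path),
                           cfg$network$format %||% "edge_list_2col"),
    label_column = cfg$label$column,
    class_map = as.character(cfg$label$classes),
    variant_mode = variant_mode,
    variant_alias = cfg$variant$alias_column %||% "cnvdata_id")
  if (variant_mode == "cnv") {
    inputs$cnv_segments <- read_cnv_segments(p(cfg$variant$path))
  } else {
    inputs$mutation <- read_omics_table(p(cfg$variant$path),
                                        "mutation_binary", "gene_symbol")
  }
  run_study_pipeline(inputs, ...)
}
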