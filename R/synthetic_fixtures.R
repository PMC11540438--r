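# Synthetic toy studies with construction-time ground truth.
#
# The generator emulates every input the pipeline consumes — probe-level
# methylation with a TSS annotation, CNV segments (or binary mutations),
# versioned-ID transcriptomics with an ID map, accession-tagged proteomics,
# a reference gene catalog, a PPI edge list, a clinical table and a sample-ID
# crosswalk — at toy scale, deliberately planting every awkward feature of
# the real inputs: duplicate rows, versioned IDs, accession tags,
# out-of-range and unannotated probes, unmapped IDs, partial sample overlap,
# junk aliases, clinical missingness and label-missing samples.
#
# GroundTruth is computed by forward bookkeeping during generation
# (straightforward set algebra and group-by arithmetic over the planted
# values), never by calling the pipeline, so end-to-end tests compare two
# independent computations.

#' Specification of a synthetic study
#'
#' Defaults define the standard toy study: 30 genes, 12 core samples, all
#' three CNV types, all five promoter regions, planted duplicates and
#' missingness in every layer.
#'
#' @param n_genes Gene universe size (>= 8).
#' @param n_samples Core sample count shared by every layer.
#' @param seed RNG seed; the fixture is byte-identical under the same seed.
#' @param variant_mode `"cnv"` (segment table, three types) or `"mutation"`
#'   (gene-level binary matrix).
#' @param probes_per_gene In-range probes per methylation gene.
#' @param out_of_range_fraction Extra probes planted outside the -6kb/+3kb
#'   window, as a fraction of in-range probes.
#' @param methyl_gene_fraction,rna_gene_fraction,prot_gene_fraction,variant_gene_fraction
#'   Fraction of the universe measured by each layer.
#' @param n_ref_dropout Genes deliberately absent from the reference catalog.
#' @param rna_dup_genes,prot_dup_genes Genes given duplicate rows.
#' @param rna_unmapped_rows Transcript rows whose ID is absent from the map.
#' @param value_missing_rate Per-cell missing rate in the value matrices.
#' @param extra_samples_per_omics Samples private to each omics layer.
#' @param clinical_extra_samples Samples present only in the clinical table.
#' @param label_missing_samples Core samples with a missing label.
#' @param clinical_feature_missing_rate Missing fraction planted in the
#'   to-be-dropped clinical feature (> 0.30).
#' @param network_gene_fraction,network_density Node coverage and edge
#'   density of the synthetic PPI network.
#' @param label_classes Ordered class values of the label column.
#' @param folds,fold_seed Cross-validation parameters carried in the config.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 30L, n_samples = 12L, seed = 1L,
                         variant_mode = c("cnv", "mutation"),
                         probes_per_gene = 4L, out_of_range_fraction = 0.15,
                         methyl_gene_fraction = 0.85,
                         rna_gene_fraction = 0.9,
                         prot_gene_fraction = 0.7,
                         variant_gene_fraction = 0.6,
                         n_ref_dropout = 3L, rna_dup_genes = 3L,
                         prot_dup_genes = 2L, rna_unmapped_rows = 2L,
                         value_missing_rate = 0.05,
                         extra_samples_per_omics = 2L,
                         clinical_extra_samples = 2L,
                         label_missing_samples = 1L,
                         clinical_feature_missing_rate = 0.4,
                         network_gene_fraction = 0.8,
                         network_density = 0.15,
                         label_classes = c("0", "1"),
                         folds = 5L, fold_seed = 42L) {
  variant_mode <- match.arg(variant_mode)
  fracs <- c(out_of_range_fraction, methyl_gene_fraction, rna_gene_fraction,
             prot_gene_fraction, variant_gene_fraction, value_missing_rate,
             clinical_feature_missing_rate, network_gene_fraction,
             network_density)
  if (any(fracs < 0 | fracs > 1)) stop("all rates must lie in [0, 1]")
  if (n_genes < 8L) stop("n_genes must be >= 8")
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (n_samples - label_missing_samples < folds) {
    stop("infeasible spec: fewer labelled samples than folds")
  }
  structure(as.list(environment()), class = "fixture_spec")
}

# mean over observed planted values per (gene, sample); all-missing -> 0
# imputed. Independent bookkeeping, not the pipeline's group-by.
.truth_mean_block <- function(rows_by_gene, values, samples) {
  genes <- sort(names(rows_by_gene), method = "radix")
  v <- matrix(0, length(genes), length(samples),
              dimnames = list(genes, samples))
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (g in genes) {
    for (s in samples) {
      obs <- values[rows_by_gene[[g]], s]
      obs <- obs[!is.na(obs)]
      if (length(obs)) {
        v[g, s] <- sum(obs) / length(obs)
        m[g, s] <- TRUE
      }
    }
  }
  list(values = v, mask = m)
}

# embed a per-omics truth block into the final gene index with a fill value
.truth_embed <- function(block, final_genes, samples, fill) {
  v <- matrix(fill, length(final_genes), length(samples),
              dimnames = list(final_genes, samples))
  m <- matrix(FALSE, length(final_genes), length(samples),
              dimnames = list(final_genes, samples))
  keep <- intersect(rownames(block$values), final_genes)
  v[keep, ] <- block$values[keep, samples, drop = FALSE]
  m[keep, ] <- block$mask[keep, samples, drop = FALSE]
  list(values = v, mask = m)
}

.rand_values <- function(n_rows, ids, cols, gen, miss_rate) {
  v <- matrix(gen(n_rows * length(cols)), n_rows, length(cols),
              dimnames = list(ids, cols))
  if (miss_rate > 0) {
    v[stats::runif(length(v)) < miss_rate] <- NA_real_
  }
  v
}

#' Generate a complete synthetic study with ground truth
#'
#' @param spec A [fixture_spec()].
#' @return List with `inputs` (ready for [run_study_pipeline()]), `truth`
#'   (the analytically expected aligned samples, final gene set, counts,
#'   harmonized block matrices with masks, labels, d and node/edge counts)
#'   and `spec`.
#' @export
gen_study <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, .gen_study_impl(spec))
}

.gen_study_impl <- function(spec) {
  ## ---- gene universe and reference catalog -------------------------------
  special <- c("LINC01128", "NR5A2", "VAMP1")
  n_other <- spec$n_genes - 3L
  others <- sprintf("G%03d", seq_len(n_other))
  genes <- c(special, others)
  chrom <- c("chr1", "chr1", "chr2",
             ifelse(seq_len(n_other) %% 2L == 1L, "chr1", "chr2"))
  start <- c(825138L, 950000L, 200000L, 1000000L + seq_len(n_other) * 20000L)
  end <- start + 7999L
  end[1L] <- 859446L  # LINC01128 spans the worked-example segment interval
  end[2L] <- 958000L
  # designated overlapping pair on chr2 (others 2 and 4)
  start[3L + 4L] <- start[3L + 2L] + 4000L
  end[3L + 4L] <- start[3L + 4L] + 7999L
  gene_id <- sprintf("ENSG%011d", seq_along(genes))
  ref_drop <- sample(others[-c(2L, 4L)], spec$n_ref_dropout)
  ref_keep <- !(genes %in% ref_drop)
  reference <- data.frame(gene_symbol = genes[ref_keep],
                          gene_id = gene_id[ref_keep],
                          chrom = chrom[ref_keep],
                          start_bp = start[ref_keep], end_bp = end[ref_keep],
                          strand = rep_len(c("+", "-"), sum(ref_keep)),
                          stringsAsFactors = FALSE)
  class(reference) <- c("reference_genome", "data.frame")
  gene_tbl <- data.frame(gene = genes, gene_id = gene_id, chrom = chrom,
                         start = start, end = end, stringsAsFactors = FALSE)

  ## ---- samples and crosswalk ---------------------------------------------
  core <- c("R1822146", sprintf("R%07d", 1000000L + seq_len(spec$n_samples - 1L)))
  xs <- spec$extra_samples_per_omics
  extras <- list(methyl = sprintf("R%07d", 2000000L + seq_len(xs)),
                 variant = sprintf("R%07d", 2100000L + seq_len(xs)),
                 rna = sprintf("R%07d", 2200000L + seq_len(xs)),
                 prot = sprintf("R%07d", 2300000L + seq_len(xs)))
  clin_extra <- sprintf("R%07d", 3000000L + seq_len(spec$clinical_extra_samples))
  all_ids <- unique(c(core, unlist(extras), clin_extra))
  alias <- data.frame(
    individual_id = all_ids,
    mwas_id = sprintf("PT-%04d", seq_along(all_ids)),
    mrna_id = sprintf("%03d_120521_%d", 500L + seq_along(all_ids),
                      1L + seq_along(all_ids) %% 2L),
    cnvdata_id = sprintf("SM-C%04d", seq_along(all_ids)),
    projid = sprintf("%08d", 20000000L + seq_along(all_ids)),
    stringsAsFactors = FALSE)
  alias$mwas_id[alias$individual_id == "R1822146"] <- "PT-M5AF"
  sample_map <- alias
  class(sample_map) <- c("sample_id_map", "data.frame")
  alias_of <- function(ids, col) alias[[col]][match(ids, alias$individual_id)]

  label_missing <- sample(core, spec$label_missing_samples)
  aligned <- sort(setdiff(core, label_missing), method = "radix")
  M <- length(aligned)

  ## ---- methylation --------------------------------------------------------
  region_names <- c("upstream", "distal_promoter", "proximal_promoter",
                    "core_promoter", "downstream")
  draw_distance <- function(region) {
    switch(region,
           core_promoter = -sample(1:50, 1L),
           proximal_promoter = -sample(51:250, 1L),
           distal_promoter = -sample(251:3000, 1L),
           upstream = -sample(3001:6000, 1L),
           downstream = sample(0:3000, 1L))
  }
  methyl_genes <- unique(c("NR5A2",
                           sample(genes, round(spec$methyl_gene_fraction *
                                               spec$n_genes))))
  probes <- data.frame(probe_id = character(), gene = character(),
                       distance = integer(), region = character(),
                       stringsAsFactors = FALSE)
  k <- 0L
  for (g in methyl_genes) {
    for (j in seq_len(spec$probes_per_gene)) {
      k <- k + 1L
      r <- region_names[((k - 1L) %% 5L) + 1L]
      probes <- rbind(probes, data.frame(
        probe_id = sprintf("cg1%07d", k), gene = g,
        distance = draw_distance(r), region = r, stringsAsFactors = FALSE))
    }
  }
  probes <- rbind(probes, data.frame(probe_id = "cg00001583", gene = "NR5A2",
                                     distance = -1200L,
                                     region = "distal_promoter",
                                     stringsAsFactors = FALSE))
  n_oor <- ceiling(spec$out_of_range_fraction * nrow(probes))
  oor <- data.frame(
    probe_id = sprintf("cg2%07d", seq_len(n_oor)),
    gene = sample(methyl_genes, n_oor, replace = TRUE),
    distance = ifelse(seq_len(n_oor) %% 2L == 1L,
                      -sample(6001:8000, n_oor, replace = TRUE),
                      sample(3001:4500, n_oor, replace = TRUE)),
    region = "out_of_range", stringsAsFactors = FALSE)
  all_probes <- rbind(probes, oor)
  annotation <- data.frame(probe_id = all_probes$probe_id,
                           gene = all_probes$gene,
                           distance_bp = all_probes$distance,
                           stringsAsFactors = FALSE)
  class(annotation) <- c("probe_annotation", "data.frame")
  methyl_ids <- c(core, extras$methyl)
  meth_values <- .rand_values(nrow(all_probes) + 1L,
                              c(all_probes$probe_id, "cg30000001"),
                              methyl_ids, stats::runif,
                              spec$value_missing_rate)
  # cg30000001 is planted unannotated (dropped-and-counted branch)
  meth_cols <- c(alias_of(methyl_ids, "mwas_id"), "PT-JUNK")
  meth_input_vals <- cbind(meth_values,
                           `PT-JUNK` = stats::runif(nrow(meth_values)))
  colnames(meth_input_vals) <- meth_cols
  methylation <- omics_table(meth_input_vals, "methylation", "probe_id",
                             row_ids = rownames(meth_values),
                             sample_ids = meth_cols)
  # truth: per-region group-by mean over planted in-range probes
  truth_methyl <- list()
  for (r in region_names) {
    pr <- probes[probes$region == r, , drop = FALSE]
    rows_by_gene <- split(pr$probe_id, pr$gene)
    truth_methyl[[paste0("methyl_", r)]] <-
      .truth_mean_block(rows_by_gene, meth_values, aligned)
  }
  methyl_union <- sort(unique(probes$gene), method = "radix")

  ## ---- genetic variation --------------------------------------------------
  variant_ids <- c(core, extras$variant)
  cnv_types <- c("DEL", "DUP", "mCNV")
  if (spec$variant_mode == "cnv") {
    ref_symbols <- reference$gene_symbol
    n_vg <- min(round(spec$variant_gene_fraction * spec$n_genes),
                length(ref_symbols))
    variant_genes <- unique(c("LINC01128", others[2L], others[4L],
                              sample(ref_symbols, n_vg)))
    variant_genes <- intersect(variant_genes, ref_symbols)
    seg <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), variation_type = character(),
                      stringsAsFactors = FALSE)
    for (i in seq_along(variant_genes)) {
      g <- variant_genes[i]
      gi <- match(g, gene_tbl$gene)
      tys <- cnv_types[((i - 1L) %% 3L) + 1L]
      if (i %% 2L == 0L) tys <- c(tys, cnv_types[(i %% 3L) + 1L])
      for (ty in tys) {
        for (rep_ in seq_len(1L + (i %% 2L))) {
          s0 <- gene_tbl$start[gi] + sample(0:2000, 1L)
          e0 <- min(s0 + sample(500:3000, 1L), gene_tbl$end[gi])
          seg <- rbind(seg, data.frame(chrom = gene_tbl$chrom[gi],
                                       start_bp = s0, end_bp = e0,
                                       variation_type = ty,
                                       stringsAsFactors = FALSE))
        }
      }
    }
    ov_start <- gene_tbl$start[match(others[4L], gene_tbl$gene)]
    seg <- rbind(seg,
                 data.frame(chrom = "chr1", start_bp = 830676L,
                            end_bp = 834492L, variation_type = "DUP",
                            stringsAsFactors = FALSE),
                 data.frame(chrom = "chr2", start_bp = ov_start + 100L,
                            end_bp = ov_start + 2100L,
                            variation_type = "mCNV",
                            stringsAsFactors = FALSE),
                 data.frame(chrom = "chr1", start_bp = 500000L,
                            end_bp = 500100L, variation_type = "DEL",
                            stringsAsFactors = FALSE),
                 data.frame(chrom = "chrX", start_bp = 100L, end_bp = 200L,
                            variation_type = "DEL", stringsAsFactors = FALSE))
    seg_values <- .rand_values(nrow(seg), NULL, variant_ids,
                               function(n) sample(0:3, n, replace = TRUE),
                               spec$value_missing_rate)
    seg_input <- seg
    for (j in seq_along(variant_ids)) {
      seg_input[[alias_of(variant_ids, "cnvdata_id")[j]]] <- seg_values[, j]
    }
    seg_input[["SM-JUNK"]] <- sample(0:3, nrow(seg), replace = TRUE)
    attr(seg_input, "sample_ids") <- c(alias_of(variant_ids, "cnvdata_id"),
                                       "SM-JUNK")
    class(seg_input) <- c("cnv_segment_table", "data.frame")
    # truth: brute-force O(S*G) overlap scan against the reference catalog
    truth_variant <- list()
    for (ty in cnv_types) {
      sums <- list()
      for (si in which(seg$variation_type == ty)) {
        hits <- reference$gene_symbol[
          reference$chrom == seg$chrom[si] &
          reference$start_bp <= seg$end_bp[si] &
          reference$end_bp >= seg$start_bp[si]]
        for (g in hits) {
          v <- seg_values[si, aligned]
          v[is.na(v)] <- 0
          sums[[g]] <- (sums[[g]] %||% stats::setNames(rep(0, M), aligned)) + v
        }
      }
      gns <- sort(names(sums), method = "radix")
      v <- matrix(0, length(gns), M, dimnames = list(gns, aligned))
      for (g in gns) v[g, ] <- sums[[g]]
      truth_variant[[paste0("cnv_", ty)]] <-
        list(values = v,
             mask = matrix(TRUE, length(gns), M,
                           dimnames = list(gns, aligned)))
    }
    variant_input <- list(cnv_segments = seg_input)
    n_g0 <- nrow(seg)
  } else {
    mut_genes <- sample(genes, round(spec$variant_gene_fraction * spec$n_genes))
    dup <- utils::head(mut_genes, 3L)
    rows <- c(mut_genes, dup)
    mut_values <- .rand_values(length(rows), NULL, variant_ids,
                               function(n) sample(0:1, n, replace = TRUE),
                               spec$value_missing_rate)
    mut_cols <- c(alias_of(variant_ids, "cnvdata_id"), "SM-JUNK")
    mut_input_vals <- cbind(mut_values,
                            sample(0:1, length(rows), replace = TRUE))
    colnames(mut_input_vals) <- mut_cols
    mutation <- omics_table(mut_input_vals, "mutation_binary", "gene_symbol",
                            row_ids = rows, sample_ids = mut_cols)
    rows_by_gene <- split(seq_along(rows), rows)
    tb <- .truth_mean_block(rows_by_gene, mut_values, aligned)
    # all-missing duplicate groups surface as -1-filled variation cells
    tb$values[!tb$mask] <- -1
    truth_variant <- list(mutation = tb)
    variant_input <- list(mutation = mutation)
    n_g0 <- length(rows)
  }
  variant_union <- sort(unique(unlist(lapply(truth_variant,
                                             function(b) rownames(b$values)))),
                        method = "radix")

  ## ---- transcriptomics ----------------------------------------------------
  rna_ids_s <- c(core, extras$rna)
  rna_genes <- unique(c("NR5A2",
                        sample(genes, round(spec$rna_gene_fraction *
                                            spec$n_genes))))
  dup_genes <- utils::head(rna_genes, spec$rna_dup_genes)
  id_map <- data.frame(source_id = gene_id, gene_symbol = genes,
                       stringsAsFactors = FALSE)
  alt_ids <- sprintf("ENSGA%010d", seq_along(dup_genes))
  id_map <- rbind(id_map, data.frame(source_id = alt_ids,
                                     gene_symbol = dup_genes,
                                     stringsAsFactors = FALSE))
  base_ids <- gene_id[match(rna_genes, genes)]
  versioned <- ifelse(seq_along(base_ids) %% 5L == 0L, base_ids,
                      paste0(base_ids, ".", sample(1:15, length(base_ids),
                                                   replace = TRUE)))
  rna_rows <- data.frame(row_id = versioned, symbol = rna_genes,
                         stringsAsFactors = FALSE)
  rna_rows <- rbind(rna_rows,
                    data.frame(row_id = sprintf("%s.%d", alt_ids,
                                                sample(1:9, length(alt_ids),
                                                       replace = TRUE)),
                               symbol = dup_genes, stringsAsFactors = FALSE),
                    data.frame(row_id = sprintf("ENSG999%08d.3",
                                                seq_len(spec$rna_unmapped_rows)),
                               symbol = rep(NA_character_,
                                            spec$rna_unmapped_rows),
                               stringsAsFactors = FALSE))
  rna_values <- .rand_values(nrow(rna_rows), NULL, rna_ids_s,
                             function(n) stats::rlnorm(n, 1, 0.6),
                             spec$value_missing_rate)
  rna_cols <- c(alias_of(rna_ids_s, "mrna_id"), "999_JUNK_9")
  rna_input_vals <- cbind(rna_values, stats::rlnorm(nrow(rna_rows), 1, 0.6))
  colnames(rna_input_vals) <- rna_cols
  rnaseq <- omics_table(rna_input_vals, "rnaseq", "versioned_gene_id",
                        row_ids = rna_rows$row_id, sample_ids = rna_cols)
  mapped <- !is.na(rna_rows$symbol)
  truth_rna <- .truth_mean_block(split(which(mapped), rna_rows$symbol[mapped]),
                                 rna_values, aligned)

  ## ---- proteomics ---------------------------------------------------------
  prot_ids_s <- c(core, extras$prot)
  prot_genes <- unique(c("VAMP1",
                         sample(genes, round(spec$prot_gene_fraction *
                                             spec$n_genes))))
  pdup <- utils::head(setdiff(prot_genes, "VAMP1"), spec$prot_dup_genes)
  tag_of <- function(g, i) {
    if (g == "VAMP1") "VAMP1|P23763"
    else if (i %% 3L == 0L) g
    else sprintf("%s|P%05d", g, 10000L + i)
  }
  tags <- vapply(seq_along(prot_genes),
                 function(i) tag_of(prot_genes[i], i), character(1L))
  prot_rows <- data.frame(tag = c(tags, paste0(pdup), "|P00001"),
                          symbol = c(prot_genes, pdup, NA_character_),
                          stringsAsFactors = FALSE)
  prot_values <- .rand_values(nrow(prot_rows), NULL, prot_ids_s,
                              function(n) stats::rlnorm(n, 0, 0.5),
                              spec$value_missing_rate)
  prot_cols <- c(alias_of(prot_ids_s, "projid"), "99999999")
  prot_input_vals <- cbind(prot_values, stats::rlnorm(nrow(prot_rows), 0, 0.5))
  colnames(prot_input_vals) <- prot_cols
  proteomics <- omics_table(prot_input_vals, "proteomics", "protein_tag",
                            row_ids = prot_rows$tag, sample_ids = prot_cols)
  pmapped <- !is.na(prot_rows$symbol)
  truth_prot <- .truth_mean_block(split(which(pmapped),
                                        prot_rows$symbol[pmapped]),
                                  prot_values, aligned)

  ## ---- regulatory network -------------------------------------------------
  net_genes <- unique(c(special,
                        sample(genes, round(spec$network_gene_fraction *
                                            spec$n_genes)),
                        c("EXT1", "EXT2")))
  forced <- data.frame(from = c("NR5A2", "LINC01128"),
                       to = c("VAMP1", "NR5A2"), stringsAsFactors = FALSE)
  pairs <- t(utils::combn(net_genes, 2L))
  n_edges <- max(3L, round(spec$network_density * nrow(pairs)))
  sel <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- rbind(forced, data.frame(from = pairs[sel, 1L],
                                    to = pairs[sel, 2L],
                                    stringsAsFactors = FALSE))
  # node set = union of edge endpoints, as an edge-list file carries it
  network <- regulatory_network(data.frame(from = edges$from, to = edges$to,
                                           directed = FALSE,
                                           stringsAsFactors = FALSE))

  ## ---- clinical -----------------------------------------------------------
  clin_ids <- c(core, clin_extra)
  n_sparse_miss <- ceiling(spec$clinical_feature_missing_rate *
                           length(core))
  sparse <- round(stats::runif(length(clin_ids)), 3)
  sparse[match(sample(core, n_sparse_miss), clin_ids)] <- NA
  status <- as.character(rep_len(spec$label_classes, length(clin_ids)))
  status[match(label_missing, clin_ids)] <- NA
  clinical <- data.frame(
    sample_id = clin_ids,
    age = as.character(60L + sample(0:30, length(clin_ids), replace = TRUE)),
    sex = sample(c("M", "F"), length(clin_ids), replace = TRUE),
    sparse_feature = as.character(sparse),
    status = status, stringsAsFactors = FALSE)
  class(clinical) <- c("clinical_table", "data.frame")
  truth_labels <- stats::setNames(
    match(clinical$status[match(aligned, clin_ids)],
          spec$label_classes) - 1L, aligned)

  ## ---- ground truth assembly ---------------------------------------------
  ref_set <- reference$gene_symbol
  methyl_ref <- intersect(methyl_union, ref_set)
  variant_ref <- intersect(variant_union, ref_set)
  rna_ref <- intersect(sort(rna_genes, method = "radix"), ref_set)
  prot_ref <- intersect(sort(prot_genes, method = "radix"), ref_set)
  n3_set <- sort(unique(c(methyl_ref, variant_ref, rna_ref, prot_ref)),
                 method = "radix")
  final_genes <- sort(intersect(n3_set, network$nodes), method = "radix")
  n <- length(final_genes)
  e <- network$edges
  p_u <- sum(e$from %in% final_genes & e$to %in% final_genes)
  d <- 5L + length(truth_variant) + 2L

  blocks <- list()
  for (nm in names(truth_methyl)) {
    b <- truth_methyl[[nm]]
    keep <- rownames(b$values) %in% methyl_ref
    b <- list(values = b$values[keep, , drop = FALSE],
              mask = b$mask[keep, , drop = FALSE])
    blocks[[nm]] <- .truth_embed(b, final_genes, aligned, 0)
  }
  # genes in the methylation union but absent from a region block are
  # measured-zero only pre-union; after region unification they are
  # imputed-zero cells, which cross-omics padding preserves — .truth_embed
  # already yields value 0 / mask FALSE for them.
  for (nm in names(truth_variant)) {
    b <- truth_variant[[nm]]
    keep <- rownames(b$values) %in% variant_ref
    b <- list(values = b$values[keep, , drop = FALSE],
              mask = b$mask[keep, , drop = FALSE])
    emb <- .truth_embed(b, final_genes, aligned, -1)
    # within-variation union pads first: a gene measured in some type but
    # not this one carries -1 regardless of the cross-omics union
    blocks[[nm]] <- emb
  }
  blocks$rnaseq <- .truth_embed(
    list(values = truth_rna$values[rownames(truth_rna$values) %in% rna_ref, ,
                                   drop = FALSE],
         mask = truth_rna$mask[rownames(truth_rna$values) %in% rna_ref, ,
                               drop = FALSE]),
    final_genes, aligned, 0)
  blocks$proteomics <- .truth_embed(
    list(values = truth_prot$values[rownames(truth_prot$values) %in% prot_ref, ,
                                    drop = FALSE],
         mask = truth_prot$mask[rownames(truth_prot$values) %in% prot_ref, ,
                                drop = FALSE]),
    final_genes, aligned, 0)

  fold_sizes <- sort(rep(M %/% spec$folds, spec$folds) +
                     c(rep(1L, M %% spec$folds),
                       rep(0L, spec$folds - M %% spec$folds)))

  truth <- list(
    samples = aligned, M = M, genes = final_genes, n = n, d = d,
    n_nodes_multilevel = 7L * n,
    n_edges_multilevel = 6L * n + 2L * p_u,
    E_flat = 2L * p_u,
    counts = list(n_e0 = nrow(all_probes) + 1L, n_g0 = n_g0,
                  n_t0 = nrow(rna_rows), n_p0 = nrow(prot_rows),
                  n_e1 = length(methyl_union),
                  n_g1 = length(variant_union),
                  n_t1 = length(rna_genes), n_p1 = length(prot_genes),
                  n_e2 = length(methyl_ref), n_g2 = length(variant_ref),
                  n_t2 = length(rna_ref), n_p2 = length(prot_ref),
                  n3 = length(n3_set),
                  n_reg = length(network$nodes), E_reg = nrow(network$edges)),
    blocks = blocks, labels = truth_labels,
    class_map = as.character(spec$label_classes),
    fold_sizes = fold_sizes,
    dropped_clinical = "sparse_feature")

  inputs <- c(list(
    methylation = methylation, methyl_alias = "mwas_id",
    probe_annotation = annotation,
    rnaseq = rnaseq, rna_alias = "mrna_id", id_map = id_map,
    proteomics = proteomics, prot_alias = "projid",
    clinical = clinical, sample_map = sample_map,
    reference = reference, network = network,
    label_column = "status",
    class_map = as.character(spec$label_classes),
    variant_mode = spec$variant_mode, variant_alias = "cnvdata_id"),
    variant_input)

  list(inputs = inputs, truth = truth, spec = spec)
}

#' Write a generated study to disk in the pipeline's input formats
#'
#' Emits every input table as CSV/TSV plus a `config.yaml` consumable by
#' [run_pipeline_config()]. The probe-annotation file gains one duplicated
#' probe row and the network file one duplicated edge line, exercising the
#' keep-first / dedup read policies.
#'
#' @param study Output of [gen_study()].
#' @param dir Output directory (created).
#' @return The config path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- study$inputs
  p <- function(f) file.path(dir, f)
  write_omics_table(inputs$methylation, p("methylation.csv"),
                    id_header = "probe_id")
  ann <- data.frame(probe_id = inputs$probe_annotation$probe_id,
                    closest_tss_gene = inputs$probe_annotation$gene,
                    distance_bp = inputs$probe_annotation$distance_bp)
  ann <- rbind(ann, data.frame(probe_id = ann$probe_id[1L],
                               closest_tss_gene = "WRONG_GENE",
                               distance_bp = -99L))
  utils::write.csv(ann, p("probe_annotation.csv"), row.names = FALSE)
  if (inputs$variant_mode == "cnv") {
    utils::write.csv(inputs$cnv_segments, p("cnv_segments.csv"),
                     row.names = FALSE)
    variant_path <- "cnv_segments.csv"
  } else {
    write_omics_table(inputs$mutation, p("mutation.csv"), id_header = "gene")
    variant_path <- "mutation.csv"
  }
  write_omics_table(inputs$rnaseq, p("rnaseq.csv"), id_header = "gene_id")
  write_omics_table(inputs$proteomics, p("proteomics.csv"),
                    id_header = "protein")
  utils::write.csv(inputs$id_map, p("id_map.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(inputs$reference)),
                   p("reference.csv"), row.names = FALSE)
  e <- inputs$network$edges
  lines <- paste(e$from, e$to, sep = "\t")
  writeLines(c(lines, lines[1L]), p("network.tsv"))
  utils::write.csv(as.data.frame(unclass(inputs$clinical)), p("clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(inputs$sample_map)),
                   p("sample_map.csv"), row.names = FALSE)
  cfg <- list(
    methylation = list(path = "methylation.csv", alias_column = "mwas_id"),
    probe_annotation = list(path = "probe_annotation.csv"),
    variant = list(path = variant_path, mode = inputs$variant_mode,
                   alias_column = "cnvdata_id"),
    rnaseq = list(path = "rnaseq.csv", alias_column = "mrna_id"),
    id_map = list(path = "id_map.csv"),
    proteomics = list(path = "proteomics.csv", alias_column = "projid"),
    clinical = list(path = "clinical.csv"),
    sample_map = list(path = "sample_map.csv"),
    reference = list(path = "reference.csv"),
    network = list(path = "network.tsv", format = "edge_list_2col"),
    label = list(column = "status",
                 classes = as.list(inputs$class_map)),
    graph = list(mode = "multilevel", folds = study$spec$folds,
                 seed = study$spec$fold_seed))
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(p("config.yaml"))
}
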