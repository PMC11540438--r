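ref_fixture <- function() {
  ref <- data.frame(
    gene_symbol = c("LINC01128", "GA", "GB", "GC"),
    gene_id = sprintf("ENSG%011d", 1:4),
    chrom = c("chr1", "chr2", "chr2", "chr3"),
    start_bp = c(825138L, 1000L, 5000L, 1000L),
    end_bp = c(859446L, 6000L, 9000L, 2000L),
    strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)
  class(ref) <- c("reference_genome", "data.frame")
  ref
}

seg_fixture <- function(df) {
  samples <- setdiff(colnames(df), c("chrom", "start_bp", "end_bp",
                                     "variation_type"))
  attr(df, "sample_ids") <- samples
  class(df) <- c("cnv_segment_table", "data.frame")
  df
}

test_that("binary mutation duplicates collapse by mean", {
  mut <- make_table(c("TP53", "TP53", "KRAS"), c("S1", "S2"),
                    c(1, 0, 1, 0, 1, NA),
                    kind = "mutation_binary", namespace = "gene_symbol")
  glm <- aggregate_binary_mutations(mut)
  expect_identical(glm$genes, c("KRAS", "TP53"))
  expect_equal(glm$values["TP53", "S1"], 0.5)
  expect_equal(glm$values["KRAS", "S1"], 1)
  expect_equal(glm$values["TP53", "S2"], 0.5)   # mean over observed (0, 1)

  # k planted duplicates reduce the row count by exactly k extras
  set.seed(4)
  genes <- sprintf("G%02d", 1:15)
  rows <- c(genes, sample(genes, 5))
  mut2 <- make_table(rows, c("S1", "S2"),
                     sample(0:1, 40, replace = TRUE),
                     kind = "mutation_binary", namespace = "gene_symbol")
  glm2 <- aggregate_binary_mutations(mut2)
  expect_identical(length(glm2$genes), 15L)
  expect_equal(glm2$values, oracle_group_mean(mut2$values, rows))

  expect_warning(aggregate_binary_mutations(
    make_table("G1", "S1", 2, kind = "mutation_binary",
               namespace = "gene_symbol")), "outside")
})

test_that("segments map to the genes they overlap, matching the worked example", {
  seg <- seg_fixture(data.frame(
    chrom = c("chr1", "chr2", "chr1", "chrX"),
    start_bp = c(830676L, 4000L, 500000L, 10L),
    end_bp = c(834492L, 5500L, 500100L, 20L),
    variation_type = c("DUP", "DEL", "DEL", "DEL"),
    S1 = c(1, 2, 1, 1), stringsAsFactors = FALSE))
  expect_warning(ann <- assign_gene_by_interval(seg, ref_fixture()), "chrX")
  # the 830676-834492 segment falls inside LINC01128
  expect_identical(ann$gene[ann$start_bp == 830676L], "LINC01128")
  # the chr2 segment spans GA (ends 6000) and GB (starts 5000)
  expect_identical(sort(ann$gene[ann$start_bp == 4000L]), c("GA", "GB"))
  # the gene-desert and chrX segments are gone
  expect_identical(attr(ann, "n_dropped"), 2L)

  # nearest-only keeps the single largest overlap
  ann2 <- suppressWarnings(assign_gene_by_interval(seg, ref_fixture(),
                                                   nearest_only = TRUE))
  expect_identical(ann2$gene[ann2$start_bp == 4000L], "GA")  # 2000 vs 501 bp
})

test_that("interval assignment equals the all-pairs overlap scan", {
  set.seed(8)
  ref <- data.frame(
    gene_symbol = sprintf("G%03d", 1:25),
    gene_id = sprintf("E%03d", 1:25),
    chrom = sample(c("chr1", "chr2"), 25, replace = TRUE),
    start_bp = sample.int(50000L, 25), stringsAsFactors = FALSE)
  ref$end_bp <- ref$start_bp + sample(100:8000, 25)
  ref$strand <- "+"
  class(ref) <- c("reference_genome", "data.frame")
  seg <- data.frame(
    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
    start_bp = sample.int(55000L, 60), stringsAsFactors = FALSE)
  seg$end_bp <- seg$start_bp + sample(50:5000, 60)
  seg$variation_type <- sample(c("DEL", "DUP", "mCNV"), 60, replace = TRUE)
  seg$S1 <- runif(60)
  seg <- seg_fixture(seg)
  ann <- assign_gene_by_interval(seg, ref)
  oracle <- oracle_overlaps(seg, ref)
  got <- paste(ann$start_bp, ann$gene)
  want <- paste(seg$start_bp[oracle[, 1]], ref$gene_symbol[oracle[, 2]])
  expect_setequal(got, want)
  expect_identical(nrow(ann), nrow(oracle))
})

test_that("per-type CNV sums match the group-by-sum oracle and conserve totals", {
  seg <- seg_fixture(data.frame(
    chrom = "chr2", start_bp = c(1100L, 1200L, 5100L),
    end_bp = c(1150L, 1250L, 5200L),
    variation_type = c("DEL", "DEL", "DUP"),
    S1 = c(1, 1, 2), S2 = c(0, 3, NA), stringsAsFactors = FALSE))
  ann <- assign_gene_by_interval(seg, ref_fixture())
  blocks <- aggregate_cnv_by_type(ann)
  expect_identical(names(blocks), c("cnv_DEL", "cnv_DUP", "cnv_mCNV"))
  expect_equal(blocks$cnv_DEL$values["GA", ], c(S1 = 2, S2 = 3))
  expect_equal(blocks$cnv_DUP$values["GB", ], c(S1 = 2, S2 = 0))
  expect_identical(length(blocks$cnv_mCNV$genes), 0L)

  # random fixture: equality with the oracle per type + total conservation
  set.seed(19)
  n <- 40
  ann2 <- seg_fixture(data.frame(
    chrom = "chr2", start_bp = rep(1100L, n), end_bp = rep(1200L, n),
    variation_type = sample(c("DEL", "DUP", "mCNV"), n, replace = TRUE),
    S1 = runif(n), S2 = runif(n), stringsAsFactors = FALSE))
  ann2$gene <- sample(c("GA", "GB"), n, replace = TRUE)
  blocks2 <- aggregate_cnv_by_type(ann2)
  vals <- as.matrix(ann2[, c("S1", "S2")])
  for (ty in c("DEL", "DUP", "mCNV")) {
    sel <- ann2$variation_type == ty
    expect_equal(blocks2[[paste0("cnv_", ty)]]$values,
                 oracle_group_sum(vals[sel, , drop = FALSE],
                                  ann2$gene[sel]))
    expect_equal(sum(blocks2[[paste0("cnv_", ty)]]$values),
                 sum(vals[sel, ], na.rm = TRUE))
  }
})

test_that("variation unification pads with -1 and keeps measured zeros", {
  del <- make_glm("A", c("S1", "S2"), c(2, 0), kind = "cnv_DEL")
  dup <- make_glm("B", c("S1", "S2"), c(1, 1), kind = "cnv_DUP")
  uni <- unify_variant_genes(list(cnv_DEL = del, cnv_DUP = dup))
  expect_identical(uni$cnv_DEL$genes, c("A", "B"))
  expect_equal(uni$cnv_DUP$values["A", ], c(S1 = -1, S2 = -1))
  expect_false(any(uni$cnv_DUP$mask["A", ]))
  # a measured 0 stays 0, distinct from the -1 fill
  expect_equal(uni$cnv_DEL$values["A", "S2"], 0)
  expect_true(uni$cnv_DEL$mask["A", "S2"])
  # identical gene sets: unchanged
  same <- unify_variant_genes(list(cnv_DEL = del,
                                   cnv_DUP = make_glm("A", c("S1", "S2"),
                                                      c(9, 9),
                                                      kind = "cnv_DUP")))
  expect_identical(same$cnv_DEL$values, del$values)
  # -1 appears only in imputed cells
  for (b in uni) expect_true(all(b$values[b$mask] != -1 | b$values[b$mask] >= 0))
  for (b in uni) expect_true(all(b$values[!b$mask] == -1))
})
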