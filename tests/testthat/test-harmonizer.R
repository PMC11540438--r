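small_ref <- function(symbols) {
  ref <- data.frame(gene_symbol = symbols,
                    gene_id = sprintf("E%02d", seq_along(symbols)),
                    chrom = "chr1", start_bp = 1L, end_bp = 2L, strand = "+",
                    stringsAsFactors = FALSE)
  class(ref) <- c("reference_genome", "data.frame")
  ref
}

test_that("reference filtering keeps exactly the catalog intersection", {
  glm <- make_glm(c("A", "B", "Z"), "S1", c(1, 2, 3))
  out <- filter_by_reference(glm, small_ref(c("A", "B", "C")))
  expect_identical(out$genes, c("A", "B"))
  # subset of the reference: identity
  expect_identical(filter_by_reference(out, small_ref(c("A", "B", "C")))$values,
                   out$values)
  expect_error(filter_by_reference(make_glm("Q", "S1", 1),
                                   small_ref(c("A"))), "no gene")

  set.seed(2)
  genes <- sample(sprintf("G%02d", 1:40), 25)
  ref_set <- sample(sprintf("G%02d", 1:40), 30)
  glm2 <- make_glm(sort(genes, method = "radix"), "S1", seq_along(genes))
  out2 <- filter_by_reference(glm2, small_ref(ref_set))
  expect_identical(out2$genes,
                   sort(intersect(genes, ref_set), method = "radix"))
})

test_that("cross-omics union pads per-omics fill values", {
  rna <- make_glm(c("A", "B"), c("S1", "S2"), c(1, 2, 3, 4), kind = "rnaseq")
  prot <- make_glm(c("B", "C"), c("S1", "S2"), c(5, 6, 7, 8),
                   kind = "proteomics")
  var <- make_glm(c("A", "C"), c("S1", "S2"), c(0, 1, 2, 0), kind = "cnv_DEL")
  padded <- union_and_pad(list(rnaseq = rna, proteomics = prot,
                               cnv_DEL = var))
  expect_identical(attr(padded, "n_union"), 3L)
  for (b in padded) expect_identical(b$genes, c("A", "B", "C"))
  expect_equal(unname(padded$proteomics$values["A", ]), c(0, 0))
  expect_equal(unname(padded$cnv_DEL$values["B", ]), c(-1, -1))
  expect_equal(padded$rnaseq$values["A", "S1"], 1)
  # mask partition: imputed cells carry exactly the declared fill value
  for (b in padded) {
    fill <- if (b$kind == "cnv_DEL") -1 else 0
    expect_true(all(b$values[!b$mask] == fill))
  }
})

test_that("padding never alters measured cells (random fixtures)", {
  set.seed(17)
  for (rep_ in 1:5) {
    samples <- paste0("S", 1:3)
    mk <- function(kind) {
      g <- sort(sample(LETTERS[1:8], sample(3:6, 1)), method = "radix")
      make_glm(g, samples, runif(length(g) * 3), kind = kind)
    }
    blocks <- list(rnaseq = mk("rnaseq"), proteomics = mk("proteomics"),
                   cnv_DUP = mk("cnv_DUP"))
    padded <- union_and_pad(blocks)
    for (nm in names(blocks)) {
      raw <- blocks[[nm]]; pad <- padded[[nm]]
      expect_identical(pad$values[raw$genes, ], raw$values)
      expect_true(all(pad$mask[raw$genes, ]))
      fill <- if (nm == "cnv_DUP") -1 else 0
      expect_true(all(pad$values[!pad$mask] == fill))
    }
  }
})

test_that("network intersection fixes the final gene set and induced edges", {
  rna <- make_glm(c("A", "B", "C"), "S1", 1:3, kind = "rnaseq")
  net <- regulatory_network(data.frame(from = c("B", "C", "D"),
                                       to = c("C", "D", "E"),
                                       directed = FALSE))
  study <- intersect_with_network(union_and_pad(list(rnaseq = rna)), net)
  expect_identical(study$genes, c("B", "C"))
  expect_identical(study$counts$n, 2L)
  expect_identical(nrow(study$network$edges), 1L)   # only B-C survives
  expect_identical(study$counts$M, 1L)

  # network covering the union: n = n(3)
  net2 <- regulatory_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                        directed = FALSE))
  study2 <- intersect_with_network(union_and_pad(list(rnaseq = rna)), net2)
  expect_identical(study2$counts$n, study2$counts$n_union)

  expect_error(intersect_with_network(
    union_and_pad(list(rnaseq = rna)),
    regulatory_network(data.frame(from = "X", to = "Y", directed = FALSE))),
    "no harmonized gene")

  # induced edge set equals a brute-force filter of the full edge list
  set.seed(23)
  nodes <- sprintf("N%02d", 1:15)
  pairs <- t(combn(nodes, 2))
  sel <- sample(nrow(pairs), 30)
  net3 <- regulatory_network(data.frame(from = pairs[sel, 1],
                                        to = pairs[sel, 2],
                                        directed = FALSE))
  keep_genes <- sample(nodes, 8)
  glm3 <- make_glm(sort(keep_genes, method = "radix"), "S1",
                   seq_along(keep_genes), kind = "rnaseq")
  study3 <- intersect_with_network(union_and_pad(list(rnaseq = glm3)), net3)
  manual <- net3$edges[net3$edges$from %in% keep_genes &
                       net3$edges$to %in% keep_genes, ]
  expect_identical(nrow(study3$network$edges), nrow(manual))
  expect_setequal(paste(study3$network$edges$from, study3$network$edges$to),
                  paste(manual$from, manual$to))
})

test_that("reference filter and union commute", {
  set.seed(29)
  ref <- small_ref(sample(LETTERS[1:10], 7))
  mk <- function(kind) {
    g <- sort(sample(LETTERS[1:10], 5), method = "radix")
    make_glm(g, "S1", runif(5), kind = kind)
  }
  blocks <- list(rnaseq = mk("rnaseq"), proteomics = mk("proteomics"))
  # filter-then-union
  a <- union_and_pad(lapply(blocks, filter_by_reference, reference = ref))
  # union-then-filter
  b <- lapply(union_and_pad(blocks), filter_by_reference, reference = ref)
  expect_identical(a$rnaseq$genes, b$rnaseq$genes)
  expect_identical(a$rnaseq$values, b$rnaseq$values)
  expect_identical(a$proteomics$values, b$proteomics$values)
})
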