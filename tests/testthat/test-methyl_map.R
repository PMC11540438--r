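test_that("signed TSS distances classify into the five promoter regions", {
  sch <- region_scheme()
  expect_identical(classify_region(-40, sch), "core_promoter")
  expect_identical(classify_region(1500, sch), "downstream")
  expect_identical(classify_region(-7000, sch), "out_of_range")
  # boundary conventions: half-open upstream bins, TSS itself downstream
  expect_identical(classify_region(c(-50, -51, -250, -251, -3000, -3001,
                                     -6000, -6001, 0, 3000, 3001), sch),
                   c("core_promoter", "proximal_promoter",
                     "proximal_promoter", "distal_promoter",
                     "distal_promoter", "upstream", "upstream",
                     "out_of_range", "downstream", "downstream",
                     "out_of_range"))
  # flipped sign convention mirrors the assignment
  expect_identical(classify_region(40, region_scheme(upstream_negative = FALSE)),
                   "core_promoter")
})

test_that("every distance maps to exactly one region (partition property)", {
  set.seed(21)
  d <- sample(-8000:4000, 10000, replace = TRUE)
  lab <- classify_region(d)
  expect_identical(lab, oracle_region(d))
  counts <- table(factor(lab, levels = c("upstream", "distal_promoter",
                                         "proximal_promoter", "core_promoter",
                                         "downstream", "out_of_range")))
  expect_identical(sum(counts), 10000L)
})

test_that("region aggregation equals the group-by-mean oracle", {
  # two-point mean and single-probe identity
  meth <- make_table(c("p1", "p2", "p3"), c("S1", "S2"),
                     c(0.2, 0.4, 0.7, 0.1, 0.3, 0.5),
                     kind = "methylation", namespace = "probe_id")
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene = c("G", "G", "H"),
                    distance_bp = c(-10L, -40L, 1500L))
  class(ann) <- c("probe_annotation", "data.frame")
  reg <- aggregate_region_means(meth, ann)
  expect_equal(reg$blocks$core_promoter$values["G", ], c(S1 = 0.3, S2 = 0.2))
  expect_equal(reg$blocks$downstream$values["H", ], c(S1 = 0.7, S2 = 0.5))

  # 20-probe random fixture vs the independent oracle, region by region
  set.seed(5)
  probes <- sprintf("cg%02d", 1:20)
  genes <- sample(c("A", "B", "C"), 20, replace = TRUE)
  dist <- sample(c(-40L, -200L, -1000L, -4000L, 800L, -7500L), 20,
                 replace = TRUE)
  vals <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("S1", "S2", "S3")))
  vals[sample(60, 6)] <- NA
  meth2 <- omics_table(vals, "methylation", "probe_id", row_ids = probes,
                       sample_ids = colnames(vals))
  ann2 <- data.frame(probe_id = probes, gene = genes, distance_bp = dist)
  class(ann2) <- c("probe_annotation", "data.frame")
  reg2 <- aggregate_region_means(meth2, ann2)
  lab <- oracle_region(dist)
  total_binned <- 0L
  for (r in names(reg2$blocks)) {
    sel <- lab == r
    total_binned <- total_binned + sum(sel)
    if (!any(sel)) {
      expect_identical(length(reg2$blocks[[r]]$genes), 0L)
      next
    }
    exp <- oracle_group_mean(vals[sel, , drop = FALSE], genes[sel])
    expect_equal(reg2$blocks[[r]]$values, exp)
  }
  expect_identical(total_binned + reg2$n_dropped, 20L)

  # mean is bounded by contributing probes and permutation-invariant
  perm <- sample(20)
  reg3 <- aggregate_region_means(
    omics_table(vals[perm, ], "methylation", "probe_id",
                row_ids = probes[perm], sample_ids = colnames(vals)), ann2)
  for (r in names(reg2$blocks)) {
    expect_equal(reg3$blocks[[r]]$values, reg2$blocks[[r]]$values)
  }

  expect_error(aggregate_region_means(
    make_table("p9", "S1", 0.5, kind = "methylation",
               namespace = "probe_id"), ann2), "no probe")
})

test_that("region unification zero-pads without touching measured cells", {
  meth <- make_table(c("p1", "p2"), c("S1", "S2"), c(0.2, 0.8, 0.6, 0.4),
                     kind = "methylation", namespace = "probe_id")
  ann <- data.frame(probe_id = c("p1", "p2"), gene = c("A", "B"),
                    distance_bp = c(-10L, -200L))
  class(ann) <- c("probe_annotation", "data.frame")
  uni <- unify_region_genes(aggregate_region_means(meth, ann))
  expect_identical(attr(uni, "n_union"), 2L)
  for (b in uni$blocks) expect_identical(b$genes, c("A", "B"))
  # A measured only in core_promoter; elsewhere imputed 0
  expect_equal(uni$blocks$core_promoter$values["A", "S1"], 0.2)
  expect_true(uni$blocks$core_promoter$mask["A", "S1"])
  expect_identical(unname(uni$blocks$proximal_promoter$values["A", ]),
                   c(0, 0))
  expect_false(any(uni$blocks$proximal_promoter$mask["A", ]))

  # mask partition on a random fixture: padding never alters measured cells
  set.seed(13)
  probes <- sprintf("cg%02d", 1:30)
  genes <- sample(LETTERS[1:6], 30, replace = TRUE)
  dist <- sample(c(-30L, -150L, -2000L, -5000L, 200L), 30, replace = TRUE)
  vals <- matrix(runif(90), 30, 3, dimnames = list(NULL, paste0("S", 1:3)))
  meth2 <- omics_table(vals, "methylation", "probe_id", row_ids = probes,
                       sample_ids = colnames(vals))
  ann2 <- data.frame(probe_id = probes, gene = genes, distance_bp = dist)
  class(ann2) <- c("probe_annotation", "data.frame")
  raw <- aggregate_region_means(meth2, ann2)
  uni2 <- unify_region_genes(raw)
  for (r in names(raw$blocks)) {
    b_raw <- raw$blocks[[r]]; b_uni <- uni2$blocks[[r]]
    for (g in b_raw$genes) {
      meas <- b_raw$mask[g, ] & !is.na(b_raw$values[g, ])
      expect_identical(b_uni$values[g, meas], b_raw$values[g, meas])
      expect_true(all(b_uni$mask[g, meas]))
    }
    expect_true(all(b_uni$values[!b_uni$mask] == 0))
  }
})
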