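test_that("size factors follow the median-of-ratios construction", {
  counts <- tibble::tibble(gene_id = c("G1", "G2"),
                           s1 = c(10L, 30L), s2 = c(20L, 60L))
  sf <- estimate_size_factors(counts)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical columns give unit factors
  eq <- tibble::tibble(gene_id = c("G1", "G2"), a = c(5L, 7L), b = c(5L, 7L))
  expect_equal(estimate_size_factors(eq)$size_factor, c(1, 1))

  # scaling one sample's column by c scales its factor by c, relative to the
  # others (the per-gene geometric means rescale alongside)
  sc <- counts
  sc$s2 <- sc$s2 * 3L
  sf2 <- estimate_size_factors(sc)
  expect_equal((sf2$size_factor[2] / sf2$size_factor[1]) /
                 (sf$size_factor[2] / sf$size_factor[1]), 3, tolerance = 1e-12)

  zero <- tibble::tibble(gene_id = c("G1", "G2"), a = c(0L, 3L), b = c(2L, 0L))
  expect_error(estimate_size_factors(zero), "pseudo-reference")
})

test_that("BH adjustment reproduces the step-up enumeration", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("nb_test: no-change genes score null, all-zero genes are dropped", {
  set.seed(8)
  design <- two_group_design(4)
  counts <- nb_null_counts(50, design)
  counts[1, -1] <- as.list(rep(100L, 8))   # identical in both groups
  counts[2, -1] <- as.list(rep(0L, 8))     # never observed
  unit_sf <- tibble::tibble(sample_id = design$sample_id, size_factor = 1)
  res <- nb_test(counts, design, "chemA", 100, size_factors = unit_sf)
  expect_false("g0002" %in% res$gene_id)
  g1 <- res[res$gene_id == "g0001", ]
  expect_equal(g1$log2_fc, 0)
  expect_gt(g1$p_value, 0.9)
  d1 <- two_group_design(1)
  expect_error(nb_test(counts[c("gene_id", d1$sample_id)], d1, "chemA", 100),
               ">= 2 replicates")
})

test_that("nb_test is calibrated on null negative-binomial genes", {
  set.seed(21)
  design <- two_group_design(4)
  counts <- nb_null_counts(500, design)
  res <- nb_test(counts, design, "chemA", 100)
  frac <- mean(res$p_value < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("deg_filter applies both cuts on the linear fold-change scale", {
  stringent <- regime_preset("stringent")
  deg <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    chemical = "chemA", dose = 100,
    log2_fc = c(1.1, -0.9, 2.5, 1.05, -3, 0.2),
    p_value = 0.001,
    fdr = c(0.005, 0.001, 0.5, 0.009, 0.0001, 0.001))
  got <- deg_filter(deg, stringent)
  # g1 (|FC|~2.14, fdr .005), g4 (|FC|~2.07, fdr .009), g5 pass; g2 fails FC,
  # g3 fails FDR, g6 fails FC
  expect_setequal(got$gene_id, c("g1", "g4", "g5"))

  # tightening either cut never adds genes
  tighter_fc <- deg_filter(deg, threshold_regime(3, 0.01))
  tighter_fdr <- deg_filter(deg, threshold_regime(2, 0.001))
  expect_true(all(tighter_fc$gene_id %in% got$gene_id))
  expect_true(all(tighter_fdr$gene_id %in% got$gene_id))
})

test_that("DEG count table covers all conditions and ignores sample order", {
  set.seed(5)
  cfg <- sim_config(n_null = 60, n_linear = 15, n_power = 0, n_hill = 0,
                    doses = c(0, 1, 100), replicates = 4, seed = 5)
  sim <- simulate_experiment(cfg)
  deg <- dplyr::bind_rows(
    nb_test(sim$counts, sim$design, "chemA", 1),
    nb_test(sim$counts, sim$design, "chemA", 100))
  regime <- regime_preset("lenient")
  tab <- deg_count_matrix(deg, regime)
  expect_equal(names(tab), c("chemical", "1", "100"))
  expect_equal(tab[["100"]], nrow(deg_filter(deg[deg$dose == 100, ], regime)))

  # permuting input rows leaves the table unchanged
  tab2 <- deg_count_matrix(deg[sample(nrow(deg)), ], regime)
  expect_equal(tab, tab2)
})

test_that("nb_test fold changes track an independent NB implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  design <- two_group_design(4)
  counts <- nb_null_counts(120, design)
  # spike 20 genes with a 4-fold increase in the treated group
  trt <- design$sample_id[design$dose > 0]
  counts[1:20, trt] <- lapply(counts[1:20, trt], function(x) x * 4L)
  res <- nb_test(counts, design, "chemA", 100)

  m <- as.matrix(counts[-1]); rownames(m) <- counts$gene_id
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, S4Vectors::DataFrame(condition = factor(design$dose > 0,
                                               levels = c(FALSE, TRUE))),
    ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  ref <- DESeq2::results(dds)
  shared <- intersect(res$gene_id, rownames(ref))
  lfc_mine <- res$log2_fc[match(shared, res$gene_id)]
  lfc_ref <- ref$log2FoldChange[match(shared, rownames(ref))]
  expect_gt(cor(lfc_mine, lfc_ref), 0.95)
  # spiked genes called in the same direction and clearly significant in both
  spiked <- sprintf("g%04d", 1:20)
  expect_true(all(res$fdr[match(spiked, res$gene_id)] < 0.05))
  expect_true(all(ref[spiked, "padj"] < 0.05))
})
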