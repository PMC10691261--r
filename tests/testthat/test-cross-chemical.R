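test_that("upset counts are exclusive and sum to the union", {
  got <- upset_counts(list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4")))
  expect_setequal(got$pattern, c("A", "B", "A&B"))
  expect_equal(got$exclusive_count[got$pattern == "A&B"], 2L)
  expect_equal(got$exclusive_count[got$pattern == "A"], 1L)
  expect_equal(sum(got$exclusive_count), 4L)

  disjoint <- upset_counts(list(A = c("x", "y"), B = c("z")))
  expect_setequal(disjoint$pattern, c("A", "B"))
})

test_that("upset counts match the element-wise oracle on random sets", {
  set.seed(88)
  genes <- sprintf("g%d", 1:30)
  for (i in 1:10) {
    sets <- lapply(setNames(1:4, c("w", "x", "y", "z")),
                   function(j) sample(genes, sample(5:20, 1)))
    got <- upset_counts(sets)
    union_g <- unique(unlist(sets))
    oracle <- table(vapply(union_g, function(g) {
      paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
            collapse = "&")
    }, character(1)))
    expect_equal(sum(got$exclusive_count), length(union_g))
    for (p in names(oracle)) {
      expect_equal(got$exclusive_count[got$pattern == p],
                   as.integer(oracle[[p]]))
    }
    expect_equal(nrow(got), length(oracle))
  }
})

test_that("shared-pathway network annotates degrees", {
  pw <- tibble::tibble(
    chemical = c("c1", "c2", "c1", "c2", "c3"),
    set_id = c("shared", "shared", "only1", "only2", "only3"))
  net <- shared_pathway_network(pw)
  expect_equal(net$pathways$degree[net$pathways$set_id == "shared"], 2L)
  expect_true(all(net$pathways$degree[net$pathways$set_id != "shared"] == 1L))
  expect_equal(sum(net$pathways$overlapping), 1)

  # a designed shared core across 4 chemicals
  core <- sprintf("core%d", 1:7)
  rows <- dplyr::bind_rows(lapply(sprintf("chem%d", 1:4), function(ch) {
    tibble::tibble(chemical = ch,
                   set_id = c(core, sprintf("%s_unique%d", ch, 1:3)))
  }))
  net4 <- shared_pathway_network(rows)
  expect_equal(sum(net4$pathways$degree == 4), 7)
  expect_equal(sum(net4$pathways$degree == 1), 12)
  expect_equal(nrow(net4$edges), 4 * 10)
})

test_that("gene BMD z-scores standardize rows and respect missingness", {
  bmd <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 3),
    chemical = rep(c("c1", "c2", "c3"), 3),
    bmd = c(5, 5, 5,  1, 2, 3,  2, 4, 9),
    flag = c(rep("pass", 8), "poor_fit"))
  m <- gene_bmd_matrix(bmd, c("g1", "g2", "g3"))
  expect_equal(m$z[m$gene_id == "g1"], c(0, 0, 0))  # identical BMDs
  expect_equal(m$z[m$gene_id == "g2"], (c(1, 2, 3) - 2) / 1, tolerance = 1e-10)
  g3 <- m[m$gene_id == "g3", ]
  expect_equal(nrow(g3), 2)   # failed QC cell is absent, not imputed
  expect_equal(g3$z, (c(2, 4) - 3) / sd(c(2, 4)), tolerance = 1e-10)
  # defined z-scores have mean 0 and sd 1 per gene
  z2 <- m$z[m$gene_id == "g2"]
  expect_equal(mean(z2), 0, tolerance = 1e-10)
  expect_equal(sd(z2), 1, tolerance = 1e-10)

  solo <- tibble::tibble(gene_id = "g", chemical = "c1", bmd = 2, flag = "pass")
  expect_true(is.na(gene_bmd_matrix(solo, "g")$z))
  expect_error(gene_bmd_matrix(bmd[9, ], "g3"), "no QC-passing")
})

test_that("dose trends are flat for constant genes and ordered for monotone ones", {
  design <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8), chemical = "chemA",
    dose = rep(c(0, 1, 10, 100), each = 2), replicate = rep(1:2, 4))
  counts <- tibble::tibble(gene_id = c("const1", "const2"))
  counts[design$sample_id] <- as.data.frame(rbind(rep(100L, 8), rep(40L, 8)))
  sf <- tibble::tibble(sample_id = design$sample_id, size_factor = 1)
  tr <- dose_trend(counts, design, "chemA", c("const1", "const2"), sf)
  expect_equal(length(unique(round(tr$mean_expr, 10))), 1)

  # strongly down-regulated set: strictly decreasing trend
  set.seed(3)
  cfg <- sim_config(n_null = 0, n_linear = 12, n_power = 0, n_hill = 0, seed = 41)
  sim <- simulate_experiment(cfg)
  down <- sim$truth$gene_id[sim$truth$direction == "down"]
  tr2 <- dose_trend(sim$counts, sim$design, "chemA", down)
  expect_lt(tr2$mean_expr[nrow(tr2)], tr2$mean_expr[1])
  expect_true(all(diff(tr2$mean_expr[tr2$dose >= 1]) < 0))

  # permuting sample order leaves the trend unchanged
  perm <- sample(nrow(sim$design))
  tr3 <- dose_trend(sim$counts[c(1, 1 + perm)], sim$design[perm, ],
                    "chemA", down)
  expect_equal(tr2, tr3)
})

test_that("top-k genes are ranked by extreme-dose change with stable ties", {
  design <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6), chemical = "chemA",
    dose = rep(c(0, 0.1, 100), each = 2), replicate = rep(1:2, 3))
  changes <- c(a = 1, b = 12, c = 3, d = 3, e = 0.5, f = 7,
               g = 2, h = 9, i = 4, j = 6, k = 5, l = 8)
  expr <- tibble::tibble(gene_id = names(changes))
  expr[design$sample_id] <- as.data.frame(
    cbind(0, 0, 0, 0, unname(changes), unname(changes)))
  top <- top_k_genes(expr, design, "chemA", names(changes), k = 10)
  expect_equal(top$gene_id,
               c("b", "h", "l", "f", "j", "k", "i", "c", "d", "g"))
  expect_equal(top$abs_change[1], 12)

  top1 <- top_k_genes(expr, design, "chemA", names(changes), k = 1)
  expect_equal(top1$gene_id, "b")

  expect_message(
    all_back <- top_k_genes(expr, design, "chemA", c("a", "b"), k = 10),
    "only 2")
  expect_equal(nrow(all_back), 2)

  # equal changes fall back to lexicographic order
  expr2 <- expr
  expr2[expr2$gene_id %in% c("c", "d"), c("s5", "s6")] <- 3
  top2 <- top_k_genes(expr2, design, "chemA", c("d", "c"), k = 2)
  expect_equal(top2$gene_id, c("c", "d"))
})
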