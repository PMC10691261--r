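make_sets <- function(...) {
  sets <- list(...)
  tibble::tibble(
    set_id = names(sets),
    set_name = paste("set", names(sets)),
    genes = unname(sets),
    n_genes = lengths(sets))
}

test_that("enrichment p equals the hypergeometric tail", {
  universe <- sprintf("g%d", 1:8)
  passing <- sprintf("g%d", 1:4)
  sets <- make_sets(S1 = c("g1", "g2", "g3", "g5"))
  got <- fisher_enrich(passing, universe, sets, min_genes = 1, p_max = 1)
  expect_equal(got$fisher_p, 17 / 70, tolerance = 1e-12)
  expect_equal(got$genes_observed, 3L)

  # independent cross-check with the two-sided machinery set one-sided
  ref <- fisher.test(matrix(c(3, 1, 1, 3), 2), alternative = "greater")$p.value
  expect_equal(got$fisher_p, ref, tolerance = 1e-12)

  # a set equal to the passing list has the smallest p among same-size sets
  sets2 <- make_sets(EXACT = passing, OTHER = c("g1", "g2", "g5", "g6"))
  got2 <- fisher_enrich(passing, universe, sets2, min_genes = 1, p_max = 1)
  expect_lt(got2$fisher_p[got2$set_id == "EXACT"],
            got2$fisher_p[got2$set_id == "OTHER"])
  expect_error(fisher_enrich(passing, character(0), sets), "empty")
})

test_that("enrichment matches the brute-force oracle on all small tables", {
  for (N in c(6, 9, 12)) {
    universe <- sprintf("u%d", seq_len(N))
    for (K in 1:N) {
      for (n_pass in 1:N) {
        passing <- universe[seq_len(n_pass)]
        sets <- make_sets(S = universe[seq_len(K)])
        got <- fisher_enrich(passing, universe, sets, min_genes = 0, p_max = 2)
        x <- length(intersect(passing, universe[seq_len(K)]))
        expect_equal(got$fisher_p, fisher_oracle(x, K, N, n_pass),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("enrichment p is monotone in overlap and invariant to relabeling", {
  # fixed margins N = 20, K = 6, n = 8: p decreases as the overlap grows
  ps <- vapply(2:6, function(x) fisher_oracle(x, 6, 20, 8), numeric(1))
  expect_true(all(diff(ps) < 0))

  universe <- sprintf("g%d", 1:10)
  sets <- make_sets(S = universe[3:7])
  a <- fisher_enrich(universe[1:5], universe, sets, min_genes = 1, p_max = 1)
  relabel <- setNames(sprintf("x%d", 10:1), universe)
  b <- fisher_enrich(unname(relabel[universe[1:5]]), unname(relabel),
                     make_sets(S = unname(relabel[universe[3:7]])),
                     min_genes = 1, p_max = 1)
  expect_equal(a$fisher_p, b$fisher_p)
})

test_that("pathway BMD aggregation takes means and medians over passing members", {
  bmd <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    flag = c("pass", "pass", "pass", "poor_fit"),
    bmd = c(1, 2, 10, 500), bmdl = c(0.5, 1, 5, 1), bmdu = c(2, 4, 20, 1000))
  agg <- aggregate_pathway_bmd(bmd, c("a", "b", "c", "d"))
  expect_equal(agg$n_passing, 3)
  expect_equal(agg$mean_bmd, 13 / 3)
  expect_equal(agg$median_bmd, 2)
  expect_true(agg$median_bmdl <= agg$median_bmd)
  expect_true(agg$median_bmd <= agg$median_bmdu)
  expect_null(aggregate_pathway_bmd(bmd[4, ], "d"))

  # member-wise ordering BMDL <= BMD <= BMDU propagates to the medians
  set.seed(66)
  for (i in 1:20) {
    k <- sample(1:9, 1)
    b <- sort(runif(k, 0, 10))
    tab <- tibble::tibble(
      gene_id = sprintf("g%d", seq_len(k)), flag = "pass",
      bmdl = b * runif(k, 0.2, 0.9), bmd = b,
      bmdu = b * runif(k, 1.1, 5))
    a <- aggregate_pathway_bmd(tab, tab$gene_id)
    expect_true(a$median_bmdl <= a$median_bmd && a$median_bmd <= a$median_bmdu)
  }
})

test_that("pathway filtering expresses both reported configurations", {
  rows <- tibble::tibble(
    set_id = sprintf("P%d", 1:5),
    fdr = c(0.02, 0.005, 0.005, 0.04, 0.002),
    genes_observed = c(7L, 6L, 4L, 9L, 12L),
    level = c(12L, 12L, 13L, 2L, 11L))
  # strict network configuration: FDR < 0.01, genes > 5, level > 11
  strict <- filter_pathways(rows, fdr_max = 0.01, min_genes = 5,
                            min_genes_inclusive = FALSE, level_gt = 11)
  expect_equal(strict$set_id, "P2")  # P1 fails fdr, P3 genes, P5 level
  # broad configuration: FDR < 0.05, genes >= 5, level = 2
  broad <- filter_pathways(rows, fdr_max = 0.05, min_genes = 5, level_eq = 2)
  expect_equal(broad$set_id, "P4")
  expect_error(filter_pathways(dplyr::select(rows, -level), level_gt = 11),
               "level")
})

test_that("accumulation data sorts, ranks and bounds pathway BMDs", {
  pw <- tibble::tibble(set_id = c("a", "b", "c"), median_bmd = c(2, 1, 3))
  acc <- accumulation_data(pw, max_dose = 100)
  expect_equal(acc$median_bmd, c(1, 2, 3))
  expect_equal(acc$cum_count, 1:3)

  tie <- tibble::tibble(set_id = c("b", "a", "c"), median_bmd = c(1, 1, 2))
  acc2 <- accumulation_data(tie, max_dose = 100)
  expect_equal(acc2$set_id, c("a", "b", "c"))   # stable by set id
  expect_equal(acc2$cum_count, 1:3)

  at_max <- tibble::tibble(set_id = "z", median_bmd = 100)
  expect_equal(nrow(accumulation_data(at_max, max_dose = 100)), 0)
})

test_that("a designed responsive set attains the minimum FDR", {
  set.seed(19)
  cfg <- sim_config(n_null = 150, n_linear = 10, n_power = 5, n_hill = 10, seed = 19)
  sim <- simulate_experiment(cfg)
  responsive <- sim$truth$gene_id[sim$truth$model != "null"]
  nulls <- sim$truth$gene_id[sim$truth$model == "null"]
  sets <- make_sets(
    RESPONSIVE = responsive,
    NULL1 = nulls[1:25], NULL2 = nulls[26:50], NULL3 = nulls[51:75],
    MIXED = c(nulls[76:95], responsive[1:5]))
  # stand-in for the BMD stage: every truly responsive gene passing QC
  bmd_tab <- tibble::tibble(
    gene_id = c(responsive, nulls),
    chemical = "chemA",
    flag = c(rep("pass", length(responsive)), rep("no_bmd", length(nulls))),
    bmd = 1, bmdl = 0.5, bmdu = 2)
  pw <- pathway_bmd(bmd_tab, sets, min_genes = 1, p_max = 1)
  expect_equal(pw$set_id[which.min(pw$fdr)], "RESPONSIVE")
})
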