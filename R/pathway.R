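#' Fisher-exact gene-set enrichment of BMD-passing genes
#'
#' One-sided (enrichment) Fisher exact test per gene set from the 2x2 table of
#' set membership against QC-passing status, over a stated gene universe.
#' P-values are BH-adjusted across all tested sets (those with at least one
#' universe member); a set is reported as enriched when it holds at least
#' `min_genes` passing members and its p-value is below `p_max`.
#'
#' @param passing Character vector of QC-passing gene ids (subset of universe).
#' @param universe Character vector: all genes eligible for enrichment
#'   (typically the genes that entered BMD modeling).
#' @param sets Gene-set tibble from [read_gmt()].
#' @param min_genes Minimum passing members (default 5, inclusive).
#' @param p_max Enrichment p cut (default 0.05).
#' @return A tibble with columns `set_id`, `set_name`, `n_universe`,
#'   `genes_observed`, `fisher_p`, `fdr`, plus a `member_genes` list column of
#'   the passing members.
#' @export
fisher_enrich <- function(passing, universe, sets, min_genes = 5, p_max = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("enrichment universe is empty")
  passing <- unique(passing)
  stray <- setdiff(passing, universe)
  if (length(stray) > 0) abort(sprintf("passing gene '%s' is not in the universe", stray[1]))
  N <- length(universe)
  n_pass <- length(passing)
  rows <- sets %>%
    mutate(
      members_in_universe = map(genes, intersect, universe),
      member_genes = map(members_in_universe, intersect, passing),
      n_universe = lengths(members_in_universe),
      genes_observed = lengths(member_genes)) %>%
    filter(n_universe > 0) %>%
    mutate(
      fisher_p = phyper(genes_observed - 1, n_universe, N - n_universe,
                        n_pass, lower.tail = FALSE),
      fdr = bh_adjust(fisher_p)) %>%
    select(set_id, set_name, n_universe, genes_observed, fisher_p, fdr, member_genes)
  filter(rows, genes_observed >= min_genes, fisher_p < p_max)
}

#' Pathway-level BMDL/BMD/BMDU aggregation
#'
#' Arithmetic mean and median of each quantity over a pathway's QC-passing
#' member genes.
#'
#' @param bmd_results A [fit_bmd()] tibble.
#' @param member_genes Character vector of the pathway's member gene ids.
#' @return A one-row tibble: `n_passing`, `mean_bmdl`, `mean_bmd`, `mean_bmdu`,
#'   `median_bmdl`, `median_bmd`, `median_bmdu`; `NULL` when no member passes.
#' @export
aggregate_pathway_bmd <- function(bmd_results, member_genes) {
  rows <- filter(bmd_results, gene_id %in% member_genes, flag == "pass")
  if (nrow(rows) == 0) return(NULL)
  tibble(
    n_passing = nrow(rows),
    mean_bmdl = mean(rows$bmdl), mean_bmd = mean(rows$bmd), mean_bmdu = mean(rows$bmdu),
    median_bmdl = median(rows$bmdl), median_bmd = median(rows$bmd),
    median_bmdu = median(rows$bmdu))
}

#' Pathway benchmark-dose table for one chemical
#'
#' Combines Fisher enrichment over the QC-passing genes with pathway-level
#' BMDL/BMD/BMDU aggregation. The enrichment universe defaults to every gene
#' that entered BMD modeling for the chemical (all rows of `bmd_results`).
#'
#' @param bmd_results A [fit_bmd()] tibble for one chemical.
#' @param sets Gene-set tibble from [read_gmt()].
#' @param universe Optional explicit universe (e.g. all assayed genes).
#' @param levels Optional tibble from [ontology_levels()]; adds a `level`
#'   column.
#' @param min_genes,p_max Passed to [fisher_enrich()].
#' @return A tibble: enrichment columns plus aggregated BMD statistics and,
#'   when available, `level`.
#' @export
pathway_bmd <- function(bmd_results, sets, universe = NULL, levels = NULL,
                        min_genes = 5, p_max = 0.05) {
  if (is.null(universe)) universe <- unique(bmd_results$gene_id)
  passing <- unique(bmd_results$gene_id[bmd_results$flag == "pass"])
  enr <- fisher_enrich(passing, universe, sets, min_genes, p_max)
  agg <- map(enr$member_genes, ~ aggregate_pathway_bmd(bmd_results, .x))
  keep <- !vapply(agg, is.null, logical(1))
  if (any(!keep)) {
    inform(sprintf("dropping %d enriched set(s) with no QC-passing members", sum(!keep)))
  }
  out <- dplyr::bind_cols(
    select(enr[keep, ], -member_genes),
    list_rbind(agg[keep]))
  if (!is.null(levels)) out <- left_join(out, levels, by = "set_id")
  out
}

#' Filter pathway results by FDR, gene count and ontology level
#'
#' Conjunction of up to three predicates, expressing both reported
#' configurations: FDR < 0.05, genes >= 5, GO level = 2; and the stricter
#' FDR < 0.01, genes > 5, GO level > 11.
#'
#' @param pathways A [pathway_bmd()] tibble.
#' @param fdr_max Maximum FDR.
#' @param min_genes Minimum `genes_observed`.
#' @param min_genes_inclusive If `TRUE` (default) the gene cut is `>=`,
#'   otherwise strict `>`.
#' @param level_eq Keep only pathways at exactly this ontology level.
#' @param level_gt Keep only pathways with level strictly above this.
#' @return The filtered tibble.
#' @export
filter_pathways <- function(pathways, fdr_max = 0.05, min_genes = 5,
                            min_genes_inclusive = TRUE,
                            level_eq = NULL, level_gt = NULL) {
  out <- filter(pathways, fdr < fdr_max)
  out <- if (min_genes_inclusive) filter(out, genes_observed >= min_genes)
         else filter(out, genes_observed > min_genes)
  if (!is.null(level_eq) || !is.null(level_gt)) {
    if (!"level" %in% names(out)) {
      abort("a level filter was requested but the pathway table has no 'level' column")
    }
    if (!is.null(level_eq)) out <- filter(out, !is.na(level), level == level_eq)
    if (!is.null(level_gt)) out <- filter(out, !is.na(level), level > level_gt)
  }
  out
}

#' Accumulation-curve data for pathway benchmark doses
#'
#' Orders pathways by median BMD (ties broken by set id) and returns the
#' cumulative count at each BMD — the data behind a BMD median accumulation
#' plot. Pathways whose median BMD is not below the maximum tested dose are
#' excluded.
#'
#' @param pathways A [pathway_bmd()] tibble.
#' @param max_dose Highest tested dose.
#' @return A tibble with `set_id`, `median_bmd` (ascending) and `cum_count`.
#' @export
accumulation_data <- function(pathways, max_dose) {
  pathways %>%
    filter(median_bmd < max_dose) %>%
    arrange(median_bmd, set_id) %>%
    mutate(cum_count = row_number()) %>%
    select(set_id, median_bmd, cum_count)
}
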