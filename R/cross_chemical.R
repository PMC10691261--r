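#' Exclusive intersection (UpSet) counts
#'
#' For every nonempty combination of the input sets, counts the elements that
#' belong to exactly that combination. Counts over all patterns sum to the
#' size of the union.
#'
#' @param sets Named list of character vectors (gene or pathway ids).
#' @return A tibble with `pattern` (set names joined by `&`), `degree` (number
#'   of sets in the pattern) and `exclusive_count`, sorted by count descending
#'   then degree, with zero-count patterns omitted.
#' @export
upset_counts <- function(sets) {
  if (length(sets) < 2) abort("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) abort("sets must be named")
  sets <- lapply(sets, unique)
  elements <- unique(unlist(sets))
  membership <- vapply(sets, function(s) elements %in% s, logical(length(elements)))
  membership <- matrix(membership, nrow = length(elements),
                       dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1, function(row) paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  out <- tibble(
    pattern = names(tab),
    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
    exclusive_count = as.integer(tab))
  arrange(out, desc(exclusive_count), degree, pattern)
}

#' Chemical-pathway network from per-chemical significant pathways
#'
#' Builds the bipartite edge list chemical -> pathway from already-filtered
#' per-chemical pathway tables, and annotates each pathway with the number of
#' chemicals sharing it; "overlapping" pathways are those of degree >= 2.
#'
#' @param pathways A tibble with columns `chemical` and `set_id` (e.g. rows of
#'   [filter_pathways()] output bound across chemicals).
#' @return A list with `edges` (tibble `chemical`, `set_id`) and `pathways`
#'   (tibble `set_id`, `degree`, `overlapping`).
#' @export
shared_pathway_network <- function(pathways) {
  edges <- distinct(pathways, chemical, set_id)
  deg <- edges %>%
    count(set_id, name = "degree") %>%
    mutate(overlapping = degree >= 2) %>%
    arrange(desc(degree), set_id)
  list(edges = arrange(edges, chemical, set_id), pathways = deg)
}

#' Gene-level BMD matrix for one pathway across chemicals
#'
#' Collects each member gene's QC-passing BMD per chemical (median when a gene
#' has several passing records) and standardizes each gene across chemicals as
#' a z-score, ignoring missing cells; genes observed in fewer than two
#' chemicals get an undefined (missing) z-score.
#'
#' @param bmd_results Combined [fit_bmd()] tibbles across chemicals (columns
#'   `gene_id`, `chemical`, `bmd`, `flag`).
#' @param pathway_genes Member gene ids of the pathway.
#' @return A long tibble `gene_id`, `chemical`, `bmd`, `z`.
#' @export
gene_bmd_matrix <- function(bmd_results, pathway_genes) {
  cells <- bmd_results %>%
    filter(gene_id %in% pathway_genes, flag == "pass") %>%
    group_by(gene_id, chemical) %>%
    summarise(bmd = median(bmd), .groups = "drop")
  if (nrow(cells) == 0) abort("pathway has no QC-passing genes in any chemical")
  cells %>%
    group_by(gene_id) %>%
    mutate(z = if (dplyr::n() < 2) NA_real_
               else if (sd(bmd) > 0) (bmd - mean(bmd)) / sd(bmd)
               else 0) %>%
    ungroup() %>%
    arrange(gene_id, chemical)
}

#' Per-dose mean expression trend of a gene set
#'
#' For each dose of a chemical, the mean over the given genes of
#' `log10(normalized count mean across replicates + 0.1)` — the data behind a
#' pathway dose-trend plot.
#'
#' @param counts Count tibble.
#' @param design Dose design tibble.
#' @param chemical Chemical name.
#' @param genes Member gene ids.
#' @param size_factors Optional size factors; computed from `counts` if `NULL`.
#' @return A tibble `dose`, `mean_expr` sorted by dose.
#' @export
dose_trend <- function(counts, design, chemical, genes, size_factors = NULL) {
  counts <- validate_counts(counts)
  design <- validate_design(design)
  chem <- chemical
  des <- filter(design, chemical == chem)
  missing <- setdiff(genes, counts$gene_id)
  if (length(missing) > 0) abort(sprintf("gene '%s' absent from counts", missing[1]))
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- size_factor_vector(size_factors, des$sample_id)
  m <- sweep(as.matrix(counts[match(genes, counts$gene_id), des$sample_id]), 2, sf, "/")
  doses <- sort(unique(des$dose))
  trend <- vapply(doses, function(d) {
    gene_means <- rowMeans(m[, des$dose == d, drop = FALSE])
    mean(log10(gene_means + 0.1))
  }, numeric(1))
  tibble(dose = doses, mean_expr = trend)
}

#' Most-regulated genes between the extreme doses
#'
#' Ranks genes by the absolute difference of mean log2 expression between the
#' highest and the lowest nonzero dose of a chemical, descending, with ties
#' broken by gene id, and returns the top `k`.
#'
#' @param expr Log2 expression tibble from [log2_matrix()].
#' @param design Dose design tibble.
#' @param chemical Chemical name.
#' @param genes Candidate gene ids.
#' @param k Number of genes to return (default 10).
#' @param from_vehicle If `TRUE`, contrast against the vehicle (dose 0) rather
#'   than the lowest nonzero dose.
#' @return A tibble `gene_id`, `abs_change`, at most `k` rows.
#' @export
top_k_genes <- function(expr, design, chemical, genes, k = 10,
                        from_vehicle = FALSE) {
  design <- validate_design(design)
  chem <- chemical
  des <- filter(design, chemical == chem)
  missing <- setdiff(genes, expr$gene_id)
  if (length(missing) > 0) abort(sprintf("gene '%s' absent from expression matrix", missing[1]))
  lo_dose <- if (from_vehicle) 0 else min(des$dose[des$dose > 0])
  hi_dose <- max(des$dose)
  m <- as.matrix(expr[match(genes, expr$gene_id), des$sample_id])
  lo <- rowMeans(m[, des$dose == lo_dose, drop = FALSE])
  hi <- rowMeans(m[, des$dose == hi_dose, drop = FALSE])
  out <- tibble(gene_id = genes, abs_change = abs(hi - lo)) %>%
    arrange(desc(abs_change), gene_id)
  if (nrow(out) < k) {
    inform(sprintf("only %d genes available; returning all", nrow(out)))
    return(out)
  }
  head(out, k)
}
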