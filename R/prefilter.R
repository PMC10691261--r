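#' Log2 expression matrix from counts
#'
#' Size-factor-normalizes counts and transforms to `log2(count/sf + 0.1)`;
#' the 0.1 offset stabilizes zeros (a zero count maps to `log2(0.1)`).
#'
#' @param counts Count tibble.
#' @param size_factors Size factors (tibble or named vector); computed by
#'   [estimate_size_factors()] when `NULL`.
#' @return A tibble with `gene_id` plus one numeric column per sample.
#' @export
log2_matrix <- function(counts, size_factors = NULL) {
  counts <- validate_counts(counts)
  sample_ids <- setdiff(names(counts), "gene_id")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- size_factor_vector(size_factors, sample_ids)
  m <- sweep(as.matrix(counts[sample_ids]), 2, sf, "/")
  out <- tibble(gene_id = counts$gene_id)
  out[sample_ids] <- as.data.frame(log2(m + 0.1))
  out
}

# vectorized one-way ANOVA across the columns of a genes x samples matrix
oneway_f <- function(m, group) {
  group <- factor(group)
  G <- nlevels(group)
  N <- ncol(m)
  sizes <- as.vector(table(group))
  if (any(sizes < 2)) {
    abort(sprintf("dose group '%s' has fewer than 2 samples",
                  levels(group)[which(sizes < 2)[1]]))
  }
  ind <- stats::model.matrix(~ 0 + group)
  means <- (m %*% ind) %*% diag(1 / sizes, G)
  grand <- rowMeans(m)
  ssb <- as.vector(((means - grand)^2) %*% sizes)
  ssw <- rowSums((m - means[, as.integer(group), drop = FALSE])^2)
  df1 <- G - 1
  df2 <- N - G
  f <- (ssb / df1) / (ssw / df2)
  # all-equal genes: 0/0 -> define F = 0; exact group fits: ssw = 0 -> F = Inf
  f[ssb <= .Machine$double.eps * N] <- 0
  p <- pf(f, df1, df2, lower.tail = FALSE)
  p[f == 0] <- 1
  list(f = f, p = p, group_means = means, levels = levels(group))
}

#' ANOVA plus fold-change prefilter for dose-responsive genes
#'
#' The pre-step before benchmark-dose modeling: a classical one-way ANOVA per
#' gene across all dose groups of a chemical (null hypothesis: all dose means
#' equal), BH adjustment of the p-values across genes, and the maximum
#' absolute log2 fold change of any dose versus the vehicle control. A gene is
#' retained when `max |FC| > fc_min` and the (adjusted) p-value is below
#' `alpha`.
#'
#' @param expr Log2 expression tibble from [log2_matrix()].
#' @param design Dose design tibble.
#' @param chemical Chemical name.
#' @param fc_min Linear fold-change cut (default 1.5).
#' @param alpha Significance cut on the (adjusted) ANOVA p (default 0.05).
#' @param padjust `"BH"` (default) adjusts across genes; `"none"` uses raw
#'   p-values.
#' @return A tibble with columns `gene_id`, `f_stat`, `p_value`, `p_adj`,
#'   `max_abs_l2fc`, `retained`.
#' @export
anova_prefilter <- function(expr, design, chemical, fc_min = 1.5, alpha = 0.05,
                            padjust = c("BH", "none")) {
  padjust <- match.arg(padjust)
  design <- validate_design(design)
  chem <- chemical
  des <- filter(design, chemical == chem)
  if (nrow(des) == 0) abort(sprintf("chemical '%s' not in design", chem))
  missing <- setdiff(des$sample_id, names(expr))
  if (length(missing) > 0) abort(sprintf("sample '%s' absent from expression matrix", missing[1]))
  m <- as.matrix(expr[des$sample_id])
  rownames(m) <- expr$gene_id
  if (length(unique(des$dose)) < 2) abort("need >= 2 dose groups")
  res <- oneway_f(m, des$dose)
  ctl_idx <- which(as.numeric(res$levels) == 0)
  fc <- abs(res$group_means[, -ctl_idx, drop = FALSE] - res$group_means[, ctl_idx])
  max_fc <- apply(fc, 1, max)
  p_adj <- if (padjust == "BH") bh_adjust(res$p) else res$p
  tibble(
    gene_id = expr$gene_id,
    f_stat = unname(res$f),
    p_value = unname(res$p),
    p_adj = unname(p_adj),
    max_abs_l2fc = unname(max_fc),
    retained = unname(max_fc) > log2(fc_min) & p_adj < alpha)
}
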