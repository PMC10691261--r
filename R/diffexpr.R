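#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of the
#' ratio of each sample's count to the per-gene geometric mean, using only
#' genes with nonzero counts in every sample.
#'
#' @param counts A count tibble (`gene_id` plus sample columns).
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  counts <- validate_counts(counts)
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  logm <- log(m)
  log_geo <- rowMeans(logm)
  use <- is.finite(log_geo)
  if (!any(use)) {
    abort(paste("no gene has nonzero counts in every sample;",
                "consider filtering samples or supplying a pseudo-reference"))
  }
  sf <- apply(logm[use, , drop = FALSE], 2, function(col) exp(median(col - log_geo[use])))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

size_factor_vector <- function(size_factors, sample_ids) {
  if (is.data.frame(size_factors)) {
    sf <- setNames(size_factors$size_factor, size_factors$sample_id)
  } else {
    sf <- size_factors
  }
  missing <- setdiff(sample_ids, names(sf))
  if (length(missing) > 0) abort(sprintf("no size factor for sample '%s'", missing[1]))
  sf[sample_ids]
}

# dispersion of normalized counts by method of moments, shrunk toward a
# mean-dispersion trend phi(mu) = a0 + a1/mu; prior weight d0 residual df
estimate_dispersions <- function(norm, group, prior_df = 6) {
  groups <- split(seq_len(ncol(norm)), group)
  ns <- lengths(groups)
  mu_g <- matrix(vapply(groups, function(j) rowMeans(norm[, j, drop = FALSE]),
                        numeric(nrow(norm))), nrow = nrow(norm))
  v_g <- matrix(vapply(groups, function(j) apply(norm[, j, drop = FALSE], 1, var),
                       numeric(nrow(norm))), nrow = nrow(norm))
  df <- sum(ns) - length(ns)
  v_pool <- as.vector(v_g %*% (ns - 1)) / df
  mu_bar <- as.vector(mu_g %*% ns) / sum(ns)
  phi_mom <- pmax((v_pool - mu_bar) / mu_bar^2, 1e-8)
  ok <- mu_bar > 1 & is.finite(phi_mom)
  trend <- c(a0 = mean(phi_mom[ok], trim = 0.05, na.rm = TRUE), a1 = 0)
  if (sum(ok) >= 10) {
    fit <- tryCatch(lm(phi_mom[ok] ~ I(1 / mu_bar[ok])), error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
      co <- stats::coef(fit)
      # only adopt the sloped trend when both pieces are admissible; a clipped
      # slope with the sloped fit's intercept would inflate the trend
      if (co[1] > 0 && co[2] > 0) trend <- c(a0 = unname(co[1]), a1 = unname(co[2]))
    }
  }
  phi_trend <- pmax(trend[["a0"]] + trend[["a1"]] / mu_bar, 1e-8)
  phi <- (df * phi_mom + prior_df * phi_trend) / (df + prior_df)
  list(phi = phi, mu = mu_bar, trend = trend, df = df)
}

#' Negative-binomial Wald test of one dose against the vehicle control
#'
#' Tests each gene for differential expression between the samples of one
#' chemical at one dose and that chemical's vehicle (dose 0) samples. Counts
#' are normalized by median-of-ratios size factors; per-gene dispersions are
#' estimated by method of moments and shrunk toward a fitted mean-dispersion
#' trend; the Wald statistic is the log2 fold change of normalized group means
#' (with a +0.5 pseudo-mean guard) over its delta-method standard error, and
#' the reference distribution is a t with the moderated residual degrees of
#' freedom. Genes with zero counts in every tested sample are excluded before
#' testing; p-values are Benjamini-Hochberg adjusted across the tested genes.
#'
#' @param counts Count tibble.
#' @param design Dose design tibble.
#' @param chemical Chemical name.
#' @param dose Treated dose (> 0) present in the design for that chemical.
#' @param size_factors Optional precomputed size factors (tibble or named
#'   vector); by default computed from the tested samples.
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @return A tibble with columns `gene_id`, `chemical`, `dose`, `base_mean`,
#'   `log2_fc`, `p_value`, `fdr`.
#' @export
nb_test <- function(counts, design, chemical, dose, size_factors = NULL,
                    prior_df = 6) {
  counts <- validate_counts(counts)
  design <- validate_design(design)
  check_counts_design(counts, design)
  chem <- chemical
  trt <- design$sample_id[design$chemical == chem & design$dose == dose]
  ctl <- design$sample_id[design$chemical == chem & design$dose == 0]
  if (dose <= 0) abort("dose must be a treated (nonzero) dose")
  if (length(trt) < 2 || length(ctl) < 2) {
    abort(sprintf("need >= 2 replicates per group; got %d treated, %d control",
                  length(trt), length(ctl)))
  }
  sub <- counts[c("gene_id", ctl, trt)]
  m <- as.matrix(sub[-1])
  rownames(m) <- sub$gene_id
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) abort("no gene has a nonzero count in the tested samples")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(sub[keep, ])
  sf <- size_factor_vector(size_factors, colnames(m))
  norm <- sweep(m, 2, sf, "/")
  group <- c(rep("control", length(ctl)), rep("treated", length(trt)))

  disp <- estimate_dispersions(norm, group, prior_df = prior_df)
  i_c <- seq_along(ctl); i_t <- length(ctl) + seq_along(trt)
  m_c <- rowMeans(norm[, i_c, drop = FALSE])
  m_t <- rowMeans(norm[, i_t, drop = FALSE])
  l2fc <- log2((m_t + 0.5) / (m_c + 0.5))

  var_group_mean <- function(mu, idx) {
    n <- length(idx)
    (mu * mean(1 / sf[idx]) / n) + disp$phi * mu^2 / n
  }
  ln2sq <- log(2)^2
  v_log <- var_group_mean(m_c, i_c) / ((m_c + 0.5)^2 * ln2sq) +
           var_group_mean(m_t, i_t) / ((m_t + 0.5)^2 * ln2sq)
  z <- l2fc / sqrt(pmax(v_log, 1e-12))
  df_mod <- disp$df + prior_df
  p <- 2 * stats::pt(-abs(z), df = df_mod)
  p[!is.finite(p)] <- 1
  tibble(
    gene_id = rownames(m), chemical = chem, dose = dose,
    base_mean = unname((m_c + m_t) / 2),
    log2_fc = unname(l2fc), p_value = unname(p), fdr = bh_adjust(unname(p)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values (capped at 1, monotone after the step-up pass).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Significance threshold regime
#'
#' The two regimes used for calling differentially expressed genes: lenient
#' (|FC| > 1.5, FDR < 0.05) and stringent (|FC| > 2, FDR < 0.01).
#'
#' @param fc_min Minimum absolute linear fold change (> 1).
#' @param fdr_max Maximum FDR (in (0, 1)).
#' @return A `threshold_regime` list.
#' @export
threshold_regime <- function(fc_min, fdr_max) {
  if (fc_min <= 1) abort("fc_min must exceed 1")
  if (fdr_max <= 0 || fdr_max >= 1) abort("fdr_max must lie in (0, 1)")
  structure(list(fc_min = fc_min, fdr_max = fdr_max), class = "threshold_regime")
}

#' @rdname threshold_regime
#' @param name `"stringent"` (|FC| > 2, FDR < 0.01) or `"lenient"`
#'   (|FC| > 1.5, FDR < 0.05).
#' @export
regime_preset <- function(name = c("stringent", "lenient")) {
  name <- match.arg(name)
  if (name == "stringent") threshold_regime(2, 0.01) else threshold_regime(1.5, 0.05)
}

#' Filter differential-expression results to significant genes
#'
#' Keeps genes with `|log2_fc| > log2(fc_min)` and `fdr < fdr_max`.
#'
#' @param deg A tibble from [nb_test()] (one chemical-dose condition).
#' @param regime A [threshold_regime()].
#' @return The significant subset of `deg`.
#' @export
deg_filter <- function(deg, regime) {
  stopifnot(inherits(regime, "threshold_regime"))
  filter(deg, abs(log2_fc) > log2(regime$fc_min), fdr < regime$fdr_max)
}

#' DEG counts per chemical and dose
#'
#' Counts significant genes for every (chemical, dose) condition present in
#' the input and returns the chemicals x doses count table, with zero counts
#' for conditions where nothing passes. Rows can be ordered by hierarchical
#' clustering of the count profiles via [hclust_order()].
#'
#' @param deg Combined [nb_test()] results over chemicals and doses.
#' @param regime A [threshold_regime()].
#' @return A wide tibble: `chemical` column plus one integer column per dose.
#' @export
deg_count_matrix <- function(deg, regime) {
  stopifnot(inherits(regime, "threshold_regime"))
  conditions <- distinct(deg, chemical, dose)
  counts <- deg_filter(deg, regime) %>%
    count(chemical, dose, name = "n_deg")
  conditions %>%
    left_join(counts, by = c("chemical", "dose")) %>%
    mutate(n_deg = as.integer(dplyr::coalesce(n_deg, 0L))) %>%
    arrange(chemical, dose) %>%
    tidyr::pivot_wider(names_from = dose, values_from = n_deg, values_fill = 0L)
}

#' Deterministic hierarchical-clustering row order
#'
#' Average-linkage clustering on Euclidean distances of the numeric columns,
#' with ties broken by label so the leaf order is reproducible.
#'
#' @param x A data frame whose first column holds labels and remaining numeric
#'   columns the profiles.
#' @return Character vector of labels in display order.
#' @export
hclust_order <- function(x) {
  labels <- x[[1]]
  m <- as.matrix(x[-1])
  if (nrow(m) < 3) return(labels[order(labels)][seq_len(nrow(m))])
  ord <- order(labels)
  m <- m[ord, , drop = FALSE]
  hc <- hclust(dist(m), method = "average")
  labels[ord][hc$order]
}
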