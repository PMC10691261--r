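#' Plot a fitted gene dose-response curve
#'
#' Observed log2 values, the selected model's fitted curve on a dense dose
#' grid, and vertical reference lines at the BMD and its profile bounds.
#'
#' @param object A `bmd_fit` from [fit_gene_bmd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bmd_fit
#' @export
autoplot.bmd_fit <- function(object, ...) {
  df <- tibble(dose = object$dose, y = object$y)
  p <- ggplot2::ggplot(df, ggplot2::aes(dose, y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "dose (µM)", y = "log2 expression")
  if (!is.null(object$best)) {
    dmax <- max(object$dose)
    grid <- c(0, exp(seq(log(dmax * 1e-4), log(dmax), length.out = 200)))
    curve <- tibble(dose = grid,
                    y = dr_mean(object$best$kind, object$best$params, grid))
    p <- p + ggplot2::geom_line(data = curve, color = "steelblue") +
      ggplot2::ggtitle(sprintf("best model: %s", object$best$kind))
    if (is.finite(object$bmd)) {
      p <- p + ggplot2::geom_vline(xintercept = object$bmd, linetype = 2) +
        ggplot2::geom_vline(xintercept = c(object$bmdl, object$bmdu),
                            linetype = 3, color = "grey50")
    }
  }
  p
}

#' Heatmap of DEG counts per chemical and dose
#'
#' @param deg_counts Wide tibble from [deg_count_matrix()].
#' @return A ggplot object; rows ordered by hierarchical clustering.
#' @export
plot_deg_counts <- function(deg_counts) {
  ord <- hclust_order(deg_counts)
  long <- tidyr::pivot_longer(deg_counts, -chemical, names_to = "dose",
                              values_to = "n_deg") %>%
    mutate(dose = factor(as.numeric(dose), levels = sort(unique(as.numeric(dose)))),
           chemical = factor(chemical, levels = ord))
  ggplot2::ggplot(long, ggplot2::aes(dose, chemical, fill = n_deg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "DEGs") +
    ggplot2::labs(x = "dose (µM)", y = NULL)
}

#' BMD median accumulation plot
#'
#' @param acc Tibble from [accumulation_data()].
#' @return A ggplot object (log10 dose axis).
#' @export
plot_accumulation <- function(acc) {
  ggplot2::ggplot(acc, ggplot2::aes(median_bmd, cum_count)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "median pathway BMD (µM)", y = "pathways accumulated")
}

#' Bar chart of exclusive intersection counts
#'
#' @param upset Tibble from [upset_counts()].
#' @param top Show at most this many patterns.
#' @return A ggplot object.
#' @export
plot_upset <- function(upset, top = 20) {
  df <- head(upset, top) %>%
    mutate(pattern = factor(pattern, levels = rev(pattern)))
  ggplot2::ggplot(df, ggplot2::aes(exclusive_count, pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "exclusive count", y = NULL)
}

#' Dose-trend line for a gene set
#'
#' @param trend Tibble from [dose_trend()].
#' @return A ggplot object.
#' @export
plot_dose_trend <- function(trend) {
  df <- mutate(trend, dose_axis = ifelse(dose == 0, min(dose[dose > 0]) / 3, dose))
  ggplot2::ggplot(df, ggplot2::aes(dose_axis, mean_expr)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µM; vehicle shown left of axis)",
                  y = "log10 mean expression")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
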