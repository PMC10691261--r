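#' Simulation configuration
#'
#' Defines a synthetic dose-response count experiment mirroring a typical
#' concentration-response screen: one vehicle control (dose 0) plus 8
#' log-spaced concentrations per chemical, a few replicates per dose, and
#' negative-binomial counts whose per-gene dose-response means follow known
#' curves on the log2 scale.
#'
#' The truth benchmark dose of each responsive gene is computed analytically
#' from its generating curve at a benchmark response of 1 x `sigma` (log2
#' units), so it depends only on the curve and `sigma` — not on sequencing
#' depth or count dispersion.
#'
#' @param n_null,n_linear,n_power,n_hill Number of genes per generator class.
#' @param doses Dose grid in micromolar; must start at 0 (vehicle) and be
#'   strictly increasing.
#' @param replicates Replicates per dose level (>= 2).
#' @param dispersion Negative-binomial dispersion of counts (> 0).
#' @param baseline_mean Expected count of an unperturbed gene at unit depth (> 0).
#' @param sigma Residual SD on the log2 scale that defines the benchmark
#'   response for the truth BMD.
#' @param depth_factors Per-sample relative sequencing depth; scalar or vector
#'   recycled across the samples of each chemical.
#' @param chemicals Character vector of chemical names to simulate.
#' @param bmd_range Range (micromolar) from which target truth BMDs are drawn
#'   log-uniformly; defaults to the span from the lowest nonzero dose to a
#'   third of the highest dose so that truth BMDs are well inside the design.
#' @param seed Master seed; per-gene streams are derived from it so gene
#'   subsets are reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_null = 100, n_linear = 20, n_power = 20, n_hill = 20,
                       doses = c(0, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100),
                       replicates = 3, dispersion = 0.02, baseline_mean = 500,
                       sigma = 0.2, depth_factors = 1, chemicals = "chemA",
                       bmd_range = NULL, seed = 1) {
  if (replicates < 2) abort("replicates must be >= 2")
  if (any(diff(doses) <= 0)) abort("doses must be strictly increasing")
  if (doses[1] != 0) abort("dose grid must start at 0 (vehicle control)")
  if (dispersion <= 0) abort("dispersion must be positive")
  if (baseline_mean <= 0) abort("baseline_mean must be positive")
  if (sigma <= 0) abort("sigma must be positive")
  if (any(depth_factors <= 0)) abort("depth_factors must be positive")
  if (is.null(bmd_range)) bmd_range <- c(min(doses[doses > 0]), max(doses) / 3)
  structure(
    list(n_null = n_null, n_linear = n_linear, n_power = n_power,
         n_hill = n_hill, doses = doses, replicates = replicates,
         dispersion = dispersion, baseline_mean = baseline_mean,
         sigma = sigma, depth_factors = depth_factors, chemicals = chemicals,
         bmd_range = bmd_range, seed = as.integer(seed)),
    class = "sim_config")
}

#' Analytic benchmark dose of a generating curve
#'
#' Smallest dose `d > 0` at which the curve's mean departs from the control
#' mean by the benchmark response (1 x `sigma`, absolute change on the log2
#' scale), or `NA` if the curve never reaches it (null genes, or a Hill
#' plateau below the BMR).
#'
#' Closed forms: linear `sigma/|b1|`; power `(sigma/|b|)^(1/delta)`; hill
#' `k * (sigma/(|v| - sigma))^(1/n)` when `|v| > sigma`.
#'
#' @param model `"null"`, `"linear"`, `"power"` or `"hill"`.
#' @param params Named list of curve parameters (see [dr_mean()]).
#' @param sigma Positive benchmark response (log2 units).
#' @return Positive dose in micromolar, or `NA_real_` when unreachable.
#' @export
analytic_bmd <- function(model, params, sigma) {
  if (sigma <= 0) abort("sigma must be positive")
  p <- as.list(params)
  switch(model,
    null = NA_real_,
    linear = if (p$b1 == 0) NA_real_ else sigma / abs(p$b1),
    power = if (p$b == 0) NA_real_ else (sigma / abs(p$b))^(1 / p$delta),
    hill = if (abs(p$v) > sigma) p$k * (sigma / (abs(p$v) - sigma))^(1 / p$n)
           else NA_real_,
    abort(sprintf("unknown generator model '%s'", model))
  )
}

draw_gene_truth <- function(model, config) {
  g0 <- log2(config$baseline_mean)
  sgn <- if (stats::runif(1) < 0.5) 1 else -1
  direction <- if (sgn > 0) "up" else "down"
  d_max <- max(config$doses)
  s <- config$sigma
  # maximum absolute log2 change at the top dose: log-uniform in a realistic
  # 0.5-4 range (1.4- to 16-fold), floored well above the BMR so every
  # responsive gene has a reachable truth BMD
  eff_lo <- max(0.5, 2.5 * s)
  effect <- exp(stats::runif(1, log(eff_lo), log(4)))
  params <- switch(model,
    null = list(b0 = g0),
    linear = list(b0 = g0, b1 = sgn * effect / d_max),
    power = {
      delta <- stats::runif(1, 1.2, 3)
      list(g = g0, b = sgn * effect / d_max^delta, delta = delta)
    },
    hill = {
      n <- stats::runif(1, 1, 4)
      k <- exp(stats::runif(1, log(config$bmd_range[1]), log(config$bmd_range[2])))
      list(g = g0, v = sgn * effect, k = k, n = n)
    })
  mean_kind <- if (model == "null") "null" else model
  list(model = model, params = params, direction = direction,
       true_bmd = analytic_bmd(model, params, s), mean_kind = mean_kind)
}

#' Simulate a dose-response count experiment with known truth
#'
#' Draws, per gene and dose, negative-binomial counts with mean
#' `depth * 2^mu_g(dose)` where `mu_g` follows the gene's generating curve
#' (null, linear, power or Hill on the log2 scale), and returns the count
#' table, the dose design and a truth table with each gene's generator, its
#' parameters and its analytic benchmark dose.
#'
#' The same seed and configuration always reproduce the identical experiment;
#' per-gene random streams are derived from the master seed so that any subset
#' of genes is reproducible on its own.
#'
#' @param config A [sim_config()] object.
#' @return A list with tibbles `counts`, `design` and `truth`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- config$n_null + config$n_linear + config$n_power + config$n_hill
  models <- rep(c("null", "linear", "power", "hill"),
                c(config$n_null, config$n_linear, config$n_power, config$n_hill))
  gene_ids <- sprintf("gene_%04d_%s", seq_len(n_genes), models)

  set.seed(config$seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, n_genes)

  n_per_chem <- length(config$doses) * config$replicates
  depth <- rep_len(config$depth_factors, n_per_chem)
  dose_vec <- rep(config$doses, each = config$replicates)

  design <- purrr::map(config$chemicals, function(chem) {
    tibble(
      sample_id = sprintf("%s_d%02d_r%d", chem,
                          rep(seq_along(config$doses), each = config$replicates),
                          rep(seq_len(config$replicates), length(config$doses))),
      chemical = chem,
      dose = dose_vec,
      replicate = rep(seq_len(config$replicates), length(config$doses))
    )
  }) %>% list_rbind()

  truth_rows <- vector("list", n_genes)
  count_rows <- matrix(0L, nrow = n_genes, ncol = nrow(design))
  size <- 1 / config$dispersion
  for (g in seq_len(n_genes)) {
    set.seed(gene_seeds[g])
    tr <- draw_gene_truth(models[g], config)
    mu <- dr_mean(tr$mean_kind, tr$params, dose_vec)
    mean_counts <- rep(depth, length(config$chemicals)) * 2^rep(mu, length(config$chemicals))
    count_rows[g, ] <- rnbinom(length(mean_counts), mu = mean_counts, size = size)
    p <- tr$params
    truth_rows[[g]] <- tibble(
      gene_id = gene_ids[g], model = tr$model,
      gamma = if (!is.null(p$b0)) p$b0 else p$g,
      beta = if (tr$model == "linear") p$b1 else if (tr$model == "power") p$b else NA_real_,
      delta = if (tr$model == "power") p$delta else NA_real_,
      nu = if (tr$model == "hill") p$v else NA_real_,
      k = if (tr$model == "hill") p$k else NA_real_,
      n_hill = if (tr$model == "hill") p$n else NA_real_,
      sigma = config$sigma,
      direction = if (tr$model == "null") NA_character_ else tr$direction,
      true_bmd = tr$true_bmd)
  }
  counts <- tibble(gene_id = gene_ids)
  counts[design$sample_id] <- as.data.frame(count_rows)
  counts <- mutate(counts, dplyr::across(-gene_id, as.integer))
  list(counts = validate_counts(counts),
       design = validate_design(design),
       truth = list_rbind(truth_rows))
}

#' Simulate noisy log2 responses from a known dose-response curve
#'
#' Convenience generator for fitting studies: evaluates a model mean at the
#' requested doses (each repeated `replicates` times) and adds i.i.d. normal
#' noise with SD `sigma` on the log2 scale.
#'
#' @param kind Model kind understood by [dr_mean()].
#' @param params Named parameter list for the curve.
#' @param doses Dose levels.
#' @param replicates Replicates per dose.
#' @param sigma Residual SD (log2 units).
#' @return A tibble with columns `dose` and `y`.
#' @export
simulate_response <- function(kind, params, doses, replicates = 3, sigma = 0.2) {
  d <- rep(doses, each = replicates)
  tibble(dose = d, y = dr_mean(kind, params, d) + stats::rnorm(length(d), 0, sigma))
}
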