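#' Pipeline configuration
#'
#' Collects the file paths and every threshold of the workflow, with the
#' standard defaults: fold-change cuts 1.5 (lenient) / 2 (stringent), FDR cuts
#' 0.05 / 0.01, prefilter |FC| > 1.5 at adjusted p < 0.05, a 1-SD benchmark
#' response, BMDU/BMDL rejection ratio 40, lack-of-fit rejection at p <= 0.1,
#' and pathway enrichment at >= 5 genes with Fisher p < 0.05. All thresholds
#' are validated before any computation.
#'
#' @param counts,design,gmt Paths to the count table, dose design and GMT file.
#' @param obo Optional path to an OBO ontology for level annotation.
#' @param outdir Output directory (created if needed).
#' @param regime `"stringent"` or `"lenient"` DEG threshold regime.
#' @param prefilter_fc,prefilter_alpha,prefilter_padjust ANOVA prefilter
#'   settings.
#' @param bmr_sd Benchmark response in residual-SD units.
#' @param max_ratio BMDU/BMDL QC limit.
#' @param fit_p Lack-of-fit QC level.
#' @param min_genes,fisher_p Pathway enrichment cuts.
#' @param enrich_universe `"modeled"` (default) tests enrichment against the
#'   genes that entered BMD modeling; `"assayed"` against every gene in the
#'   count table.
#' @param pathway_fdr FDR cut used for the cross-chemical pathway network.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts, design, gmt, obo = NULL, outdir,
                            regime = c("stringent", "lenient"),
                            prefilter_fc = 1.5, prefilter_alpha = 0.05,
                            prefilter_padjust = "BH", bmr_sd = 1,
                            max_ratio = 40, fit_p = 0.1, min_genes = 5,
                            fisher_p = 0.05, enrich_universe = c("modeled", "assayed"),
                            pathway_fdr = 0.05) {
  regime <- match.arg(regime)
  enrich_universe <- match.arg(enrich_universe)
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 1) {
      abort(sprintf("%s must be a single number in (0, 1); got %s", name,
                    paste(x, collapse = ",")))
    }
  }
  chk_prob(prefilter_alpha, "prefilter_alpha")
  chk_prob(fit_p, "fit_p")
  chk_prob(fisher_p, "fisher_p")
  chk_prob(pathway_fdr, "pathway_fdr")
  if (prefilter_fc <= 1) abort("prefilter_fc must exceed 1")
  if (bmr_sd <= 0) abort("bmr_sd must be positive")
  if (max_ratio <= 1) abort("max_ratio must exceed 1")
  if (min_genes < 1) abort("min_genes must be >= 1")
  structure(
    list(counts = counts, design = design, gmt = gmt, obo = obo,
         outdir = outdir, regime = regime, prefilter_fc = prefilter_fc,
         prefilter_alpha = prefilter_alpha,
         prefilter_padjust = prefilter_padjust, bmr_sd = bmr_sd,
         max_ratio = max_ratio, fit_p = fit_p, min_genes = min_genes,
         fisher_p = fisher_p, enrich_universe = enrich_universe,
         pathway_fdr = pathway_fdr),
    class = "pipeline_config")
}

stage_log <- function(stage, chem, n_in, n_out) {
  inform(sprintf("[%s] %s: %d in -> %d out", stage, chem, n_in, n_out))
}

#' Run the full dose-response workflow
#'
#' Executes, for every chemical in the design: differential expression of each
#' dose against the vehicle, the ANOVA + fold-change prefilter, benchmark-dose
#' modeling with QC, and pathway enrichment with BMD aggregation; then the
#' cross-chemical comparison (exclusive-intersection counts of the
#' highest-dose DEG sets and of the significant pathway sets, and the shared
#' chemical-pathway network). Each stage writes a tab-separated table under
#' `config$outdir`, and a manifest records every threshold and the package
#' version. Identical inputs and configuration produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- read_counts(config$counts)
  design <- read_design(config$design)
  check_counts_design(counts, design)
  sets <- read_gmt(config$gmt)
  levels <- if (!is.null(config$obo)) ontology_levels(config$obo) else NULL
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  regime <- regime_preset(config$regime)
  params <- config[!(names(config) %in% c("counts", "design", "gmt", "obo", "outdir"))]
  paths <- list()
  out <- function(name) file.path(config$outdir, name)

  size_factors <- estimate_size_factors(counts)
  expr <- log2_matrix(counts, size_factors)
  chems <- sort(unique(design$chemical))
  deg_sets <- list()
  pathway_tables <- list()

  for (chem in chems) {
    doses <- sort(setdiff(unique(design$dose[design$chemical == chem]), 0))
    deg <- list_rbind(map(doses, function(d) nb_test(counts, design, chem, d)))
    stage_log("deg", chem, length(unique(deg$gene_id)) * length(doses), nrow(deg_filter(deg, regime)))
    paths[[paste0("deg_", chem)]] <- write_table(deg, out(sprintf("deg_%s.tsv", chem)),
                                                 params["regime"])
    top_dose_deg <- deg_filter(filter(deg, dose == max(doses)), regime)
    deg_sets[[chem]] <- top_dose_deg$gene_id

    pre <- anova_prefilter(expr, design, chem, fc_min = config$prefilter_fc,
                           alpha = config$prefilter_alpha,
                           padjust = config$prefilter_padjust)
    stage_log("prefilter", chem, nrow(pre), sum(pre$retained))
    paths[[paste0("prefilter_", chem)]] <-
      write_table(pre, out(sprintf("prefilter_%s.tsv", chem)),
                  params[c("prefilter_fc", "prefilter_alpha", "prefilter_padjust")])

    retained <- pre$gene_id[pre$retained]
    bmd_tab <- if (length(retained) > 0) {
      fit_bmd(expr, design, chem, genes = retained, bmr_factor = config$bmr_sd,
              max_ratio = config$max_ratio, fit_p_min = config$fit_p)
    } else {
      tibble(gene_id = character(0), chemical = character(0),
             model = character(0), params = character(0), sigma = double(0),
             loglik = double(0), aic = double(0), fit_p = double(0),
             bmd = double(0), bmdl = double(0), bmdu = double(0),
             flag = character(0))
    }
    stage_log("bmd", chem, length(retained), sum(bmd_tab$flag == "pass"))
    paths[[paste0("bmd_", chem)]] <-
      write_table(bmd_tab, out(sprintf("bmd_%s.tsv", chem)),
                  params[c("bmr_sd", "max_ratio", "fit_p")])

    pw <- if (sum(bmd_tab$flag == "pass") > 0) {
      universe <- if (config$enrich_universe == "assayed") counts$gene_id else NULL
      pathway_bmd(bmd_tab, sets, universe = universe, levels = levels,
                  min_genes = config$min_genes, p_max = config$fisher_p)
    } else {
      tibble(set_id = character(0), set_name = character(0),
             n_universe = integer(0), genes_observed = integer(0),
             fisher_p = double(0), fdr = double(0))
    }
    stage_log("pathways", chem, nrow(sets), nrow(pw))
    paths[[paste0("pathways_", chem)]] <-
      write_table(pw, out(sprintf("pathways_%s.tsv", chem)),
                  params[c("min_genes", "fisher_p")])
    pathway_tables[[chem]] <- mutate(pw, chemical = chem)
  }

  if (length(chems) >= 2) {
    nonempty <- deg_sets[lengths(deg_sets) > 0]
    if (length(nonempty) >= 2) {
      paths$upset <- write_table(upset_counts(nonempty), out("upset.tsv"))
    } else {
      paths$upset <- write_table(
        tibble(pattern = character(0), degree = integer(0),
               exclusive_count = integer(0)), out("upset.tsv"))
    }
    pw_all <- list_rbind(pathway_tables)
    pw_sig <- filter_pathways(pw_all, fdr_max = config$pathway_fdr,
                              min_genes = config$min_genes)
    net <- shared_pathway_network(pw_sig)
    paths$network_edges <- write_table(net$edges, out("network_edges.tsv"),
                                       params["pathway_fdr"])
    paths$network_pathways <- write_table(net$pathways, out("network_pathways.tsv"))
  }

  manifest <- c(
    sprintf("tidybmd_version\t%s", as.character(packageVersion("tidybmd"))),
    sprintf("%s\t%s", names(params), vapply(params, as.character, character(1))))
  writeLines(manifest, out("manifest.tsv"))
  paths$manifest <- out("manifest.tsv")
  invisible(paths)
}
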