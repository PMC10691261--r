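# materialize a simulated multi-chemical study (plus a designed gene-set
# collection) as files for pipeline-level tests

write_gmt_lines <- function(sets, file = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, paste("desc of", id), sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  file
}

materialize_study <- function(sim, dir = tempfile("study")) {
  dir.create(dir, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  design_path <- file.path(dir, "design.tsv")
  write_counts(sim$counts, counts_path)
  writeLines(
    c("sample\tchemical\tdose",
      sprintf("%s\t%s\t%.10g", sim$design$sample_id, sim$design$chemical,
              sim$design$dose)),
    design_path)
  list(dir = dir, counts = counts_path, design = design_path)
}

# gene sets with one designed dose-responsive pathway against null decoys
designed_gmt <- function(truth, file = tempfile(fileext = ".gmt")) {
  responsive <- truth$gene_id[truth$model != "null"]
  nulls <- truth$gene_id[truth$model == "null"]
  sets <- list(RESPONSIVE = responsive)
  n_decoys <- max(1, floor(length(nulls) / 25))
  for (i in seq_len(n_decoys)) {
    sets[[sprintf("DECOY%02d", i)]] <- nulls[((i - 1) * 25 + 1):min(i * 25, length(nulls))]
  }
  sets$MIXED <- c(head(responsive, 3), head(nulls, 22))
  write_gmt_lines(sets, file)
}
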