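#' Read a gene x sample count table
#'
#' Reads a tab-separated count table whose first column holds gene identifiers
#' and whose header row holds sample identifiers, and validates it: identifiers
#' must be unique, every count must be a non-negative integer, and at least two
#' samples must be present. Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with a `gene_id` character column followed by one integer
#'   column per sample.
#' @export
read_counts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) abort("count table must have a header row and at least one gene row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  gene_ids <- vapply(rows, `[[`, character(1), 1L)
  cells <- lapply(rows, function(r) r[-1])
  width <- lengths(cells)
  if (any(width != length(sample_ids))) {
    bad <- which(width != length(sample_ids))[1]
    abort(sprintf("row %d ('%s') has %d count fields; expected %d",
                  bad, gene_ids[bad], width[bad], length(sample_ids)))
  }
  mat <- do.call(rbind, cells)
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(sprintf("count for gene '%s', sample '%s' is '%s'; counts must be non-negative integers",
                  gene_ids[i], sample_ids[j], mat[i, j]))
  }
  counts <- as_tibble(setNames(as.data.frame(num), sample_ids))
  counts <- mutate(counts, dplyr::across(dplyr::everything(), as.integer))
  out <- bind_cols_counts(gene_ids, counts)
  validate_counts(out)
}

bind_cols_counts <- function(gene_ids, counts) {
  out <- tibble(gene_id = gene_ids)
  out[names(counts)] <- counts
  out
}

#' Validate a count table
#'
#' @param counts A data frame with `gene_id` plus one column per sample.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (!"gene_id" %in% names(counts)) abort("count table must have a 'gene_id' column")
  sample_ids <- setdiff(names(counts), "gene_id")
  if (length(sample_ids) < 2) abort("count table must have at least 2 samples")
  dup_g <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup_g) > 0) abort(sprintf("duplicate gene identifier: '%s'", dup_g[1]))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s) > 0) abort(sprintf("duplicate sample identifier: '%s'", dup_s[1]))
  m <- as.matrix(counts[sample_ids])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m))) {
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1, ]
    abort(sprintf("count for gene '%s', sample '%s' must be a non-negative integer",
                  counts$gene_id[bad[1]], sample_ids[bad[2]]))
  }
  counts
}

#' Read a dose design table
#'
#' Reads the sample-to-treatment map: tab-separated with columns `sample`
#' (or `sample_id`), `chemical` and `dose` (micromolar; 0 denotes the vehicle
#' control). A `replicate` index is added per (chemical, dose) if absent.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `sample_id`, `chemical`, `dose`, `replicate`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("sample" %in% names(df)) names(df)[names(df) == "sample"] <- "sample_id"
  validate_design(df)
}

#' Validate a dose design table
#'
#' @param design A data frame with columns `sample_id`, `chemical`, `dose`.
#' @return A validated tibble with a `replicate` column.
#' @export
validate_design <- function(design) {
  design <- as_tibble(design)
  need <- c("sample_id", "chemical", "dose")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols) > 0) {
    abort(sprintf("design is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup) > 0) abort(sprintf("duplicate sample row: '%s'", dup[1]))
  design$dose <- as.numeric(design$dose)
  if (anyNA(design$dose) || any(design$dose < 0)) abort("doses must be non-negative reals (micromolar)")
  by_chem <- split(design$dose, design$chemical)
  for (chem in names(by_chem)) {
    d <- by_chem[[chem]]
    if (!any(d == 0)) abort(sprintf("chemical '%s' has no vehicle control (dose 0) samples", chem))
    if (length(unique(d)) < 2) abort(sprintf("chemical '%s' has fewer than 2 distinct dose levels", chem))
  }
  if (!"replicate" %in% names(design)) {
    design <- design %>%
      group_by(chemical, dose) %>%
      mutate(replicate = row_number()) %>%
      ungroup()
  }
  select(design, sample_id, chemical, dose, replicate, dplyr::everything())
}

check_counts_design <- function(counts, design) {
  sample_ids <- setdiff(names(counts), "gene_id")
  missing <- setdiff(sample_ids, design$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample '%s' in counts is absent from the design", missing[1]))
  }
  invisible(TRUE)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated, `set_id`, description, then
#' member gene identifiers. Set identifiers must be unique and member lists
#' non-empty.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `set_name`, `genes` (list column of
#'   character vectors) and `n_genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has %d fields; expected set id, description and at least one member",
                  short[1], lengths(fields)[short[1]]))
  }
  set_id <- vapply(fields, `[[`, character(1), 1L)
  dup <- set_id[duplicated(set_id)]
  if (length(dup) > 0) abort(sprintf("duplicate set id in GMT: '%s'", dup[1]))
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- which(lengths(genes) == 0)
  if (length(empty) > 0) abort(sprintf("GMT line %d ('%s') has an empty member list", empty[1], set_id[empty[1]]))
  tibble(
    set_id = set_id,
    set_name = vapply(fields, `[[`, character(1), 2L),
    genes = genes,
    n_genes = lengths(genes)
  )
}

#' Ontology term levels from an OBO file
#'
#' Parses `[Term]` stanzas and their `is_a` edges and assigns each term a
#' level: the shortest `is_a` path length from its namespace root (a term with
#' no `is_a` parent). Obsolete terms are skipped. A cyclic `is_a` graph is an
#' error.
#'
#' @param path Path to an OBO file.
#' @return A tibble with columns `set_id` and `level`.
#' @export
ontology_levels <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) abort("no [Term] stanzas found in OBO file")
  block_end <- c(term_starts[-1] - 1L, length(lines))
  ids <- character(0)
  parents <- list()
  for (b in seq_along(term_starts)) {
    chunk <- lines[term_starts[b]:block_end[b]]
    stanza_brk <- grep("^\\[", chunk[-1])
    if (length(stanza_brk) > 0) chunk <- chunk[seq_len(stanza_brk[1])]
    get_vals <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), chunk, value = TRUE))
      sub(" *!.*$", "", v)
    }
    if (length(get_vals("is_obsolete")) > 0 && any(get_vals("is_obsolete") == "true")) next
    id <- get_vals("id")
    if (length(id) == 0) next
    ids <- c(ids, id[1])
    parents[[id[1]]] <- get_vals("is_a")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) abort(sprintf("duplicate term id in OBO: '%s'", dup[1]))
  # keep only in-file parents; terms with none are namespace roots (level 0)
  parents <- lapply(parents, intersect, ids)
  level <- setNames(rep(NA_integer_, length(ids)), ids)
  frontier <- ids[lengths(parents) == 0]
  if (length(frontier) == 0) abort("cyclic is_a graph: no root term found")
  level[frontier] <- 0L
  depth <- 0L
  while (length(frontier) > 0) {
    depth <- depth + 1L
    nxt <- ids[is.na(level) & vapply(parents[ids], function(p) any(p %in% frontier), logical(1))]
    level[nxt] <- depth
    frontier <- nxt
  }
  if (anyNA(level)) abort("cyclic is_a graph: some terms are unreachable from any root")
  tibble(set_id = ids, level = unname(level[ids]))
}

fmt_cell <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.12g", x)
    out[is.na(x)] <- "NA"
    out
  } else {
    out <- as.character(x)
    out[is.na(x)] <- "NA"
    out
  }
}

#' Write a result table as tab-separated text
#'
#' Writes a data frame with a leading `#` provenance comment (package version
#' plus caller-supplied parameters), deterministic column order and fixed
#' numeric formatting (12 significant digits), so that tables round-trip
#' through [read_result_table()] unchanged at that precision.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param params Optional named list recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, params = NULL) {
  x <- as_tibble(x)
  meta <- sprintf("# tidybmd %s", as.character(packageVersion("tidybmd")))
  if (length(params) > 0) {
    meta <- paste0(meta, " | ", paste(names(params), unlist(params), sep = "=", collapse = " "))
  }
  body <- if (nrow(x) == 0) character(0) else {
    cols <- lapply(x, fmt_cell)
    do.call(paste, c(cols, sep = "\t"))
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(c(meta, paste(names(x), collapse = "\t"), body), con, useBytes = TRUE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to a tab-separated file with `#` comment lines.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, comment = "#", na = "NA", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a count table
#'
#' Inverse of [read_counts()]: genes in rows, samples in columns, tab-separated.
#'
#' @param counts A validated count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  cols <- lapply(counts, fmt_cell)
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(paste(names(counts), collapse = "\t"), body), path, useBytes = TRUE)
  invisible(path)
}
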