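# small in-code fixtures shared across test files

toy_counts <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    s1 = c(10L, 30L, 0L),
    s2 = c(20L, 60L, 5L),
    s3 = c(15L, 45L, 2L))
}

toy_design <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    chemical = "chemA",
    dose = c(0, 0, 1),
    replicate = c(1L, 2L, 1L))
}

write_tsv_lines <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# a balanced two-group count design for DE tests
two_group_design <- function(n_per_group = 4, dose = 100) {
  tibble::tibble(
    sample_id = c(sprintf("c%d", seq_len(n_per_group)),
                  sprintf("t%d", seq_len(n_per_group))),
    chemical = "chemA",
    dose = rep(c(0, dose), each = n_per_group),
    replicate = rep(seq_len(n_per_group), 2))
}

nb_null_counts <- function(n_genes, design, mu = 500, phi = 0.02) {
  m <- matrix(rnbinom(n_genes * nrow(design), mu = mu, size = 1 / phi),
              nrow = n_genes)
  out <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes)))
  out[design$sample_id] <- as.data.frame(m)
  dplyr::mutate(out, dplyr::across(-gene_id, as.integer))
}

# standard 9-level dose grid used throughout (vehicle + 8 concentrations)
dose_grid <- function() c(0, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100)

# brute-force BH step-up oracle: sort, scale by n/i, cummin from the tail
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# one-sided Fisher enrichment oracle by direct hypergeometric tail enumeration
fisher_oracle <- function(x, K, N, n) {
  xs <- x:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
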