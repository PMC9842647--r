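# Shared fixture builders; everything is generated in code.

# cells x genes matrix with dimnames
named_matrix <- function(x, n_cells, n_genes, cell_prefix = "c",
                         gene_prefix = "g") {
  matrix(x, n_cells, n_genes,
         dimnames = list(paste0(cell_prefix, seq_len(n_cells)),
                         paste0(gene_prefix, seq_len(n_genes))))
}

# small scRNA config used where full defaults would be slow
small_sc_config <- function(seed = 1L, ...) {
  sc_sim_config(
    n_samples = 2L,
    cell_counts = c(malignant = 150L, immune = 100L, stromal = 50L),
    n_genes = 600L, n_chroms = 5L,
    cnv_segments = tibble::tibble(
      chrom = c("chr1", "chr2"),
      start_gene_idx = c(1L, 121L), end_gene_idx = c(120L, 240L),
      log2_dosage = c(1, -1)),
    programs = list(
      list(name = "progA", gene_set_size = 25L, n_active_cells = 60L, effect = 2),
      list(name = "progB", gene_set_size = 25L, n_active_cells = 60L, effect = 2)),
    seed = seed, ...
  )
}

# uniform-bin contact-map builder for hand fixtures
toy_contact_map <- function(m, bin_size = 1e5, chrom = "chr1") {
  n <- nrow(m)
  bins <- tibble::tibble(bin_id = seq_len(n) - 1L, chrom = chrom,
                         start = (seq_len(n) - 1L) * bin_size,
                         end = seq_len(n) * bin_size)
  contact_map(bins, m, resolution = bin_size)
}

# brute-force two-sided Fisher p over all tables with the observed margins
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, 0)
  p_obs <- probs[a_range == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC as the concordant-pair fraction, counted exhaustively
auc_enum <- function(scores, outcome) {
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + (p > q) + 0.5 * (p == q)
  }
  conc / (length(pos) * length(neg))
}
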