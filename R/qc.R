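#' Cell quality-control thresholds
#'
#' Cells outside `[min_genes, max_genes]` detected genes (count > 0) or
#' above `max_mito_frac` mitochondrial count fraction are flagged
#' low-quality and removed.
#'
#' @param min_genes,max_genes Detected-gene bounds (inclusive).
#' @param max_mito_frac Maximum mitochondrial count fraction (inclusive).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 5000L,
                          max_mito_frac = 0.30) {
  min_genes <- check_count(min_genes, "min_genes", min = 0L)
  max_genes <- check_count(max_genes, "max_genes")
  if (min_genes >= max_genes) abort("min_genes must be < max_genes.")
  max_mito_frac <- check_number(max_mito_frac, "max_mito_frac",
                                min = 0, max = 1, strict_min = TRUE)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_frac = max_mito_frac), class = "qc_thresholds")
}

#' Filter low-quality cells from a raw count matrix
#'
#' Mitochondrial fraction is computed on raw counts. A cell is kept when
#' `min_genes <= detected genes <= max_genes` and the mitochondrial
#' fraction is at most `max_mito_frac`. The reported reason for a removed
#' cell is the first violated criterion in the order `min_genes`,
#' `max_genes`, `mito_frac`.
#'
#' @param counts Cells x genes raw count matrix.
#' @param thresholds A [qc_thresholds()].
#' @param mito_genes Character vector of mitochondrial gene ids (may be
#'   empty; ids absent from the matrix are ignored).
#' @return List with `counts` (kept cells) and `report`, a tibble with one
#'   row per input cell (`cell_id`, `n_genes`, `mito_frac`, `kept`,
#'   `reason`).
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(),
                      mito_genes = character()) {
  counts <- check_cells_genes(counts, "counts")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  n_genes <- rowSums(counts > 0)
  mito <- intersect(mito_genes, colnames(counts))
  totals <- rowSums(counts)
  mito_frac <- if (length(mito) > 0) {
    rowSums(counts[, mito, drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, nrow(counts))
  }
  reason <- dplyr::case_when(
    n_genes < thresholds$min_genes ~ "min_genes",
    n_genes > thresholds$max_genes ~ "max_genes",
    mito_frac > thresholds$max_mito_frac ~ "mito_frac",
    TRUE ~ NA_character_
  )
  kept <- is.na(reason)
  if (!any(kept)) {
    abort(sprintf(
      "All %d cells removed by QC (min_genes: %d, max_genes: %d, mito_frac: %d).",
      nrow(counts), sum(reason == "min_genes", na.rm = TRUE),
      sum(reason == "max_genes", na.rm = TRUE),
      sum(reason == "mito_frac", na.rm = TRUE)))
  }
  list(
    counts = counts[kept, , drop = FALSE],
    report = tibble(cell_id = rownames(counts), n_genes = as.integer(n_genes),
                    mito_frac = as.numeric(mito_frac), kept = kept,
                    reason = reason)
  )
}

#' Depth-normalize and log-transform a count matrix
#'
#' Scales each cell to a common total, then applies `log2(x + 1)`. Zeros
#' stay zero.
#'
#' @param counts Cells x genes non-negative matrix.
#' @param scale Common per-cell total (default 10,000).
#' @return Cells x genes matrix of log-normalized expression.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  counts <- check_cells_genes(counts, "counts")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    abort(sprintf("%d cell(s) have zero total counts; run qc_filter first.",
                  sum(totals == 0)))
  }
  log2(counts / totals * scale + 1)
}

#' Rank-sum marker statistics, each group versus the rest
#'
#' For every gene and every group, computes a two-sided Wilcoxon rank-sum
#' test (normal approximation with tie correction, no continuity
#' correction) of the group's cells against all other cells, with
#' Benjamini-Hochberg adjustment within each group's gene list. The fold
#' change is `log2((mean_in + eps) / (mean_out + eps))` on the supplied
#' expression values.
#'
#' @param mat Cells x genes expression matrix (normally log-normalized).
#' @param labels Group label per cell (length `nrow(mat)`); at least two
#'   groups with two cells each.
#' @param eps Pseudo-value guarding the fold-change ratio.
#' @return Tibble with `gene_id`, `group`, `rank_sum_statistic`,
#'   `p_value`, `adjusted_p`, `log_fc`, sorted by group then adjusted p.
#' @export
rank_sum_markers <- function(mat, labels, eps = 1e-9) {
  mat <- check_cells_genes(mat, "mat")
  labels <- as.character(labels)
  if (length(labels) != nrow(mat)) {
    abort("`labels` must have one entry per cell.")
  }
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("Need >= 2 groups with >= 2 cells each.")
  }
  n <- nrow(mat)
  # rank every gene once over all cells; the group-vs-rest rank sum is the
  # sum of the group's ranks in that common ranking
  ranks <- apply(mat, 2, rank)
  tie_term <- apply(mat, 2, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  out <- purrr::map_dfr(names(tab), function(g) {
    in_g <- labels == g
    n1 <- sum(in_g)
    n2 <- n - n1
    r1 <- colSums(ranks[in_g, , drop = FALSE])
    mu <- n1 * (n + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    sigma <- sqrt(pmax(sigma2, 0))
    z <- ifelse(sigma > 0, (r1 - mu) / sigma, 0)
    p <- ifelse(sigma > 0, 2 * pnorm(-abs(z)), 1)
    m_in <- colMeans(mat[in_g, , drop = FALSE])
    m_out <- colMeans(mat[!in_g, , drop = FALSE])
    ratio <- (m_in + eps) / (m_out + eps)
    lfc <- rep(NA_real_, length(ratio))
    lfc[ratio > 0] <- log2(ratio[ratio > 0])
    lfc[sigma == 0] <- 0
    p <- unname(pmin(p, 1))
    tibble(gene_id = colnames(mat), group = g,
           rank_sum_statistic = unname(as.numeric(r1)), p_value = p,
           adjusted_p = p.adjust(p, method = "BH"),
           log_fc = unname(lfc))
  })
  dplyr::arrange(out, .data$group, .data$adjusted_p, .data$p_value)
}

#' Filter a differential-expression table by significance and effect size
#'
#' The conventional bulk DEG predicate: adjusted p below `padj_max` and
#' |log2 fold change| above `lfc_min` (optionally one-directional).
#'
#' @param df Data frame with columns `gene_id`, `adjusted_p`, `log_fc`.
#' @param padj_max Adjusted-p ceiling (strict).
#' @param lfc_min Fold-change floor on log2 scale (strict).
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of gene ids passing the filter.
#' @export
filter_degs <- function(df, padj_max = 0.01, lfc_min = 1,
                        direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (!all(c("gene_id", "adjusted_p", "log_fc") %in% names(df))) {
    abort("`df` needs columns gene_id, adjusted_p, log_fc.")
  }
  eff <- switch(direction,
                both = abs(df$log_fc) > lfc_min,
                up = df$log_fc > lfc_min,
                down = df$log_fc < -lfc_min)
  unique(df$gene_id[df$adjusted_p < padj_max & eff])
}
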