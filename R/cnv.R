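#' Infer smoothed copy-number profiles from expression
#'
#' Expression-derived relative copy-number profiles over genomically
#' ordered genes, following the moving-average approach: (1) log-
#' normalized expression is centered per gene on the reference-cell mean;
#' (2) centered values are clipped to `[-clip, clip]`; (3) within each
#' chromosome a symmetric moving average over `window` genes (ordered by
#' start coordinate, truncated at chromosome ends) is applied; (4) each
#' cell's profile is re-centered on its median; (5) the mean reference
#' profile is subtracted. Reference cells receive profiles too.
#'
#' @param mat Cells x genes log-normalized expression matrix.
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`);
#'   must cover at least 80% of the matrix genes — the remainder are
#'   dropped from profiles with a warning.
#' @param reference_cells Character vector of reference (presumed
#'   non-malignant) cell ids; non-empty.
#' @param window Moving-average width in genes.
#' @param clip Symmetric clipping bound on centered expression.
#' @return A `cnv_profiles` object: list with `values` (cells x ordered
#'   genes matrix of smoothed relative log2 dosage), `genes` (ordered
#'   annotation) and `reference_cells`.
#' @export
infer_cnv_profiles <- function(mat, annotation, reference_cells,
                               window = 101L, clip = 3.0) {
  mat <- check_cells_genes(mat, "mat")
  window <- check_count(window, "window")
  clip <- check_number(clip, "clip", min = 0, strict_min = TRUE)
  if (length(reference_cells) == 0) abort("`reference_cells` is empty.")
  missing_ref <- setdiff(reference_cells, rownames(mat))
  if (length(missing_ref) > 0) {
    abort(sprintf("%d reference cell(s) not in the matrix.",
                  length(missing_ref)))
  }
  annotation <- as_tibble(annotation)
  ann <- annotation[annotation$gene_id %in% colnames(mat), ]
  frac <- nrow(ann) / ncol(mat)
  if (frac < 0.8) {
    abort(sprintf("Annotation covers only %.0f%% of genes (>= 80%% required).",
                  100 * frac))
  }
  if (frac < 1) {
    warn(sprintf("%d gene(s) without annotation dropped from CNV profiles.",
                 ncol(mat) - nrow(ann)))
  }
  chrom_order <- sorted_chroms(ann$chrom)
  ann <- ann[order(match(ann$chrom, chrom_order), ann$start, ann$gene_id), ]

  x <- mat[, ann$gene_id, drop = FALSE]
  ref_idx <- rownames(x) %in% reference_cells
  centered <- sweep(x, 2, colMeans(x[ref_idx, , drop = FALSE]))
  centered <- pmin(pmax(centered, -clip), clip)

  smoothed <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (ch in chrom_order) {
    cols <- which(ann$chrom == ch)
    ng <- length(cols)
    if (ng < ceiling(window / 4)) {
      warn(sprintf("Chromosome %s has only %d gene(s); window truncated.",
                   ch, ng))
    }
    op <- moving_average_operator(ng, min(window, 2L * ng - 1L))
    smoothed[, cols] <- as.matrix(centered[, cols, drop = FALSE] %*% op)
  }
  smoothed <- sweep(smoothed, 1, apply(smoothed, 1, median))
  ref_profile <- colMeans(smoothed[ref_idx, , drop = FALSE])
  values <- sweep(smoothed, 2, ref_profile)

  structure(list(values = values, genes = ann,
                 reference_cells = reference_cells,
                 window = window, clip = clip),
            class = "cnv_profiles")
}

#' @export
print.cnv_profiles <- function(x, ...) {
  cat(sprintf("<cnv_profiles> %d cells x %d ordered genes (%d chromosomes)\n",
              nrow(x$values), ncol(x$values), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Per-cell CNV signal
#'
#' The default statistic is the mean of squared profile values; the
#' `"range"` variant (max - min) is available behind the `stat` flag.
#'
#' @param profiles A [infer_cnv_profiles()] result, or a cells x genes
#'   profile matrix.
#' @param stat `"mean_square"` (default) or `"range"`.
#' @return Named numeric vector, one signal per cell.
#' @export
cnv_signal <- function(profiles, stat = c("mean_square", "range")) {
  stat <- match.arg(stat)
  v <- if (inherits(profiles, "cnv_profiles")) profiles$values else
    check_matrix(profiles, "profiles")
  if (ncol(v) == 0) abort("Empty CNV profile.")
  if (stat == "mean_square") rowMeans(v^2)
  else apply(v, 1, function(r) max(r) - min(r))
}

#' Correlation of each cell's CNV profile with a tumour consensus
#'
#' @param profiles A `cnv_profiles` object or profile matrix.
#' @param consensus Consensus profile vector over the same ordered genes
#'   (see [tumor_consensus_profile()]).
#' @return Named numeric vector of Pearson correlations; 0 where either
#'   vector is constant.
#' @export
cnv_correlation <- function(profiles, consensus) {
  v <- if (inherits(profiles, "cnv_profiles")) profiles$values else
    check_matrix(profiles, "profiles")
  if (length(consensus) != ncol(v)) {
    abort("Consensus profile length must match the gene set.")
  }
  apply(v, 1, safe_pearson, y = as.numeric(consensus))
}

#' Tumour consensus CNV profile
#'
#' Mean profile of the top `top_frac` cells by CNV signal; when `samples`
#' is supplied the top fraction is taken within each sample and the
#' per-sample consensus is returned for each cell's own sample.
#'
#' @param profiles A `cnv_profiles` object or profile matrix.
#' @param top_frac Fraction of cells defining the consensus.
#' @param stat Signal statistic passed to [cnv_signal()].
#' @return Numeric consensus vector (genes).
#' @export
tumor_consensus_profile <- function(profiles, top_frac = 0.05,
                                    stat = "mean_square") {
  v <- if (inherits(profiles, "cnv_profiles")) profiles$values else
    check_matrix(profiles, "profiles")
  top_frac <- check_number(top_frac, "top_frac", min = 0, max = 1,
                           strict_min = TRUE)
  sig <- cnv_signal(v, stat = stat)
  k <- max(1L, ceiling(top_frac * nrow(v)))
  top <- order(sig, decreasing = TRUE)[seq_len(k)]
  colMeans(v[top, , drop = FALSE])
}

#' Classify cells as malignant from CNV signal and correlation
#'
#' A cell is malignant iff both strict inequalities hold:
#' `signal > signal_threshold` and `correlation > corr_threshold`.
#'
#' @param signal,correlation Numeric vectors (recycled to equal length).
#' @param signal_threshold,corr_threshold Classification thresholds.
#' @return Character vector, `"malignant"` or `"non-malignant"`.
#' @export
classify_malignant <- function(signal, correlation,
                               signal_threshold = 0.05,
                               corr_threshold = 0.5) {
  if (any(!is.finite(signal)) || any(!is.finite(correlation))) {
    abort("`signal` and `correlation` must be finite.")
  }
  ifelse(signal > signal_threshold & correlation > corr_threshold,
         "malignant", "non-malignant")
}

#' End-to-end malignancy calls for a CNV profile set
#'
#' Computes per-cell signal, correlation against the tumour consensus and
#' the threshold classification in one step.
#'
#' @inheritParams cnv_correlation
#' @inheritParams classify_malignant
#' @inheritParams tumor_consensus_profile
#' @return Tibble with `cell_id`, `cnv_signal`, `cnv_correlation`,
#'   `label`.
#' @export
call_malignancy <- function(profiles, signal_threshold = 0.05,
                            corr_threshold = 0.5, top_frac = 0.05,
                            stat = "mean_square") {
  v <- if (inherits(profiles, "cnv_profiles")) profiles$values else
    check_matrix(profiles, "profiles")
  sig <- cnv_signal(v, stat = stat)
  consensus <- tumor_consensus_profile(v, top_frac = top_frac, stat = stat)
  r <- cnv_correlation(v, consensus)
  tibble(cell_id = rownames(v), cnv_signal = as.numeric(sig),
         cnv_correlation = as.numeric(r),
         label = classify_malignant(sig, r, signal_threshold, corr_threshold))
}

#' Mean-expression score over a marker gene set
#'
#' Per-cell mean of log-normalized expression over the markers present in
#' the matrix. Serves the epithelial score (EPCAM, cytokeratins, SFN) and
#' any other gene-set score (e.g. exhausted-CD8 or meta-signature
#' scoring).
#'
#' @param mat Cells x genes log-normalized expression matrix.
#' @param marker_set Character vector of gene ids; members absent from the
#'   matrix are dropped with a warning, and an empty intersection is an
#'   error.
#' @return Tibble with `cell_id` and `score`.
#' @export
epithelial_score <- function(mat, marker_set) {
  mat <- check_cells_genes(mat, "mat")
  present <- intersect(marker_set, colnames(mat))
  if (length(present) == 0) {
    abort("None of the marker genes are present in the matrix.")
  }
  if (length(present) < length(unique(marker_set))) {
    warn(sprintf("%d marker gene(s) absent from the matrix; dropped.",
                 length(unique(marker_set)) - length(present)))
  }
  tibble(cell_id = rownames(mat),
         score = unname(rowMeans(mat[, present, drop = FALSE])))
}
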