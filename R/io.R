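#' Binned contact map container
#'
#' A light container for a binned, symmetric Hi-C contact matrix: the bin
#' table, the matrix itself, an optional ICE bias vector (`NA` on masked
#' bins) and the resolution in bp. All genomic coordinates in the bin
#' table are 0-based half-open.
#'
#' @param bins Tibble with columns `bin_id` (0-based), `chrom`, `start`,
#'   `end`.
#' @param matrix Symmetric non-negative numeric matrix, one row/column per
#'   bin.
#' @param bias Optional per-bin balancing weights.
#' @param resolution Bin width in bp.
#' @param balanced Whether `matrix` has already been ICE-balanced.
#' @return A `contact_map` object.
#' @export
contact_map <- function(bins, matrix, bias = NULL, resolution = NULL,
                        balanced = FALSE) {
  bins <- as_tibble(bins)
  if (!all(c("bin_id", "chrom", "start", "end") %in% names(bins))) {
    abort("`bins` needs columns bin_id, chrom, start, end.")
  }
  m <- check_matrix(matrix, "matrix")
  if (nrow(m) != nrow(bins) || ncol(m) != nrow(bins)) {
    abort("Contact matrix dimensions must match the bin table.")
  }
  if (any(m[!is.na(m)] < 0)) abort("Contact matrix must be non-negative.")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) {
    abort("Contact matrix must be symmetric.")
  }
  if (is.null(resolution)) resolution <- max(bins$end - bins$start)
  structure(
    list(bins = bins, matrix = m, bias = bias,
         resolution = as.numeric(resolution), balanced = isTRUE(balanced)),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d bins @ %s bp, %d chromosome(s)%s\n",
              nrow(x$bins), format(x$resolution, big.mark = ","),
              length(unique(x$bins$chrom)),
              if (x$balanced) ", ICE-balanced" else ""))
  invisible(x)
}

#' Read a 10x-style count triplet into a cells x genes matrix
#'
#' Reads a MatrixMarket coordinate file (genes in rows, cells in columns,
#' the 10x convention) plus barcode and feature TSVs, and returns the
#' transposed dense cells x genes matrix used throughout the package.
#'
#' @param mtx_path Path to the MatrixMarket file.
#' @param barcodes_path One barcode per line.
#' @param features_path One feature id per line (first column used).
#' @return Numeric cells x genes matrix with barcode rownames and feature
#'   colnames.
#' @export
read_counts <- function(mtx_path, barcodes_path, features_path) {
  for (p in c(mtx_path, barcodes_path, features_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  m <- Matrix::readMM(mtx_path)
  barcodes <- readr::read_tsv(barcodes_path, col_names = FALSE,
                              show_col_types = FALSE)[[1]]
  features <- readr::read_tsv(features_path, col_names = FALSE,
                              show_col_types = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    abort(sprintf(
      "Dimension mismatch: %s is %d x %d but %s has %d features and %s has %d barcodes.",
      mtx_path, nrow(m), ncol(m), features_path, length(features),
      barcodes_path, length(barcodes)))
  }
  m <- as.matrix(m)
  if (any(m != round(m))) {
    warn("Non-integer values in count matrix; keeping as-is.")
  }
  out <- t(m)
  dimnames(out) <- list(barcodes, features)
  out
}

#' Write a cells x genes matrix as a 10x-style triplet
#'
#' @param counts Cells x genes matrix with dimnames.
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `barcodes.tsv`, `features.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(counts, dir) {
  counts <- check_cells_genes(counts, "counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE), paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}

#' Read a binned contact map from a bin table and (i, j, count) triplets
#'
#' The triplet file is interpreted as the upper triangle (plus diagonal);
#' the matrix is mirrored to full symmetry and unreported entries are
#' zero. Duplicate `(i, j)` entries are summed with a warning.
#'
#' @param bins_path TSV with header `bin_id, chrom, start, end`.
#' @param triplet_path TSV with header `i, j, count` (0-based bin ids).
#' @return A [contact_map()].
#' @export
read_contacts <- function(bins_path, triplet_path) {
  bins <- readr::read_tsv(bins_path, show_col_types = FALSE)
  trip <- readr::read_tsv(triplet_path, show_col_types = FALSE)
  if (!all(c("i", "j", "count") %in% names(trip))) {
    abort("Triplet file needs columns i, j, count.")
  }
  n <- nrow(bins)
  if (nrow(trip) > 0 && (min(trip$i, trip$j) < 0 || max(trip$i, trip$j) >= n)) {
    abort("Triplet bin ids fall outside the bin table.")
  }
  key <- paste(pmin(trip$i, trip$j), pmax(trip$i, trip$j))
  if (anyDuplicated(key)) {
    warn("Duplicate (i, j) entries in triplet file; summing.")
  }
  m <- matrix(0, n, n)
  for (r in seq_len(nrow(trip))) {
    i <- trip$i[r] + 1L
    j <- trip$j[r] + 1L
    m[i, j] <- m[i, j] + trip$count[r]
    if (i != j) m[j, i] <- m[j, i] + trip$count[r]
  }
  contact_map(bins, m)
}

#' Write a contact map as bin-table and triplet TSVs
#'
#' Only the upper triangle (including the diagonal) of non-zero,
#' non-missing entries is written.
#'
#' @param map A [contact_map()].
#' @param bins_path,triplet_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_contacts <- function(map, bins_path, triplet_path) {
  stopifnot(inherits(map, "contact_map"))
  readr::write_tsv(map$bins, bins_path)
  m <- map$matrix
  idx <- which(upper.tri(m, diag = TRUE) & !is.na(m) & m != 0, arr.ind = TRUE)
  trip <- tibble(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                 count = m[idx])
  readr::write_tsv(trip[order(trip$i, trip$j), ], triplet_path)
  invisible(c(bins_path, triplet_path))
}

#' Read a BED-like interval file
#'
#' Expects at least three tab-separated columns (`chrom`, `start`, `end`),
#' with optional `name` and `strand` columns. Coordinates are kept 0-based
#' half-open, verbatim; the output is sorted by `(chrom, start)`.
#'
#' @param path Path to the file (no header).
#' @return Tibble with columns `chrom`, `start`, `end` and, when present,
#'   `gene_id` and `strand`.
#' @export
read_bed_like <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (ncol(raw) < 3) abort("BED-like input needs >= 3 tab-separated columns.")
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("Invalid interval (start >= end or non-numeric) at line(s): %s",
                  paste(bad, collapse = ", ")))
  }
  out <- tibble(chrom = raw[[1]], start = start, end = end)
  if (ncol(raw) >= 4) out$gene_id <- raw[[4]]
  if (ncol(raw) >= 6) out$strand <- raw[[6]]
  else if (ncol(raw) == 5) out$strand <- raw[[5]]
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write intervals as a BED-like file
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `gene_id` and `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_like <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "gene_id", "strand"),
                    names(intervals))
  df <- intervals[cols]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Pipeline parameter set with validated defaults
#'
#' Collects every tunable parameter of the pipeline in one validated
#' list. `read_pipeline_config()` overlays values from a YAML file onto
#' the defaults.
#'
#' @param ... Name-value overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    qc_min_genes = 200L, qc_max_genes = 5000L, qc_max_mito_frac = 0.30,
    normalize_scale = 1e4,
    cnv_window = 101L, cnv_clip = 3.0,
    cnv_signal_threshold = 0.05, cnv_corr_threshold = 0.5,
    cnv_consensus_top_frac = 0.05, cnv_signal_stat = "mean_square",
    nmf_k = 6L, nmf_restarts = 10L,
    consensus_r_threshold = 0.2, consensus_linkage = "average",
    meta_signature_size = 20L,
    deg_padj_max = 0.01, deg_lfc_min = 1,
    compartment_resolution = 500000L,
    insulation_resolution = 40000L, insulation_window = 480000L,
    tad_delta_window = 100000L, tad_strength_min = 0.1,
    tad_min_size = 200000L,
    conserved_min_overlap = 0.70, conserved_reciprocal = TRUE,
    ice_tol = 1e-5, ice_max_iter = 200L, ice_low_coverage_frac = 0.02,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown pipeline parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (cfg$qc_min_genes >= cfg$qc_max_genes) {
    abort("qc_min_genes must be < qc_max_genes.")
  }
  check_number(cfg$qc_max_mito_frac, "qc_max_mito_frac",
               min = 0, max = 1, strict_min = TRUE)
  check_number(cfg$consensus_r_threshold, "consensus_r_threshold",
               min = -1, max = 1)
  check_number(cfg$conserved_min_overlap, "conserved_min_overlap",
               min = 0, max = 1)
  if (cfg$insulation_window %% cfg$insulation_resolution != 0) {
    abort("insulation_window must be a multiple of insulation_resolution.")
  }
  if (!cfg$cnv_signal_stat %in% c("mean_square", "range")) {
    abort("cnv_signal_stat must be \"mean_square\" or \"range\".")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file of overrides.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  over <- yaml::read_yaml(path)
  do.call(pipeline_config, over %||% list())
}
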