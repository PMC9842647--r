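#' Configuration for the synthetic single-cell RNA-seq generator
#'
#' Defines a multi-sample droplet-style experiment with planted
#' chromosome-arm copy-number changes in the malignant compartment and
#' planted co-expression programs active in subsets of malignant cells.
#' The defaults describe the study conditions used throughout the test
#' suite: ten chromosomes of equal gene content, three whole-chromosome
#' CNVs (30% of the genome altered at |log2 dosage| >= 0.5) and four
#' programs of which two emulate metastasis-associated programs.
#'
#' @param n_samples Number of tumour samples cells are drawn from.
#' @param cell_counts Named integer vector of cells per cell type; must
#'   contain a `"malignant"` entry (CNVs and programs are planted there).
#' @param n_genes Total number of genes.
#' @param n_chroms Number of chromosomes; genes are laid out in contiguous
#'   equal blocks `chr1 ... chr<n_chroms>`.
#' @param cnv_segments Data frame with columns `chrom`, `start_gene_idx`,
#'   `end_gene_idx` (1-based inclusive global gene indices) and
#'   `log2_dosage`. Segments may not overlap within a chromosome and must
#'   lie inside their named chromosome's gene block.
#' @param programs List of program descriptors, each a list with
#'   `gene_set_size`, `n_active_cells` and `effect` (log2 fold shift in
#'   active cells). Program gene sets are drawn disjointly.
#' @param library_size_mean Expected total counts per cell.
#' @param dropout_rate Probability that an observed count is zeroed.
#' @param nb_size Negative-binomial size (inverse dispersion) of the count
#'   noise.
#' @param seed Integer seed; identical configs give identical data.
#'
#' @return A `sc_sim_config` list, validated.
#' @export
sc_sim_config <- function(n_samples = 4L,
                          cell_counts = c(malignant = 600L, immune = 300L,
                                          stromal = 100L),
                          n_genes = 2000L,
                          n_chroms = 10L,
                          cnv_segments = default_cnv_segments(n_genes, n_chroms),
                          programs = default_programs(),
                          library_size_mean = 5000,
                          dropout_rate = 0.1,
                          nb_size = 2,
                          seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_genes <- check_count(n_genes, "n_genes")
  n_chroms <- check_count(n_chroms, "n_chroms")
  if (is.null(names(cell_counts)) || any(names(cell_counts) == "")) {
    abort("`cell_counts` must be a named vector.")
  }
  if (!"malignant" %in% names(cell_counts)) {
    abort("`cell_counts` must include a \"malignant\" entry.")
  }
  if (any(cell_counts <= 0) || any(cell_counts != round(cell_counts))) {
    abort("All `cell_counts` must be positive integers.")
  }
  library_size_mean <- check_number(library_size_mean, "library_size_mean",
                                    min = 0, strict_min = TRUE)
  dropout_rate <- check_number(dropout_rate, "dropout_rate", min = 0, max = 1)
  nb_size <- check_number(nb_size, "nb_size", min = 0, strict_min = TRUE)
  seed <- check_count(seed, "seed", min = 0L)

  cnv_segments <- as_tibble(cnv_segments)
  if (nrow(cnv_segments) > 0) {
    needed <- c("chrom", "start_gene_idx", "end_gene_idx", "log2_dosage")
    if (!all(needed %in% names(cnv_segments))) {
      abort("`cnv_segments` needs columns chrom, start_gene_idx, end_gene_idx, log2_dosage.")
    }
    if (any(cnv_segments$start_gene_idx < 1) ||
        any(cnv_segments$end_gene_idx > n_genes) ||
        any(cnv_segments$start_gene_idx > cnv_segments$end_gene_idx)) {
      abort("`cnv_segments` gene indices must satisfy 1 <= start <= end <= n_genes.")
    }
    # reject overlapping segments on the same chromosome
    by_chrom <- split(cnv_segments, cnv_segments$chrom)
    for (seg in by_chrom) {
      seg <- seg[order(seg$start_gene_idx), ]
      if (nrow(seg) > 1 &&
          any(seg$start_gene_idx[-1] <= seg$end_gene_idx[-nrow(seg)])) {
        abort("Overlapping CNV segments on one chromosome are not allowed.")
      }
    }
    blocks <- chrom_blocks(n_genes, n_chroms)
    seg_chr <- match(cnv_segments$chrom, blocks$chrom)
    if (anyNA(seg_chr)) abort("`cnv_segments` names a chromosome outside the layout.")
    inside <- cnv_segments$start_gene_idx >= blocks$first[seg_chr] &
      cnv_segments$end_gene_idx <= blocks$last[seg_chr]
    if (!all(inside)) {
      abort("Each CNV segment must lie within its named chromosome's gene block.")
    }
  }

  for (p in programs) {
    if (!all(c("gene_set_size", "n_active_cells", "effect") %in% names(p))) {
      abort("Each program needs gene_set_size, n_active_cells and effect.")
    }
    if (p$gene_set_size < 1 || p$n_active_cells < 1) {
      abort("Program sizes must be positive.")
    }
  }
  if (length(programs) > 0 &&
      sum(vapply(programs, function(p) p$gene_set_size, 0)) > n_genes) {
    abort("Program gene sets exceed the gene universe.")
  }

  structure(
    list(n_samples = n_samples, cell_counts = cell_counts, n_genes = n_genes,
         n_chroms = n_chroms, cnv_segments = cnv_segments, programs = programs,
         library_size_mean = library_size_mean, dropout_rate = dropout_rate,
         nb_size = nb_size, seed = seed),
    class = "sc_sim_config"
  )
}

#' @rdname sc_sim_config
#' @export
default_cnv_segments <- function(n_genes = 2000L, n_chroms = 10L) {
  per <- n_genes %/% n_chroms
  tibble(
    chrom = c("chr1", "chr2", "chr3"),
    start_gene_idx = c(1L, per + 1L, 2L * per + 1L),
    end_gene_idx = c(per, 2L * per, 3L * per),
    log2_dosage = c(1, -1, 0.5)
  )
}

#' @rdname sc_sim_config
#' @export
default_programs <- function() {
  list(
    list(name = "metastasis-I", gene_set_size = 30L, n_active_cells = 200L, effect = 2),
    list(name = "metastasis-II", gene_set_size = 30L, n_active_cells = 200L, effect = 2),
    list(name = "hypoxia", gene_set_size = 30L, n_active_cells = 200L, effect = 2),
    list(name = "cell-cycle", gene_set_size = 30L, n_active_cells = 200L, effect = 2)
  )
}

chrom_blocks <- function(n_genes, n_chroms) {
  sizes <- rep(n_genes %/% n_chroms, n_chroms)
  rem <- n_genes - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  last <- cumsum(sizes)
  tibble(chrom = paste0("chr", seq_len(n_chroms)),
         first = c(1L, head(last, -1L) + 1L), last = last, size = sizes)
}

#' Simulate a multi-sample single-cell count matrix with planted truth
#'
#' Draws per-gene baseline abundances, applies the configured CNV dosage
#' multiplicatively to malignant cells' means, up-shifts planted program
#' genes in their active cells, then adds negative-binomial count noise
#' with per-cell library-size factors followed by Bernoulli dropout.
#'
#' @param config A [sc_sim_config()].
#'
#' @return A list with
#'   * `counts`: cells x genes integer matrix,
#'   * `cells`: tibble of cell metadata (`cell_id`, `cell_type`, `sample`,
#'     `malignant`),
#'   * `annotation`: gene annotation tibble (`gene_id`, `chrom`, `start`,
#'     `end`, `strand`; 0-based half-open),
#'   * `truth`: planted ground truth (malignant cell ids, CNV segment map,
#'     program gene and cell sets).
#' @export
simulate_scrna <- function(config = sc_sim_config()) {
  stopifnot(inherits(config, "sc_sim_config"))
  withr::with_seed(config$seed, {
    n_cells <- sum(config$cell_counts)
    cell_type <- rep(names(config$cell_counts), config$cell_counts)
    cell_id <- sprintf("cell_%04d", seq_len(n_cells))
    sample_id <- paste0("s", (seq_len(n_cells) - 1L) %% config$n_samples + 1L)
    malignant <- cell_type == "malignant"

    blocks <- chrom_blocks(config$n_genes, config$n_chroms)
    gene_id <- sprintf("gene_%04d", seq_len(config$n_genes))
    chrom <- rep(blocks$chrom, blocks$size)
    # genes 10 kb apart, 1 kb long, per chromosome
    within_idx <- unlist(lapply(blocks$size, seq_len), use.names = FALSE)
    start <- (within_idx - 1L) * 10000L
    annotation <- tibble(gene_id = gene_id, chrom = chrom, start = start,
                         end = start + 1000L, strand = "+")

    # baseline relative abundances
    base <- rgamma(config$n_genes, shape = 0.5, rate = 1) + 0.02
    base <- base / sum(base)

    # per-cell mean matrix on relative scale
    mult <- matrix(1, n_cells, config$n_genes)
    if (nrow(config$cnv_segments) > 0) {
      for (s in seq_len(nrow(config$cnv_segments))) {
        seg <- config$cnv_segments[s, ]
        g <- seq.int(seg$start_gene_idx, seg$end_gene_idx)
        mult[malignant, g] <- mult[malignant, g] * 2^seg$log2_dosage
      }
    }

    # programs: disjoint gene sets, active cells drawn among malignant cells
    free_genes <- seq_len(config$n_genes)
    program_gene_sets <- list()
    program_cell_sets <- list()
    for (i in seq_along(config$programs)) {
      p <- config$programs[[i]]
      gs <- sort(sample(free_genes, p$gene_set_size))
      free_genes <- setdiff(free_genes, gs)
      n_act <- min(p$n_active_cells, sum(malignant))
      act <- sort(sample(which(malignant), n_act))
      mult[act, gs] <- mult[act, gs] * 2^p$effect
      nm <- p$name %||% paste0("program", i)
      program_gene_sets[[nm]] <- gene_id[gs]
      program_cell_sets[[nm]] <- cell_id[act]
    }

    lib <- rlnorm(n_cells, meanlog = log(config$library_size_mean) - 0.3^2 / 2,
                  sdlog = 0.3)
    mu <- (mult * rep(base, each = n_cells)) * lib
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = config$nb_size),
      n_cells, config$n_genes
    )
    if (config$dropout_rate > 0) {
      keep <- matrix(rbinom(length(counts), 1L, 1 - config$dropout_rate),
                     n_cells, config$n_genes)
      counts <- counts * keep
    }
    dimnames(counts) <- list(cell_id, gene_id)

    truth <- list(
      malignant_cell_ids = cell_id[malignant],
      cnv_segment_map = dplyr::mutate(
        config$cnv_segments,
        genes = purrr::map2(.data$start_gene_idx, .data$end_gene_idx,
                            ~ gene_id[seq.int(.x, .y)])
      ),
      program_gene_sets = program_gene_sets,
      program_cell_sets = program_cell_sets,
      base_abundance = setNames(base, gene_id)
    )

    list(
      counts = counts,
      cells = tibble(cell_id = cell_id, cell_type = cell_type,
                     sample = sample_id, malignant = malignant),
      annotation = annotation,
      truth = truth
    )
  })
}
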