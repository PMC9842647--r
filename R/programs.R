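# Intratumoral expression programs: per-cluster NMF, cross-cluster
# consensus meta-programs, signature scoring and annotation.

nmf_mu <- function(X, k, max_iter = 300L, tol = 1e-8) {
  # multiplicative updates minimizing ||X - W H||_F; X genes x cells
  eps <- 1e-12
  ng <- nrow(X)
  nc <- ncol(X)
  W <- matrix(runif(ng * k, 0.1, 1), ng, k)
  H <- matrix(runif(k * nc, 0.1, 1), k, nc)
  err_prev <- Inf
  xn <- norm(X, "F")
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      err <- norm(X - W %*% H, "F") / xn
      if (is.finite(err_prev) && abs(err_prev - err) < tol) break
      err_prev <- err
    }
  }
  err <- norm(X - W %*% H, "F") / xn
  list(W = W, H = H, rel_error = err)
}

#' Relative-expression preprocessing for program discovery
#'
#' Centers log-normalized expression per gene on the cluster mean and
#' clips negative values to zero, so that NMF factors capture deviations
#' from the cluster's average cell rather than absolute expression —
#' without this, factor loading vectors share the expression baseline
#' and every program correlates with every other across clusters.
#'
#' @param mat Cells x genes log-normalized expression matrix (one
#'   cluster).
#' @return Non-negative cells x genes matrix of positive relative
#'   expression.
#' @export
relative_expression <- function(mat) {
  mat <- check_cells_genes(mat, "mat")
  out <- sweep(mat, 2, colMeans(mat))
  out[out < 0] <- 0
  out
}

#' Non-negative matrix factorization programs for one malignant cluster
#'
#' Factorizes the (non-negative, log-normalized) expression of one
#' malignant cluster into `k` programs by multiplicative-update NMF
#' minimizing Frobenius error, keeping the best of `n_restarts` random
#' initializations. Factor loadings are L2-normalized with the scale
#' absorbed into the cell usages. Deterministic given `seed`.
#'
#' When `stability_min` is set (and `n_restarts > 1`), factors of the
#' best fit whose mean best-match correlation with the factors of the
#' other restarts falls below the threshold are dropped — a restart-
#' stability filter that removes noise factors before consensus.
#'
#' @param mat Cells x genes non-negative expression matrix restricted to
#'   one cluster (typically [relative_expression()] of the log-normalized
#'   data); needs at least `10 * k` cells.
#' @param k Number of programs; must be below both matrix dimensions.
#' @param n_restarts Random restarts; best by reconstruction error.
#' @param seed Integer seed.
#' @param cluster_id Identifier stored with the result.
#' @param n_top_genes Length of each factor's top-gene list.
#' @param stability_min Optional restart-stability threshold in \[0, 1\]
#'   (e.g. 0.7); `NULL` keeps all factors.
#' @return A `program_set`: list with `cluster_id`, `basis` (genes x k),
#'   `usage` (cells x k), `top_genes` (list of length k), `stability`
#'   (per retained factor; `NA` when unfiltered) and `rel_error`.
#' @export
nmf_programs <- function(mat, k, n_restarts = 10L, seed = 1L,
                         cluster_id = "cluster1", n_top_genes = 50L,
                         stability_min = NULL) {
  mat <- check_cells_genes(mat, "mat")
  if (any(mat < 0)) abort("NMF input must be non-negative.")
  k <- check_count(k, "k", min = 1L)
  if (k >= min(dim(mat))) abort("`k` must be smaller than both dimensions.")
  if (nrow(mat) < 10L * k) {
    warn(sprintf("Only %d cells for k = %d (< 10k); factors may be unstable.",
                 nrow(mat), k))
  }
  n_restarts <- check_count(n_restarts, "n_restarts")
  seed <- check_count(seed, "seed", min = 0L)
  X <- t(mat)  # genes x cells
  fits <- lapply(seq_len(n_restarts), function(r) {
    withr::with_seed(seed + r - 1L, nmf_mu(X, k))
  })
  best_i <- which.min(vapply(fits, function(f) f$rel_error, 0))
  best <- fits[[best_i]]
  scale <- sqrt(colSums(best$W^2))
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2, scale, "/")
  U <- t(best$H * scale)  # cells x k
  dimnames(W) <- list(colnames(mat), paste0("factor", seq_len(k)))
  dimnames(U) <- list(rownames(mat), colnames(W))

  stability <- rep(NA_real_, k)
  if (!is.null(stability_min) && n_restarts > 1L) {
    others <- fits[-best_i]
    stability <- vapply(seq_len(k), function(j) {
      mean(vapply(others, function(f) {
        r <- suppressWarnings(cor(W[, j], f$W))
        r[is.na(r)] <- 0
        max(r)
      }, 0))
    }, 0)
    keep <- stability >= stability_min
    if (!any(keep)) {
      warn(sprintf("No factor of %s passed stability >= %.2f; keeping the most stable.",
                   cluster_id, stability_min))
      keep <- seq_len(k) == which.max(stability)
    }
    W <- W[, keep, drop = FALSE]
    U <- U[, keep, drop = FALSE]
    stability <- stability[keep]
    k <- ncol(W)
  }
  top <- lapply(seq_len(k), function(j) {
    ord <- order(-W[, j], rownames(W))
    rownames(W)[ord][seq_len(min(n_top_genes, nrow(W)))]
  })
  names(top) <- colnames(W)
  structure(list(cluster_id = cluster_id, basis = W, usage = U,
                 top_genes = top, stability = stability,
                 rel_error = best$rel_error),
            class = "program_set")
}

#' Discover expression programs for every malignant cluster
#'
#' Convenience wrapper: for each cluster, takes the cluster's cells,
#' applies [relative_expression()] and runs [nmf_programs()] with the
#' restart-stability filter, returning the list of program sets ready for
#' [consensus_metaprograms()].
#'
#' @param mat Cells x genes log-normalized expression matrix (malignant
#'   cells).
#' @param clusters Cluster label per cell (length `nrow(mat)`).
#' @param k Factors per cluster.
#' @param n_restarts,seed,stability_min Passed to [nmf_programs()].
#' @return Named list of `program_set` objects, one per cluster (in
#'   sorted label order).
#' @export
discover_programs <- function(mat, clusters, k = 6L, n_restarts = 6L,
                              seed = 1L, stability_min = 0.8) {
  mat <- check_cells_genes(mat, "mat")
  clusters <- as.character(clusters)
  if (length(clusters) != nrow(mat)) {
    abort("`clusters` must have one label per cell.")
  }
  ids <- sort(unique(clusters))
  out <- lapply(seq_along(ids), function(i) {
    sub <- relative_expression(mat[clusters == ids[i], , drop = FALSE])
    nmf_programs(sub, k = k, n_restarts = n_restarts, seed = seed + i,
                 cluster_id = ids[i], stability_min = stability_min)
  })
  setNames(out, ids)
}

#' @export
print.program_set <- function(x, ...) {
  cat(sprintf("<program_set> %s: %d factors over %d genes x %d cells (rel. error %.3g)\n",
              x$cluster_id, ncol(x$basis), nrow(x$basis), nrow(x$usage),
              x$rel_error))
  invisible(x)
}

#' Factor-stability profile over candidate k
#'
#' For each candidate `k`, runs `n_restarts` factorizations and reports
#' the mean across restart pairs of the mean best-match Pearson
#' correlation between their factors — a simple stability criterion for
#' choosing `k` (factors stable when the mean pairwise r exceeds ~0.7).
#'
#' @inheritParams nmf_programs
#' @param ks Candidate factor counts.
#' @return Tibble with `k`, `mean_stability`, `rel_error`.
#' @export
nmf_k_stability <- function(mat, ks = 4:10, n_restarts = 5L, seed = 1L) {
  mat <- check_cells_genes(mat, "mat")
  X <- t(mat)
  purrr::map_dfr(ks, function(k) {
    fits <- lapply(seq_len(n_restarts), function(r) {
      withr::with_seed(seed + 1000L * k + r, nmf_mu(X, k))
    })
    pairs <- utils::combn(n_restarts, 2)
    stab <- mean(apply(pairs, 2, function(pr) {
      r_mat <- suppressWarnings(cor(fits[[pr[1]]]$W, fits[[pr[2]]]$W))
      r_mat[is.na(r_mat)] <- 0
      mean(apply(r_mat, 1, max))
    }))
    tibble(k = k, mean_stability = stab,
           rel_error = min(vapply(fits, function(f) f$rel_error, 0)))
  })
}

#' Consensus meta-programs across malignant clusters
#'
#' Pools the factor loading vectors of several per-cluster program sets
#' over the union gene universe (absent loadings are zero), clusters them
#' hierarchically with distance `1 - Pearson r`, cuts the tree at
#' `1 - r_threshold`, and summarises each cluster by the mean loading
#' vector. The meta-signature is the top `signature_size` genes by mean
#' loading (ties broken lexicographically). Singleton clusters are kept.
#'
#' @param program_sets List of [nmf_programs()] results (>= 2 programs in
#'   total; a single program is passed through as its own meta-program).
#' @param r_threshold Pearson threshold defining the tree cut.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param signature_size Meta-signature length (default 20).
#' @return Tibble with one row per meta-program: `meta_program`,
#'   `n_members`, `members` (list of tibbles with `cluster_id`,
#'   `factor`), `mean_loading` (list of named vectors), `meta_signature`
#'   (list of character vectors) and `annotation` (all `"unassigned"`).
#' @export
consensus_metaprograms <- function(program_sets, r_threshold = 0.2,
                                   linkage = "average",
                                   signature_size = 20L) {
  if (inherits(program_sets, "program_set")) program_sets <- list(program_sets)
  if (length(program_sets) == 0) abort("No program sets supplied.")
  r_threshold <- check_number(r_threshold, "r_threshold", min = -1, max = 1)

  universe <- sort(unique(unlist(lapply(program_sets,
                                        function(p) rownames(p$basis)))))
  loadings <- list()
  members <- list()
  for (p in program_sets) {
    for (j in seq_len(ncol(p$basis))) {
      v <- setNames(numeric(length(universe)), universe)
      v[rownames(p$basis)] <- p$basis[, j]
      loadings[[length(loadings) + 1L]] <- v
      members[[length(members) + 1L]] <-
        tibble(cluster_id = p$cluster_id, factor = colnames(p$basis)[j])
    }
  }
  L <- do.call(cbind, loadings)
  n_prog <- ncol(L)
  if (n_prog < 2) {
    grp <- rep(1L, n_prog)
  } else {
    r <- suppressWarnings(cor(L))
    r[is.na(r)] <- 0
    hc <- hclust(as.dist(1 - r), method = linkage)
    grp <- cutree(hc, h = 1 - r_threshold)
  }
  # canonical order: by first member index, so output is stable
  ord <- order(vapply(split(seq_len(n_prog), grp), min, 0L))
  groups <- split(seq_len(n_prog), grp)[ord]
  purrr::imap_dfr(groups, function(idx, nm) {
    mean_load <- rowMeans(L[, idx, drop = FALSE])
    gene_ord <- order(-mean_load, names(mean_load))
    sig <- names(mean_load)[gene_ord][seq_len(min(signature_size,
                                                  length(mean_load)))]
    tibble(
      meta_program = paste0("MP", which(vapply(groups, identical, TRUE, idx))),
      n_members = length(idx),
      members = list(dplyr::bind_rows(members[idx])),
      mean_loading = list(mean_load),
      meta_signature = list(sig),
      annotation = "unassigned"
    )
  })
}

#' Score cells by a meta-signature
#'
#' Mean log-normalized expression of the signature genes per cell — the
#' same scorer as [epithelial_score()].
#'
#' @inheritParams epithelial_score
#' @param meta_signature Character vector of signature genes.
#' @return Tibble with `cell_id` and `score`.
#' @export
score_cells_by_signature <- function(mat, meta_signature) {
  epithelial_score(mat, meta_signature)
}

#' Annotate a meta-signature against reference gene sets
#'
#' Hypergeometric over-representation of the signature in each reference
#' set over a declared gene universe. The label of the smallest p is
#' assigned only when that p stays below 0.01 after Bonferroni correction
#' across the reference sets; otherwise `"unassigned"`.
#'
#' @param meta_signature Character vector of signature genes.
#' @param reference_sets Named list of reference gene sets.
#' @param universe Character vector: the gene universe (non-empty).
#' @return Tibble with one row per reference set (`label`, `overlap`,
#'   `p_value`) plus attributes; the assigned label is in the
#'   `assigned` attribute and first row order (sorted by p).
#' @export
annotate_program <- function(meta_signature, reference_sets, universe) {
  if (length(universe) == 0) abort("Empty gene universe.")
  if (length(reference_sets) == 0 || is.null(names(reference_sets))) {
    abort("`reference_sets` must be a non-empty named list.")
  }
  universe <- unique(universe)
  sig <- intersect(unique(meta_signature), universe)
  res <- purrr::imap_dfr(reference_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    ov <- length(intersect(sig, set))
    p <- phyper(ov - 1L, length(set), length(universe) - length(set),
                length(sig), lower.tail = FALSE)
    tibble(label = nm, set_size = length(set), overlap = ov, p_value = p)
  })
  res <- dplyr::arrange(res, .data$p_value, .data$label)
  n_sets <- nrow(res)
  assigned <- if (res$p_value[1] * n_sets < 0.01) res$label[1] else "unassigned"
  attr(res, "assigned") <- assigned
  res
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then genes, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(bad, collapse = ", ")))
  }
  setNames(lapply(fields, function(f) f[-(1:2)]),
           vapply(fields, `[[`, "", 1L))
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
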