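# Hi-C structural analysis: ICE balancing, observed/expected,
# A/B compartments, insulation-score TADs, conserved-TAD matching and the
# per-gene structural switch report.

#' ICE matrix balancing
#'
#' Iterative correction of a symmetric contact matrix: bins with zero
#' coverage, and those in the lowest `low_coverage_frac` of non-zero
#' marginal sums, are masked; the remaining matrix is iteratively scaled
#' by its relative marginals until the coefficient of variation of the
#' retained marginals falls below `tol`. The returned map carries the
#' bias vector (`NA` on masked bins) and the balanced matrix, with masked
#' rows/columns set to `NA`.
#'
#' @param map A [contact_map()].
#' @param tol Convergence tolerance on the marginal coefficient of
#'   variation.
#' @param max_iter Iteration cap; non-convergence returns with a warning
#'   and `converged = FALSE` in the result.
#' @param low_coverage_frac Fraction of lowest-coverage non-zero bins to
#'   mask.
#' @return A balanced `contact_map` (fields `bias` and `balanced` set,
#'   plus a `converged` flag).
#' @export
ice_normalize <- function(map, tol = 1e-5, max_iter = 200L,
                          low_coverage_frac = 0.02) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$matrix
  n <- nrow(m)
  marg <- rowSums(m, na.rm = TRUE)
  all_na <- apply(m, 1, function(r) all(is.na(r)))
  retained <- marg > 0 & !all_na
  if (low_coverage_frac > 0 && any(retained)) {
    cut <- quantile(marg[retained], low_coverage_frac)
    # small relative slack keeps bins whose marginals tie with the cut up
    # to the balancing tolerance, so a balanced map is a fixed point
    retained <- retained & marg >= cut * (1 - 1e-4)
  }
  if (sum(retained) < 2) abort("Fewer than 2 bins retained for balancing.")
  w <- m[retained, retained, drop = FALSE]
  w[is.na(w)] <- 0
  bias_r <- rep(1, nrow(w))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    mu <- mean(s)
    if (mu == 0) abort("Degenerate matrix: zero marginals during balancing.")
    if (sd(s) / mu < tol) {
      converged <- TRUE
      break
    }
    s_rel <- s / mu
    w <- w / outer(s_rel, s_rel)
    bias_r <- bias_r * s_rel
  }
  if (!converged && sd(rowSums(w)) / mean(rowSums(w)) < tol) converged <- TRUE
  if (!converged) warn(sprintf("ICE did not converge in %d iterations.", max_iter))
  balanced <- matrix(NA_real_, n, n)
  balanced[retained, retained] <- w
  bias <- rep(NA_real_, n)
  bias[retained] <- bias_r
  out <- contact_map(map$bins, ifelse(is.na(balanced), NA, balanced),
                     bias = bias, resolution = map$resolution,
                     balanced = TRUE)
  out$converged <- converged
  out
}

#' Observed / expected transformation
#'
#' Divides each cis entry by the mean of its diagonal (same genomic
#' distance within the chromosome) over retained bins. Entries with zero
#' expected value, masked bins and trans entries become `NA`.
#'
#' @param map A balanced [contact_map()].
#' @return A `contact_map` holding the O/E matrix.
#' @export
observed_expected <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$matrix
  oe <- matrix(NA_real_, nrow(m), ncol(m))
  for (ch in unique(map$bins$chrom)) {
    idx <- which(map$bins$chrom == ch)
    sub <- m[idx, idx, drop = FALSE]
    nb <- length(idx)
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    for (dist in 0:(nb - 1L)) {
      sel <- d == dist
      vals <- sub[sel]
      expd <- mean(vals, na.rm = TRUE)
      out <- rep(NA_real_, sum(sel))
      if (is.finite(expd) && expd > 0) out <- vals / expd
      sub[sel] <- out
    }
    oe[idx, idx] <- sub
  }
  res <- contact_map(map$bins, oe, bias = map$bias,
                     resolution = map$resolution, balanced = map$balanced)
  res$oe <- TRUE
  res
}

#' Gene density per bin
#'
#' Counts annotated gene start positions falling in each bin — the
#' density used to orient compartment signs.
#'
#' @param bins Bin table (`chrom`, `start`, `end`).
#' @param annotation Gene annotation (`chrom`, `start`).
#' @return Integer vector, one count per bin.
#' @export
gene_density_per_bin <- function(bins, annotation) {
  vapply(seq_len(nrow(bins)), function(i) {
    sum(annotation$chrom == bins$chrom[i] &
          annotation$start >= bins$start[i] &
          annotation$start < bins$end[i])
  }, 0L)
}

#' A/B compartment track from an O/E map
#'
#' Per chromosome: Pearson correlation matrix of the O/E columns over
#' retained bins, leading eigenvector (largest absolute eigenvalue), sign
#' oriented so that the mean gene density of positive bins is at least
#' that of negative bins (equal densities fall back to "larger block is
#' A", with a warning). Positive bins are labelled A, negative B.
#'
#' @param oe_map An [observed_expected()] map.
#' @param gene_density Numeric vector of per-bin gene density (see
#'   [gene_density_per_bin()]).
#' @return Tibble with `bin_id`, `chrom`, `start`, `end`, `eigen`,
#'   `compartment` (`"A"`/`"B"`/`NA`).
#' @export
compartment_track <- function(oe_map, gene_density) {
  stopifnot(inherits(oe_map, "contact_map"))
  bins <- oe_map$bins
  if (length(gene_density) != nrow(bins)) {
    abort("`gene_density` must have one value per bin.")
  }
  ev_full <- rep(NA_real_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    sub <- oe_map$matrix[idx, idx, drop = FALSE]
    ret <- which(colSums(!is.na(sub)) > 0)
    if (length(ret) < 10) {
      warn(sprintf("Chromosome %s has < 10 retained bins; skipped.", ch))
      next
    }
    cm <- suppressWarnings(cor(sub[ret, ret], use = "pairwise.complete.obs"))
    cm[!is.finite(cm)] <- 0
    if (all(abs(cm[upper.tri(cm)]) < 1e-12)) {
      warn(sprintf("Degenerate correlation matrix on %s; all-NA track.", ch))
      next
    }
    eg <- eigen(cm, symmetric = TRUE)
    lead <- which.max(abs(eg$values))
    v <- eg$vectors[, lead]
    dens <- gene_density[idx][ret]
    pos <- v > 0
    neg <- v < 0
    d_pos <- if (any(pos)) mean(dens[pos]) else NA_real_
    d_neg <- if (any(neg)) mean(dens[neg]) else NA_real_
    if (is.finite(d_pos) && is.finite(d_neg) && d_pos != d_neg) {
      if (d_pos < d_neg) v <- -v
    } else {
      warn(sprintf(
        "Equal gene density in both compartments on %s; larger block set to A.",
        ch))
      if (sum(v > 0) < sum(v < 0)) v <- -v
    }
    ev_full[idx[ret]] <- v
  }
  tibble(bin_id = bins$bin_id, chrom = bins$chrom, start = bins$start,
         end = bins$end, eigen = ev_full,
         compartment = dplyr::case_when(ev_full > 0 ~ "A",
                                        ev_full < 0 ~ "B",
                                        TRUE ~ NA_character_))
}

locus_status <- function(track, chrom, start, end) {
  hit <- track$chrom == chrom & track$start < end & track$end > start
  if (!any(hit)) return(NULL)
  comp <- track$compartment[hit]
  n_a <- sum(comp == "A", na.rm = TRUE)
  n_b <- sum(comp == "B", na.rm = TRUE)
  if (n_a == n_b) "ambiguous" else if (n_a > n_b) "A" else "B"
}

#' Compartment switch label for a locus between two conditions
#'
#' Per condition, the status is the majority compartment sign over the
#' bins the locus overlaps (ties give `"ambiguous"`); the label joins
#' both statuses, e.g. `"B->A"` for a B-to-A switch.
#'
#' @param track_cond1,track_cond2 [compartment_track()] results sharing a
#'   bin table.
#' @param chrom,start,end The locus interval (0-based half-open).
#' @return A single label in `A->A`, `A->B`, `B->A`, `B->B`,
#'   `ambiguous`.
#' @export
compartment_switch <- function(track_cond1, track_cond2, chrom, start, end) {
  s1 <- locus_status(track_cond1, chrom, start, end)
  s2 <- locus_status(track_cond2, chrom, start, end)
  if (is.null(s1) || is.null(s2)) {
    abort("Locus does not overlap any bin of the compartment tracks.")
  }
  if (identical(s1, "ambiguous") || identical(s2, "ambiguous")) {
    return("ambiguous")
  }
  paste0(s1, "->", s2)
}

#' Insulation-score track
#'
#' For each bin `i`, the mean balanced contact in the square
#' `[i-w, i-1] x [i+1, i+w]` (with `w = window / resolution`), log2-scaled
#' against the chromosome mean of those window means. Bins within `w` of a
#' chromosome end are `NA`.
#'
#' @param map A balanced [contact_map()] (typically 40-kb bins).
#' @param window Window size in bp; must be a multiple of the map
#'   resolution.
#' @return Tibble with `bin_id`, `chrom`, `start`, `end`, `insulation`.
#' @export
insulation_track <- function(map, window = 480000) {
  stopifnot(inherits(map, "contact_map"))
  if (window %% map$resolution != 0) {
    abort("`window` must be a multiple of the map resolution.")
  }
  w <- as.integer(window / map$resolution)
  if (w < 1) abort("Window smaller than one bin.")
  bins <- map$bins
  ins <- rep(NA_real_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    nb <- length(idx)
    if (nb < 3L * w) {
      warn(sprintf("Chromosome %s shorter than 3 windows; insulation NA.", ch))
      next
    }
    sub <- map$matrix[idx, idx, drop = FALSE]
    raw <- rep(NA_real_, nb)
    for (i in (w + 1L):(nb - w)) {
      block <- sub[(i - w):(i - 1L), (i + 1L):(i + w), drop = FALSE]
      v <- mean(block, na.rm = TRUE)
      raw[i] <- if (is.finite(v)) v else NA_real_
    }
    mu <- mean(raw, na.rm = TRUE)
    if (!is.finite(mu) || mu <= 0) {
      warn(sprintf("All-NA insulation on chromosome %s; skipped.", ch))
      next
    }
    ins[idx] <- log2(raw / mu)
  }
  tibble(bin_id = bins$bin_id, chrom = bins$chrom, start = bins$start,
         end = bins$end, insulation = ins)
}

#' Call TADs from an insulation track
#'
#' A boundary sits where the delta vector — mean insulation over
#' `delta_window` to the left of a bin minus the mean to its right —
#' crosses zero downward with local depth (max of delta in the left
#' window minus min in the right window) at least `strength_min`. TADs
#' are the intervals between consecutive boundaries (and chromosome
#' ends). TADs shorter than `min_size`, or overlapping any excluded
#' region (telomeres/centromeres), are flagged filtered with a reason;
#' a chromosome without boundaries yields a single whole-chromosome TAD
#' flagged low-confidence.
#'
#' @param track An [insulation_track()] tibble.
#' @param delta_window Averaging window of the delta vector, bp.
#' @param strength_min Minimum boundary depth.
#' @param min_size Minimum retained TAD length, bp (default 200 kb).
#' @param excluded Optional tibble of excluded intervals (`chrom`,
#'   `start`, `end`).
#' @return A `tad_set` tibble: `chrom`, `start`, `end`,
#'   `boundary_strength` (strength of the boundary starting the TAD, `NA`
#'   at chromosome starts), `filtered`, `reason`, `retained`,
#'   `low_confidence`.
#' @export
call_tads <- function(track, delta_window = 100000, strength_min = 0.1,
                      min_size = 200000, excluded = NULL) {
  if (!all(c("chrom", "start", "end", "insulation") %in% names(track))) {
    abort("`track` must be an insulation_track tibble.")
  }
  res <- max(track$end - track$start)
  dw <- max(1L, as.integer(round(delta_window / res)))
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    nb <- nrow(tr)
    is <- tr$insulation
    delta <- rep(NA_real_, nb)
    for (i in seq_len(nb)) {
      left <- if (i > 1L) is[max(1L, i - dw):(i - 1L)] else numeric()
      right <- if (i < nb) is[(i + 1L):min(nb, i + dw)] else numeric()
      ml <- mean(left, na.rm = TRUE)
      mr <- mean(right, na.rm = TRUE)
      if (is.finite(ml) && is.finite(mr)) delta[i] <- ml - mr
    }
    bounds <- integer()
    strengths <- numeric()
    for (i in seq_len(nb - 1L)) {
      if (!is.na(delta[i]) && !is.na(delta[i + 1L]) &&
          delta[i] >= 0 && delta[i + 1L] < 0) {
        lo <- max(1L, i - dw + 1L)
        hi <- min(nb, i + dw)
        depth <- suppressWarnings(
          max(delta[lo:i], na.rm = TRUE) -
            min(delta[(i + 1L):hi], na.rm = TRUE))
        if (is.finite(depth) && depth >= strength_min) {
          bounds <- c(bounds, i)
          strengths <- c(strengths, depth)
        }
      }
    }
    chrom_start <- min(tr$start)
    chrom_end <- max(tr$end)
    if (length(bounds) == 0) {
      out[[ch]] <- tibble(chrom = ch, start = chrom_start, end = chrom_end,
                          boundary_strength = NA_real_,
                          low_confidence = TRUE)
      next
    }
    cuts <- tr$end[bounds]  # boundary between bin i and i+1
    edges <- c(chrom_start, cuts, chrom_end)
    out[[ch]] <- tibble(chrom = ch, start = edges[-length(edges)],
                        end = edges[-1L],
                        boundary_strength = c(NA_real_, strengths),
                        low_confidence = FALSE)
  }
  tads <- dplyr::bind_rows(out)
  reason <- rep(NA_character_, nrow(tads))
  reason[tads$end - tads$start < min_size] <- "min_size"
  if (!is.null(excluded) && nrow(excluded) > 0) {
    for (r in seq_len(nrow(excluded))) {
      hit <- is.na(reason) & tads$chrom == excluded$chrom[r] &
        tads$start < excluded$end[r] & tads$end > excluded$start[r]
      reason[hit] <- "excluded_region"
    }
  }
  tads$filtered <- !is.na(reason)
  tads$reason <- reason
  tads$retained <- !tads$filtered
  structure(tads, class = c("tad_set", class(tads)))
}

#' Match conserved TADs between two conditions
#'
#' A pair `(x, y)` of retained TADs is conserved when the overlap covers
#' at least `min_overlap` of `x` and (reciprocally) of `y`. Each TAD is
#' matched to at most one partner — the one with the greatest overlap,
#' ties to the leftmost.
#'
#' @param tads_a,tads_b [call_tads()] results (only retained TADs are
#'   considered).
#' @param min_overlap Required overlap fraction (default 0.70).
#' @param reciprocal Require the fraction on both TADs (default `TRUE`).
#' @return List with `pairs` (tibble: indices into the retained sets,
#'   `overlap`, `frac_a`, `frac_b`, `conserved`) and `tads_a`/`tads_b`
#'   with a per-TAD `conserved` flag added.
#' @export
conserved_tads <- function(tads_a, tads_b, min_overlap = 0.70,
                           reciprocal = TRUE) {
  keep <- function(t) {
    if ("retained" %in% names(t)) t[t$retained, , drop = FALSE] else t
  }
  a <- keep(as_tibble(tads_a))
  b <- keep(as_tibble(tads_b))
  cand <- list()
  for (i in seq_len(nrow(a))) {
    hit <- which(b$chrom == a$chrom[i] & b$start < a$end[i] &
                   b$end > a$start[i])
    for (j in hit) {
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      cand[[length(cand) + 1L]] <- tibble(
        idx_a = i, idx_b = j, overlap = ov,
        frac_a = ov / (a$end[i] - a$start[i]),
        frac_b = ov / (b$end[j] - b$start[j]))
    }
  }
  pairs <- if (length(cand) > 0) dplyr::bind_rows(cand) else
    tibble(idx_a = integer(), idx_b = integer(), overlap = numeric(),
           frac_a = numeric(), frac_b = numeric())
  # greedy one-to-one matching: greatest overlap first, ties leftmost
  if (nrow(pairs) > 0) {
    ord <- order(-pairs$overlap, a$start[pairs$idx_a], b$start[pairs$idx_b])
    pairs <- pairs[ord, ]
    used_a <- used_b <- logical(0)
    take <- logical(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      ia <- pairs$idx_a[r]
      ib <- pairs$idx_b[r]
      if (!isTRUE(used_a[ia]) && !isTRUE(used_b[ib])) {
        take[r] <- TRUE
        used_a[ia] <- TRUE
        used_b[ib] <- TRUE
      }
    }
    pairs <- pairs[take, ]
    pairs$conserved <- pairs$frac_a >= min_overlap &
      (!reciprocal | pairs$frac_b >= min_overlap)
    pairs <- dplyr::arrange(pairs, .data$idx_a)
  } else {
    pairs$conserved <- logical(0)
  }
  a$conserved <- seq_len(nrow(a)) %in% pairs$idx_a[pairs$conserved]
  b$conserved <- seq_len(nrow(b)) %in% pairs$idx_b[pairs$conserved]
  list(pairs = pairs, tads_a = a, tads_b = b)
}

#' Interior boundary positions of a TAD set
#'
#' Returns the genomic positions where two consecutive retained TADs
#' abut, per chromosome.
#'
#' @param tads A [call_tads()] result.
#' @return Tibble with `chrom` and `pos` (bp).
#' @export
tad_boundaries_of <- function(tads) {
  # interior edges between consecutive retained TADs
  t <- if ("retained" %in% names(tads)) tads[tads$retained, ] else tads
  out <- list()
  for (ch in unique(t$chrom)) {
    s <- t[t$chrom == ch, ]
    s <- s[order(s$start), ]
    pos <- intersect(s$end[-nrow(s)], s$start[-1L])
    if (length(pos) > 0) out[[ch]] <- tibble(chrom = ch, pos = pos)
  }
  if (length(out) == 0) tibble(chrom = character(), pos = numeric())
  else dplyr::bind_rows(out)
}

#' Per-gene structural comparison report between two conditions
#'
#' For every annotated gene: the compartment status in each condition
#' (majority sign over overlapping compartment bins), the switch label, a
#' boundary-change flag (a retained TAD boundary within two insulation
#' bins of the gene in exactly one condition) and the local insulation
#' difference (condition 2 minus condition 1 at the gene's bin). Genes on
#' chromosomes absent from the tracks get an `NA` row.
#'
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param comp1,comp2 [compartment_track()] tibbles per condition.
#' @param tads1,tads2 [call_tads()] results per condition.
#' @param ins1,ins2 [insulation_track()] tibbles per condition.
#' @param boundary_tol_bins Boundary proximity tolerance, in insulation
#'   bins.
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `compartment_cond1`, `compartment_cond2`, `switch`,
#'   `boundary_change`, `insulation_diff`.
#' @export
gene_structure_report <- function(annotation, comp1, comp2, tads1, tads2,
                                  ins1, ins2, boundary_tol_bins = 2L) {
  ins_res <- max(ins1$end - ins1$start)
  tol <- boundary_tol_bins * ins_res
  b1 <- tad_boundaries_of(tads1)
  b2 <- tad_boundaries_of(tads2)
  near_boundary <- function(bt, chrom, start, end) {
    any(bt$chrom == chrom & bt$pos >= start - tol & bt$pos <= end + tol)
  }
  ins_at <- function(ins, chrom, pos) {
    hit <- which(ins$chrom == chrom & ins$start <= pos & ins$end > pos)
    if (length(hit) == 0) NA_real_ else ins$insulation[hit[1]]
  }
  purrr::map_dfr(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    s1 <- locus_status(comp1, g$chrom, g$start, g$end)
    s2 <- locus_status(comp2, g$chrom, g$start, g$end)
    if (is.null(s1) || is.null(s2)) {
      return(tibble(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                    end = g$end, compartment_cond1 = NA_character_,
                    compartment_cond2 = NA_character_, switch = NA_character_,
                    boundary_change = NA, insulation_diff = NA_real_))
    }
    sw <- if (s1 == "ambiguous" || s2 == "ambiguous") "ambiguous" else
      paste0(s1, "->", s2)
    nb1 <- near_boundary(b1, g$chrom, g$start, g$end)
    nb2 <- near_boundary(b2, g$chrom, g$start, g$end)
    tibble(gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
           compartment_cond1 = s1, compartment_cond2 = s2, switch = sw,
           boundary_change = xor(nb1, nb2),
           insulation_diff = ins_at(ins2, g$chrom, g$start) -
             ins_at(ins1, g$chrom, g$start))
  })
}

#' Write a per-bin track as bedGraph
#'
#' @param track Tibble with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default last column).
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, value = NULL) {
  value <- value %||% names(track)[ncol(track)]
  df <- track[!is.na(track[[value]]), c("chrom", "start", "end", value)]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
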