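#' Configuration for the synthetic Hi-C contact-map generator
#'
#' Describes a single-chromosome binned contact map for two conditions
#' sharing a distance-decay background but allowed to differ in planted
#' A/B compartment sign tracks and TAD boundaries (emulating a normal
#' versus tumour cell-line comparison).
#'
#' @param n_bins Number of bins.
#' @param bin_size Bin width in bp.
#' @param compartment_blocks Run lengths of alternating compartment signs
#'   (first block is A/+1); either one vector shared by both conditions or
#'   a list of two vectors, one per condition. Must sum to `n_bins`;
#'   `NULL` gives four near-equal blocks shared by both conditions.
#' @param tad_boundaries Sorted interior bin indices (1-based, exclusive of
#'   chromosome ends) where TADs abut; one vector or a list of two.
#'   `NULL` plants quartile boundaries plus one extra boundary in
#'   condition 2.
#' @param contact_decay_exponent Power-law exponent of the distance decay.
#' @param noise_sd Standard deviation of multiplicative log-normal noise
#'   (on the natural-log scale), symmetrized.
#' @param tad_enrichment Multiplier applied to within-TAD contacts.
#' @param compartment_strength Strength `c` of the rank-1 modulation
#'   `1 + c * s_i * s_j`; must be in \[0, 1).
#' @param base_contacts Expected contact count at distance zero.
#' @param seed Integer seed.
#'
#' @return A validated `hic_sim_config` list.
#' @export
hic_sim_config <- function(n_bins = 100L,
                           bin_size = 500000L,
                           compartment_blocks = NULL,
                           tad_boundaries = NULL,
                           contact_decay_exponent = 1,
                           noise_sd = 0.1,
                           tad_enrichment = 2,
                           compartment_strength = 0.4,
                           base_contacts = 1000,
                           seed = 1L) {
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  bin_size <- check_count(bin_size, "bin_size")
  contact_decay_exponent <- check_number(contact_decay_exponent,
                                         "contact_decay_exponent", min = 0)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  tad_enrichment <- check_number(tad_enrichment, "tad_enrichment",
                                 min = 0, strict_min = TRUE)
  compartment_strength <- check_number(compartment_strength,
                                       "compartment_strength",
                                       min = 0, max = 1, strict_max = TRUE)
  base_contacts <- check_number(base_contacts, "base_contacts",
                                min = 0, strict_min = TRUE)
  seed <- check_count(seed, "seed", min = 0L)

  # defaults: four near-equal alternating compartment blocks shared by both
  # conditions; condition 2 gains one extra TAD boundary (a planted change)
  if (is.null(compartment_blocks)) {
    q <- n_bins %/% 4L
    compartment_blocks <- c(rep(q, 3L), n_bins - 3L * q)
  }
  if (is.null(tad_boundaries)) {
    q <- n_bins %/% 4L
    tad_boundaries <- list(c(q, 2L * q, 3L * q),
                           unique(sort(c(q, q + max(1L, q %/% 2L),
                                         2L * q, 3L * q))))
  }
  as_pair <- function(x) {
    if (is.list(x)) {
      if (length(x) == 1L) rep(x, 2L) else x
    } else {
      list(x, x)
    }
  }
  compartment_blocks <- as_pair(compartment_blocks)
  tad_boundaries <- as_pair(tad_boundaries)
  if (length(compartment_blocks) != 2L || length(tad_boundaries) != 2L) {
    abort("Per-condition fields must have length 1 or 2.")
  }
  for (b in compartment_blocks) {
    if (length(b) > 0 && (any(b < 1) || sum(b) != n_bins)) {
      abort("`compartment_blocks` must be positive and sum to n_bins.")
    }
  }
  for (tb in tad_boundaries) {
    if (length(tb) > 0 &&
        (is.unsorted(tb, strictly = TRUE) || any(tb < 1) || any(tb >= n_bins))) {
      abort("`tad_boundaries` must be strictly increasing interior bin indices.")
    }
  }

  structure(
    list(n_bins = n_bins, bin_size = bin_size,
         compartment_blocks = compartment_blocks,
         tad_boundaries = tad_boundaries,
         contact_decay_exponent = contact_decay_exponent,
         noise_sd = noise_sd, tad_enrichment = tad_enrichment,
         compartment_strength = compartment_strength,
         base_contacts = base_contacts, seed = seed),
    class = "hic_sim_config"
  )
}

blocks_to_signs <- function(blocks, n_bins) {
  if (length(blocks) == 0) return(rep(1, n_bins))
  rep(rep_len(c(1, -1), length(blocks)), blocks)
}

boundaries_to_tads <- function(bounds, n_bins, bin_size, chrom = "chr1") {
  edges <- c(0L, as.integer(bounds), n_bins)
  tibble(chrom = chrom,
         start = edges[-length(edges)] * as.numeric(bin_size),
         end = edges[-1L] * as.numeric(bin_size))
}

#' Simulate paired Hi-C contact maps with planted structure
#'
#' Builds, for each of two conditions, a symmetric contact matrix whose
#' expected value is a power-law distance decay modulated by (i) a rank-1
#' compartment term `1 + c * s_i * s_j` from the planted sign track and
#' (ii) a within-TAD enrichment factor, then perturbed by symmetrized
#' multiplicative log-normal noise.
#'
#' @param config A [hic_sim_config()].
#'
#' @return A list with `maps` (two [contact_map()] objects, `cond1` and
#'   `cond2`) and `truth` (planted compartment sign tracks and TAD
#'   interval tables per condition).
#' @export
simulate_hic <- function(config = hic_sim_config()) {
  stopifnot(inherits(config, "hic_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_bins
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    decay <- config$base_contacts * (d + 1)^(-config$contact_decay_exponent)

    bins <- tibble(bin_id = seq_len(n) - 1L, chrom = "chr1",
                   start = (seq_len(n) - 1L) * as.numeric(config$bin_size),
                   end = seq_len(n) * as.numeric(config$bin_size))

    maps <- list()
    truth <- list(compartment_signs = list(), tad_intervals = list())
    for (cond in 1:2) {
      s <- blocks_to_signs(config$compartment_blocks[[cond]], n)
      comp <- 1 + config$compartment_strength * outer(s, s)
      bounds <- config$tad_boundaries[[cond]]
      if (length(bounds) > 0) {
        tad_id <- findInterval(seq_len(n) - 0.5, c(0, bounds, n))
        within <- outer(tad_id, tad_id, "==")
        tad_mult <- ifelse(within, config$tad_enrichment, 1)
      } else {
        tad_mult <- 1  # no planted domains: pure decay background
      }
      m <- decay * comp * tad_mult
      if (config$noise_sd > 0) {
        e <- matrix(rnorm(n * n, sd = config$noise_sd), n, n)
        e <- (e + t(e)) / 2
        m <- m * exp(e)
      }
      nm <- paste0("cond", cond)
      maps[[nm]] <- contact_map(bins, m, resolution = config$bin_size)
      truth$compartment_signs[[nm]] <- s
      truth$tad_intervals[[nm]] <-
        boundaries_to_tads(bounds, n, config$bin_size)
    }
    list(maps = maps, truth = truth)
  })
}
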