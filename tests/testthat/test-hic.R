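test_that("ICE leaves a doubly-balanced matrix unchanged with unit bias", {
  # equal row sums: already a fixed point of the iteration
  m <- matrix(1, 6, 6)
  diag(m) <- 2
  map <- toy_contact_map(m)
  bal <- ice_normalize(map)
  expect_true(bal$converged)
  expect_equal(unname(bal$bias), rep(1, 6), tolerance = 1e-8)
  expect_equal(bal$matrix, m, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ICE equalizes retained marginals and is idempotent", {
  sim <- simulate_hic(hic_sim_config(n_bins = 50, noise_sd = 0.3, seed = 13))
  bal <- ice_normalize(sim$maps$cond1, tol = 1e-6)
  marg <- rowSums(bal$matrix, na.rm = TRUE)
  marg <- marg[!is.na(bal$bias)]
  expect_lt(sd(marg) / mean(marg), 1e-5)

  twice <- ice_normalize(bal, tol = 1e-6)
  expect_equal(twice$matrix, bal$matrix, tolerance = 1e-6)
})

test_that("ICE bias solves the fixed-point equations on a 4x4 oracle", {
  m <- matrix(c(0, 4, 2, 1,
                4, 0, 6, 2,
                2, 6, 0, 3,
                1, 2, 3, 0), 4, 4)
  bal <- ice_normalize(toy_contact_map(m), tol = 1e-10, max_iter = 2000,
                       low_coverage_frac = 0)
  # independent naive fixed-point iteration on the defining equations
  b <- rep(1, 4)
  for (it in 1:20000) {
    w <- m / outer(b, b)
    s <- rowSums(w)
    b <- b * s / mean(s)
  }
  w <- m / outer(b, b)
  # the balanced matrix is unique up to overall scale
  expect_equal(bal$matrix / mean(bal$matrix), w / mean(w),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(bal$bias) / mean(bal$bias), b / mean(b),
               tolerance = 1e-5)
})

test_that("observed/expected normalizes every diagonal to mean one", {
  sim <- simulate_hic(hic_sim_config(n_bins = 40, seed = 21))
  bal <- ice_normalize(sim$maps$cond1)
  oe <- observed_expected(bal)
  keep <- which(!is.na(oe$bias))
  sub <- oe$matrix[keep, keep]
  nd <- length(keep)
  d <- abs(outer(seq_len(nd), seq_len(nd), "-"))
  for (dist in 0:5) {
    expect_equal(mean(sub[d == dist], na.rm = TRUE), 1, tolerance = 1e-10)
  }

  # a matrix equal to its own distance profile becomes all ones
  prof <- outer(1:8, 1:8, function(i, j) 100 / (abs(i - j) + 1))
  oe2 <- observed_expected(toy_contact_map(prof))
  expect_true(all(abs(oe2$matrix - 1) < 1e-12))

  # spot-check one entry against a manual diagonal mean on a 6-bin fixture
  set.seed(2)
  m <- matrix(rexp(36), 6, 6)
  m <- (m + t(m)) / 2
  oe3 <- observed_expected(toy_contact_map(m))
  manual <- m[1, 3] / mean(m[cbind(1:4, 3:6)])
  expect_equal(oe3$matrix[1, 3], manual, tolerance = 1e-12)
})

test_that("planted checkerboard compartments are recovered exactly without noise", {
  cfg <- hic_sim_config(n_bins = 40, compartment_blocks = c(10L, 10L, 10L, 10L),
                        tad_boundaries = integer(), noise_sd = 0, seed = 1)
  sim <- simulate_hic(cfg)
  bal <- ice_normalize(sim$maps$cond1)
  oe <- observed_expected(bal)
  dens <- ifelse(sim$truth$compartment_signs$cond1 > 0, 5, 1)
  track <- compartment_track(oe, dens)
  expect_identical(track$compartment,
                   ifelse(sim$truth$compartment_signs$cond1 > 0, "A", "B"))

  # orientation follows gene density: swapping density flips the labels
  track_flip <- compartment_track(oe, rev(dens))
  expect_identical(track_flip$compartment,
                   ifelse(sim$truth$compartment_signs$cond1 > 0, "B", "A"))

  # equal gene density falls back to the larger block, with a warning
  cfg2 <- hic_sim_config(n_bins = 40, compartment_blocks = c(30L, 10L),
                         tad_boundaries = integer(), noise_sd = 0, seed = 2)
  sim2 <- simulate_hic(cfg2)
  oe2 <- observed_expected(ice_normalize(sim2$maps$cond1))
  expect_warning(tr2 <- compartment_track(oe2, rep(1, 40)), "larger block")
  expect_equal(sum(tr2$compartment == "A", na.rm = TRUE), 30)
})

test_that("compartment switch labels follow the majority-sign rule", {
  mk_track <- function(signs) {
    tibble::tibble(bin_id = seq_along(signs) - 1L, chrom = "chr1",
                   start = (seq_along(signs) - 1L) * 1e5,
                   end = seq_along(signs) * 1e5,
                   eigen = signs,
                   compartment = ifelse(signs > 0, "A",
                                        ifelse(signs < 0, "B", NA)))
  }
  t_b <- mk_track(c(-1, -1, -1, 1))
  t_a <- mk_track(c(1, 1, 1, 1))
  expect_equal(compartment_switch(t_a, t_a, "chr1", 0, 2e5), "A->A")
  expect_equal(compartment_switch(t_b, t_a, "chr1", 0, 2e5), "B->A")
  expect_equal(compartment_switch(t_b, t_b, "chr1", 0, 2e5), "B->B")
  # locus spanning two bins with opposite signs in one condition
  t_mix <- mk_track(c(-1, 1, 1, 1))
  expect_equal(compartment_switch(t_mix, t_a, "chr1", 0, 2e5), "ambiguous")
  expect_error(compartment_switch(t_a, t_a, "chr9", 0, 2e5), "Locus")
})

test_that("insulation is zero on uniform matrices and scale-invariant", {
  u <- matrix(1, 30, 30)
  map <- toy_contact_map(u, bin_size = 4e4)
  ins <- insulation_track(map, window = 1.6e5)
  defined <- !is.na(ins$insulation)
  expect_true(any(defined))
  expect_true(all(abs(ins$insulation[defined]) < 1e-12))

  sim <- simulate_hic(hic_sim_config(n_bins = 60, bin_size = 4e4,
                                     tad_boundaries = list(c(20L, 40L)),
                                     seed = 3))
  bal <- ice_normalize(sim$maps$cond1)
  i1 <- insulation_track(bal, window = 1.6e5)
  scaled <- bal
  scaled$matrix <- bal$matrix * 7.3
  i2 <- insulation_track(scaled, window = 1.6e5)
  expect_equal(i1$insulation, i2$insulation, tolerance = 1e-10)
})

test_that("a planted block boundary is the exact insulation minimum", {
  cfg <- hic_sim_config(n_bins = 60, bin_size = 4e4,
                        compartment_blocks = 60L, compartment_strength = 0,
                        tad_boundaries = list(30L), noise_sd = 0,
                        tad_enrichment = 3, seed = 1)
  sim <- simulate_hic(cfg)
  ins <- insulation_track(sim$maps$cond1, window = 1.6e5)
  # minimum must sit at one of the two bins abutting the planted cut
  expect_true(which.min(ins$insulation) %in% c(30L, 31L))
})

test_that("TAD calling recovers planted blocks and applies the size filter", {
  # three 400-kb blocks at 40-kb bins
  cfg <- hic_sim_config(n_bins = 30, bin_size = 4e4, compartment_blocks = 30L,
                        compartment_strength = 0, noise_sd = 0.05,
                        tad_boundaries = list(c(10L, 20L)),
                        tad_enrichment = 3, seed = 5)
  sim <- simulate_hic(cfg)
  bal <- ice_normalize(sim$maps$cond1)
  ins <- insulation_track(bal, window = 1.6e5)
  tads <- call_tads(ins, delta_window = 1.2e5)
  retained <- tads[tads$retained, ]
  expect_equal(nrow(retained), 3L)
  expect_equal(retained$start, c(0, 4e5, 8e5))
  expect_equal(retained$end, c(4e5, 8e5, 12e5))

  # boundary positions are invariant to an additive shift of the track
  shifted <- ins
  shifted$insulation <- shifted$insulation + 0.7
  tads2 <- call_tads(shifted, delta_window = 1.2e5)
  expect_equal(tads2$start, tads$start)

  # a 150-kb domain between two insulation valleys is filtered for min_size
  is_vals <- rep(0, 30)
  is_vals[c(10, 13)] <- -1  # valleys three 50-kb bins apart
  track150 <- tibble::tibble(bin_id = 0:29, chrom = "chr1",
                             start = (0:29) * 5e4, end = (1:30) * 5e4,
                             insulation = is_vals)
  tads3 <- call_tads(track150, delta_window = 5e4)
  small <- tads3[tads3$end - tads3$start < 2e5, ]
  expect_equal(nrow(small), 1L)
  expect_equal(small$start, 5e5)
  expect_equal(small$end, 6.5e5)
  expect_true(all(small$filtered))
  expect_true(all(small$reason == "min_size"))
  expect_false(any(tads3$retained & tads3$end - tads3$start < 2e5))

  # excluded regions are flagged with their own reason
  tads4 <- call_tads(ins, delta_window = 1.2e5,
                     excluded = tibble::tibble(chrom = "chr1", start = 0,
                                               end = 5e4))
  expect_equal(tads4$reason[1], "excluded_region")
})

test_that("conserved-TAD matching honours the reciprocal 70% rule", {
  mk_tads <- function(df) {
    df$filtered <- FALSE
    df$retained <- TRUE
    df
  }
  a <- mk_tads(tibble::tibble(chrom = "chr1", start = 0, end = 1e6))
  b <- mk_tads(tibble::tibble(chrom = "chr1", start = 0, end = 7e5))
  res <- conserved_tads(a, b)
  # 700/1000 = 0.70 >= 0.70 and 700/700 = 1.0: conserved boundary case
  expect_true(res$pairs$conserved)
  expect_equal(res$pairs$frac_a, 0.7)

  c_ <- mk_tads(tibble::tibble(chrom = "chr1", start = 5e5, end = 1e6))
  res2 <- conserved_tads(a, c_)
  expect_false(res2$pairs$conserved)

  # identical sets: everything conserved; matching is symmetric
  sets <- mk_tads(tibble::tibble(chrom = "chr1",
                                 start = c(0, 4e5, 9e5),
                                 end = c(4e5, 9e5, 1.5e6)))
  res3 <- conserved_tads(sets, sets)
  expect_true(all(res3$tads_a$conserved))
  ab <- conserved_tads(a, b)
  ba <- conserved_tads(b, a)
  expect_equal(ab$pairs$conserved, ba$pairs$conserved)
  expect_equal(ab$pairs$frac_a, ba$pairs$frac_b)
})

test_that("the per-gene structure report flags only the planted switch locus", {
  # condition 2 flips bins 31..40 from B to A and adds a boundary at bin 35
  cfg <- hic_sim_config(
    n_bins = 40, bin_size = 1e5,
    compartment_blocks = list(c(20L, 20L), c(20L, 10L, 10L)),
    tad_boundaries = list(c(10L, 30L), c(10L, 30L, 35L)),
    noise_sd = 0.05, seed = 8)
  sim <- simulate_hic(cfg)
  prep <- function(map) {
    bal <- ice_normalize(map)
    list(oe = observed_expected(bal),
         ins = insulation_track(bal, window = 3e5))
  }
  p1 <- prep(sim$maps$cond1)
  p2 <- prep(sim$maps$cond2)
  dens1 <- ifelse(sim$truth$compartment_signs$cond1 > 0, 5, 1)
  comp1 <- compartment_track(p1$oe, dens1)
  comp2 <- compartment_track(p2$oe, dens1)
  tads1 <- call_tads(p1$ins, delta_window = 2e5)
  tads2 <- call_tads(p2$ins, delta_window = 2e5)

  ann <- tibble::tibble(
    gene_id = c("stable_gene", "switch_gene", "outside"),
    chrom = c("chr1", "chr1", "chr7"),
    start = c(5e5, 3.44e6, 100), end = c(5.1e5, 3.46e6, 200))
  rep_ <- gene_structure_report(ann, comp1, comp2, tads1, tads2,
                                p1$ins, p2$ins)
  expect_equal(nrow(rep_), 3L)
  expect_equal(rep_$switch[1], "A->A")
  expect_equal(rep_$switch[2], "B->A")
  expect_true(rep_$boundary_change[2])
  expect_false(rep_$boundary_change[1])
  expect_true(is.na(rep_$switch[3]))

  # identical conditions: no switches, no boundary changes, zero IS diff
  same <- gene_structure_report(ann[1:2, ], comp1, comp1, tads1, tads1,
                                p1$ins, p1$ins)
  expect_equal(same$switch, c("A->A", "B->B"))
  expect_false(any(same$boundary_change))
  expect_true(all(same$insulation_diff == 0))
})
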