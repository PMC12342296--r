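test_that("the reference karyotype freezes the large/short boundary", {
  ref <- gecko_reference_karyotype()
  expect_equal(ref$size_class, c(rep("large", 4), rep("short", 13)))
  expect_equal(ref$morphology[c(1, 4)], c("metacentric", "metacentric"))
  expect_equal(mean(ref$length_um), 60.31, tolerance = 1e-9)
  expect_true(all(diff(ref$length_um[5:17]) < 0))
})

test_that("strictly decreasing lengths with metacentrics first and fourth rank identically", {
  ds <- toy_two_cells()   # built on the reference profile in rank order
  ranked <- rank_scs(ds)
  for (id in c("A", "B")) {
    s <- ranked$scs[ranked$scs$cell_id == id, ]
    expect_equal(s$sc_rank[order(-s$length_um)][c(1, 4)] %in% c(1L, 4L),
                 c(TRUE, TRUE))
    expect_equal(sort(s$sc_rank), 1:17)
  }
  # the toy is already in reference order, so ranking is the identity
  expect_equal(ranked$scs$sc_rank[ranked$scs$cell_id == "A"], 1:17)
})

test_that("ranking is deterministic under ties and is always a permutation", {
  prof <- gecko_sc_profile()
  base <- toy_two_cells()
  ds <- filter_cells(base, animal = "a1")
  # force a three-way tie among acrocentrics and shuffle input order
  scs <- ds$scs[ds$scs$cell_id == "A", ]
  scs$length_um[c(6, 7, 8)] <- 50
  set.seed(77)
  for (i in 1:5) {
    shuffled <- scs[sample(nrow(scs)), ]
    one <- meio_dataset(ds$cells[ds$cells$cell_id == "A", ], shuffled,
                        ds$foci[ds$foci$cell_id == "A", ])
    r1 <- rank_scs(one)$scs
    r2 <- rank_scs(one)$scs
    expect_identical(r1, r2)
    expect_equal(sort(r1$sc_rank), 1:17)
    expect_equal(sort(r1$sc_rank[r1$morphology == "metacentric"]), c(1L, 4L))
  }
  # cells without 17 SCs are excluded with a log message
  partial <- meio_dataset(ds$cells, ds$scs[-1, ], ds$foci)
  expect_message(out <- rank_scs(partial), "excluding 1 cell")
  expect_equal(attr(out, "excluded_cells"), "A")
})

test_that("length summaries recover construction: single cell, shrinkage ratio", {
  one <- filter_cells(toy_two_cells(), animal = "a1")
  one$cells <- one$cells[one$cells$cell_id == "A", ]
  one$scs <- one$scs[one$scs$cell_id == "A", ]
  one$foci <- one$foci[one$foci$cell_id == "A", ]
  s <- sc_length_summary(one)
  expect_equal(s$per_rank$mean_um, gecko_sc_profile()$length_um)
  expect_true(all(s$per_rank$sd_um == 0))
  expect_equal(s$per_cell$total_um, sum(gecko_sc_profile()$length_um))

  full <- simulate_dataset(quick_config(n_cells = 100, seed = 81))
  shrunk <- simulate_dataset(quick_config(n_cells = 100, seed = 82,
                                          axis_shrinkage = 0.8))
  ratio <- sc_length_summary(shrunk)$grand_mean_um /
    sc_length_summary(full)$grand_mean_um
  expect_equal(ratio, 0.8, tolerance = 0.04)
})

test_that("CO density follows the arithmetic and the obligate-CO model property", {
  ds <- toy_two_cells()
  dens <- co_density(ds)
  sc50 <- dens$per_sc
  # hand check on one SC: density = n/length
  expect_equal(sc50$density_per_um, sc50$n_foci / sc50$length_um)
  # pure shrinkage with unchanged counts scales density by 1/0.8
  shrunk <- ds
  shrunk$scs$length_um <- shrunk$scs$length_um * 0.8
  shrunk$scs$centromere_um <- shrunk$scs$centromere_um * 0.8
  shrunk$foci$position_um <- shrunk$foci$position_um * 0.8
  expect_equal(co_density(shrunk)$per_rank$density_per_um,
               dens$per_rank$density_per_um * 1.25, tolerance = 1e-12)
  # fixed intensity, no conditioning: density approximately rank-independent;
  # obligate CO: density rises as axes shorten
  flat <- simulate_dataset(quick_config(n_cells = 150, seed = 83,
                                        obligate_co = FALSE,
                                        centromere_suppression_p = 0))
  obl <- simulate_dataset(quick_config(n_cells = 150, seed = 84,
                                       centromere_suppression_p = 0))
  d_flat <- co_density(flat)$per_rank
  d_obl <- co_density(obl)$per_rank
  expect_lt(max(d_flat$density_per_um) / min(d_flat$density_per_um), 1.35)
  expect_lt(stats::cor(d_obl$mean_length_um, d_obl$density_per_um,
                       method = "spearman"), -0.8)
})

test_that("relative positions use the centromere as reference on both morphologies", {
  # metacentric: length 100, centromere 40, focus at 70 -> q arm, 0.5
  ds <- toy_metacentric(c(0, 40, 70, 100))
  rp <- relative_positions(ds)
  expect_equal(rp$arm, c("p", "q", "q", "q"))
  expect_equal(rp$pos_frac, c(1, 0, 0.5, 1))
  # acrocentric: origin is the centromeric end
  acro <- filter_cells(toy_two_cells(), animal = "a1")
  rp2 <- relative_positions(acro)
  f <- acro$foci[acro$foci$sc_rank == 17 & acro$foci$cell_id == "A", ]
  L <- acro$scs$length_um[acro$scs$sc_rank == 17 & acro$scs$cell_id == "A"]
  expect_equal(rp2$pos_frac[rp2$sc_rank == 17 & rp2$cell_id == "A"],
               f$position_um / L)
  # counts conserved: one RelativePosition per focus
  expect_equal(nrow(rp2), nrow(acro$foci))
  # scale-free: shrinking axes and positions together leaves pos_frac fixed
  shrunk <- acro
  shrunk$scs$length_um <- shrunk$scs$length_um * 0.8
  shrunk$scs$centromere_um <- shrunk$scs$centromere_um * 0.8
  shrunk$foci$position_um <- shrunk$foci$position_um * 0.8
  expect_equal(relative_positions(shrunk)$pos_frac, rp2$pos_frac,
               tolerance = 1e-12)
})

test_that("binning uses half-open intervals with a closed last bin", {
  h <- bin_positions(c(0.05, 0.15, 0.15, 0.95), n_bins = 10)
  expect_equal(h$freq[c(1, 2, 10)], c(0.25, 0.5, 0.25))
  expect_equal(sum(h$freq), 1)
  expect_equal(sum(h$count), 4)
  expect_equal(bin_positions(rep(0.95, 7))$freq[10], 1)
  expect_equal(bin_positions(c(0.1999999, 1.0))$count[c(2, 10)], c(1L, 1L))
  set.seed(91)
  u <- bin_positions(stats::runif(1e5))
  expect_true(all(abs(u$freq - 0.1) < 0.01))
  expect_error(bin_positions(numeric(0)), "empty input")
})

test_that("the KS comparison equals the brute-force ECDF gap", {
  set.seed(92)
  for (i in 1:50) {
    a <- stats::runif(sample(5:60, 1))
    b <- stats::rbeta(sample(5:60, 1), 2, 1)
    expect_equal(compare_position_distributions_ks(a, b)$D,
                 ks_stat_brute(a, b), tolerance = 1e-12)
  }
  a <- stats::runif(30)
  self <- compare_position_distributions_ks(a, a)
  expect_equal(self$D, 0)
  expect_equal(self$p_value, 1)
  expect_equal(compare_position_distributions_ks(rep(0.1, 50),
                                                 rep(0.9, 50))$D, 1)
  expect_error(compare_position_distributions_ks(c(0.1, 0.2), a), "n >= 5")
})

test_that("the centromere-effect index tracks the thinning probability", {
  set.seed(93)
  expect_equal(centromere_effect(stats::runif(2e4)), 1, tolerance = 0.05)
  # complete suppression: index 0 by construction
  ds1 <- simulate_dataset(quick_config(n_cells = 100, seed = 94,
                                       centromere_suppression_p = 1))
  expect_equal(centromere_effect(relative_positions(ds1)), 0)
  # partial thinning: index ~ (1-p)/(1 - p*w) from the thinning algebra
  ds2 <- simulate_dataset(quick_config(n_cells = 400, seed = 95,
                                       obligate_co = FALSE,
                                       centromere_suppression_p = 0.5))
  idx <- centromere_effect(relative_positions(ds2))
  expect_equal(idx, 0.5 / (1 - 0.05), tolerance = 0.12)
  expect_error(centromere_effect(numeric(0)), "empty input")
})
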