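test_that("per-cell focus counts sum the SC loads", {
  ds <- toy_two_cells()
  fpc <- foci_per_cell(ds)
  counts <- setNames(fpc$counts$n_foci, fpc$counts$cell_id)
  expect_equal(counts[["A"]], 17L)   # one focus on every SC
  expect_equal(counts[["B"]], 21L)   # 3+2+2+2 + 12*1 + 0
  # conservation: per-SC counts sum to the per-cell count, for every cell
  per_sc <- table(ds$foci$cell_id)
  expect_equal(as.integer(per_sc[fpc$counts$cell_id]), fpc$counts$n_foci)
  expect_error(foci_per_cell(filter_cells(ds, temperature = 99)),
               "empty selection")
})

test_that("summary statistics match hand arithmetic", {
  # three cells carrying 18, 20 and 22 foci: one per SC plus extra second
  # foci on the first (n - 17) SCs
  prof <- gecko_sc_profile()
  mk <- function(id, n) {
    scs <- data.frame(cell_id = id, sc_rank = 1:17,
                      morphology = prof$morphology,
                      length_um = prof$length_um,
                      centromere_um = prof$centromere_frac * prof$length_um,
                      stringsAsFactors = FALSE)
    extra <- n - 17L
    n_per <- rep(1L, 17) + c(rep(1L, extra), rep(0L, 17 - extra))
    foci <- data.frame(cell_id = id, sc_rank = rep(1:17, n_per),
                       focus_index = sequence(n_per),
                       position_um = unlist(lapply(1:17, function(k)
                         seq(0.5, 0.9, length.out = n_per[k]) *
                           prof$length_um[k])),
                       stringsAsFactors = FALSE)
    list(scs = scs, foci = foci)
  }
  parts <- Map(mk, c("c18", "c20", "c22"), c(18L, 20L, 22L))
  cells <- data.frame(cell_id = c("c18", "c20", "c22"), animal_id = "a1",
                      temperature_C = 28, stage = "pachytene",
                      rpa_count = NA_real_, stringsAsFactors = FALSE)
  ds <- meio_dataset(cells, do.call(rbind, lapply(parts, `[[`, "scs")),
                     do.call(rbind, lapply(parts, `[[`, "foci")))
  fpc <- foci_per_cell(ds)
  expect_equal(fpc$mean, 20)
  expect_equal(fpc$sd, 2)
  expect_equal(fpc$n, 3L)
})

test_that("class distribution counts SCs by focus load", {
  ds <- toy_two_cells()
  d <- foci_class_distribution(ds)
  expect_equal(attr(d, "n_scs"), 34L)
  expect_equal(sum(d$freq), 1)
  expect_equal(d$count[d$class == "0"], 1L)
  expect_equal(d$count[d$class == "1"], 29L)
  expect_equal(d$count[d$class == "2"], 3L)
  expect_equal(d$count[d$class == "3"], 1L)
  # obligate-CO simulation: class-0 frequency exactly 0
  sim <- simulate_dataset(quick_config(n_cells = 50, seed = 62))
  d2 <- foci_class_distribution(sim)
  expect_equal(d2$freq[d2$class == "0"], 0)
  # stratified mode returns one distribution per rank
  d3 <- foci_class_distribution(sim, by_rank = TRUE)
  expect_equal(sort(unique(d3$sc_rank)), 1:17)
  for (r in c(1, 17))
    expect_equal(sum(d3$freq[d3$sc_rank == r]), 1)
})

test_that("the Welch t-test matches the hand formula and handles degeneracy", {
  a <- c(20, 21, 22, 23); b <- c(18, 19, 20, 21)
  res <- compare_means_ttest(a, b)
  # hand Welch computation
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- (var(a) / 4 + var(b) / 4)^2 /
    ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p_value, p_hand)

  same <- compare_means_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  const <- compare_means_ttest(c(5, 5, 5), c(5, 5))
  expect_equal(const$p_value, 1)
  expect_error(compare_means_ttest(1, c(1, 2)), "n >= 2")
})

test_that("the class chi-squared test matches the hand 2x2 formula and pools sparse classes", {
  a <- data.frame(class = c("1", "2"), count = c(10, 20))
  b <- data.frame(class = c("1", "2"), count = c(20, 10))
  res <- compare_class_distribution_chisq(a, b)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)  # 4 * (5^2/15)
  expect_equal(res$p_value, stats::pchisq(20 / 3, 1, lower.tail = FALSE))

  ident <- compare_class_distribution_chisq(a, a)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  # sparse top class pools downward, preserving the total count
  a2 <- data.frame(class = c("1", "2", "3", "4+"), count = c(40, 30, 6, 1))
  b2 <- data.frame(class = c("1", "2", "3", "4+"), count = c(35, 30, 4, 2))
  res2 <- compare_class_distribution_chisq(a2, b2)
  expect_equal(sum(res2$table), 77 + 71)
  expect_lt(ncol(res2$table), 4)
  expect_error(compare_class_distribution_chisq(
    data.frame(class = "1", count = 3), data.frame(class = "1", count = 4)),
    "not testable")
})

test_that("a higher simulated CO load shifts the multi-CO classes and is detectable", {
  # extreme-temperature-like (more COs per cell) vs optimum-like load
  hits <- multi_hi <- multi_lo <- logical(12)
  for (r in seq_len(12)) {
    hi <- simulate_dataset(sim_config(n_cells = 40, seed = 700 + r,
                                      intensity_per_um = 0.0147 * 1.18))
    lo <- simulate_dataset(sim_config(n_cells = 40, seed = 800 + r,
                                      intensity_per_um = 0.0147))
    dh <- foci_class_distribution(hi)
    dl <- foci_class_distribution(lo)
    ge2 <- function(d) sum(d$freq[d$class %in% c("2", "3", "4+")])
    multi_hi[r] <- ge2(dh); multi_lo[r] <- ge2(dl)
    hits[r] <- compare_class_distribution_chisq(dh, dl)$p_value < 0.05
  }
  expect_gt(mean(multi_hi > multi_lo), 0.5)
  expect_gt(mean(hits), 0.5)
})
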