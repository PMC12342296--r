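test_that("two-CO distances are harvested only from two-focus SCs", {
  ds <- toy_two_cells()
  # cell B: SCs 2-4 carry exactly two foci at 0.3L and 0.9L
  d <- inter_focus_distances(ds, normalize = TRUE)
  expect_equal(sort(unique(round(d, 9))), 0.6)
  prof <- gecko_sc_profile()
  expect_equal(sort(inter_focus_distances(ds)),
               sort(0.6 * prof$length_um[2:4]))
  # SCs with 1 or 3 foci contribute nothing: 3 two-CO SCs in the toy
  expect_length(d, 3L)
  expect_error(inter_focus_distances(filter_cells(ds, temperature = 99)),
               "empty result")
})

test_that("the gamma ML fit recovers known laws and matches the oracles", {
  set.seed(111)
  x_exp <- stats::rexp(3000, 2)
  f1 <- fit_gamma_ml(x_exp)
  expect_equal(f1$shape, 1, tolerance = 0.1)

  x_g <- stats::rgamma(3000, shape = 8, rate = 16)
  f8 <- fit_gamma_ml(x_g)
  expect_equal(f8$shape, 8, tolerance = 0.1)
  expect_equal(f8$rate, 16, tolerance = 0.1)
  # grid-search ML oracle agreement to grid resolution
  expect_equal(f8$shape, gamma_shape_grid(x_g), tolerance = 0.011)
  # independent library cross-check
  md <- suppressWarnings(MASS::fitdistr(x_g, "gamma"))
  expect_equal(unname(coef(f8)["shape"]), unname(md$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(logLik(f8)[1], md$loglik, tolerance = 1e-6)

  expect_error(fit_gamma_ml(rep(0.5, 100)), "degenerate fit")
  expect_error(fit_gamma_ml(stats::rexp(10)), "insufficient data")
  expect_error(fit_gamma_ml(c(stats::rexp(50), -1)), "positive")
})

test_that("gamma ML agrees with the grid oracle across random samples", {
  set.seed(112)
  for (i in 1:20) {
    shape <- stats::runif(1, 0.8, 15)
    x <- stats::rgamma(sample(50:200, 1), shape = shape, rate = shape)
    fit <- fit_gamma_ml(x)
    expect_equal(fit$shape, gamma_shape_grid(x), tolerance = 0.011)
  }
})

test_that("the 4-arm 2-interval toy reproduces the hand-enumerated CoC", {
  arms <- list(c(0.2, 0.7), 0.2, 0.7, c(0.2, 0.7))
  cc <- coc_curve(arms, n_intervals = 2)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$separation, 0.5)
  expect_equal(cc$coc, 0.5 / 0.5625, tolerance = 1e-12)  # 0.888...
})

test_that("single-CO arms give complete interference (CoC identically 0)", {
  set.seed(113)
  arms <- as.list(stats::runif(400))
  cc <- coc_curve(arms, n_intervals = 20)
  expect_true(all(cc$coc == 0))
})

test_that("Poisson-placed arms give CoC near 1 at every separation", {
  set.seed(114)
  arms <- replicate(3000, simulate_gamma_renewal(1, 2), simplify = FALSE)
  cc <- coc_curve(arms, n_intervals = 20)
  expect_equal(mean(cc$coc), 1, tolerance = 0.05)
  expect_true(all(abs(cc$coc - 1) < 0.35))
})

test_that("the vectorized CoC equals the naive double-loop oracle exactly", {
  set.seed(115)
  for (i in 1:50) {
    n_arms <- sample(5:30, 1)
    n_int <- sample(3:8, 1)
    arms <- replicate(n_arms,
                      stats::runif(stats::rpois(1, 1.5)), simplify = FALSE)
    got <- try(coc_curve(arms, n_intervals = n_int), silent = TRUE)
    ref <- coc_brute(arms, n_int)
    if (inherits(got, "try-error")) {
      expect_equal(nrow(ref), 0L)
    } else {
      expect_equal(got$separation, ref$separation)
      expect_equal(got$coc, ref$coc, tolerance = 1e-12)
      expect_equal(got$n_pairs, as.integer(ref$n_pairs))
    }
  }
})

test_that("interference distance interpolates the first upward crossing", {
  mk <- function(sep, coc) structure(
    data.frame(separation = sep, coc = coc, n_pairs = rep(1L, length(sep))),
    class = c("coc_curve", "data.frame"))
  expect_equal(interference_distance(mk(c(0.5, 0.6), c(0.8, 1.2)))$distance,
               0.55)
  atstart <- interference_distance(mk(c(0.1, 0.2), c(1.3, 0.9)))
  expect_equal(atstart$distance, 0.1)
  never <- interference_distance(mk(c(0.1, 0.5), c(0.2, 0.6)))
  expect_false(never$reached)
  expect_equal(never$distance, 0.5)
  expect_error(interference_distance(mk(numeric(0), numeric(0))),
               "empty curve")
})

test_that("stronger simulated interference deepens and widens the CoC trough", {
  # matched arm ensembles at the same placement intensity; the trough of the
  # CoC curve (depth at short separations, and the distance to half-recovery
  # CoC = 0.5) grows with the interference shape
  set.seed(120)
  wins_depth <- wins_d05 <- 0L
  for (r in 1:5) {
    res <- sapply(c(4, 12), function(nu) {
      arms <- replicate(1800, simulate_gamma_renewal(nu, 1.8),
                        simplify = FALSE)
      cc <- coc_curve(arms, n_intervals = 20)
      c(trough = mean(cc$coc[cc$separation <= 0.25]),
        d05 = interference_distance(cc, threshold = 0.5)$distance)
    })
    wins_depth <- wins_depth + (res["trough", 2] < res["trough", 1])
    wins_d05 <- wins_d05 + (res["d05", 2] > res["d05", 1])
  }
  expect_gt(wins_depth, 2.5)
  expect_gt(wins_d05, 2.5)
})

test_that("a simulated nu = 8 dataset is recovered by the downstream fit", {
  lam <- 20.18 / sum(gecko_sc_profile()$length_um)
  cfg <- sim_config(n_cells = 180, seed = 121, nu = 8,
                    intensity_per_um = lam, centromere_suppression_p = 0)
  ds <- simulate_dataset(cfg)
  fit <- fit_gamma_ml(inter_focus_distances(ds, include_metacentric = FALSE))
  expect_equal(fit$shape, 8, tolerance = 0.15)
})
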