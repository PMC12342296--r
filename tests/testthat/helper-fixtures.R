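# Shared fixtures: tiny hand-built datasets and the calibrated study-like
# simulation conditions used across test files.

# two fully scored pachytene cells: cell A all-acrocentric-like profile with
# one focus per SC; cell B identical lengths, varied focus loads
toy_two_cells <- function() {
  prof <- gecko_sc_profile()
  mk_cell <- function(id, n_foci_per_sc) {
    scs <- data.frame(cell_id = id, sc_rank = 1:17,
                      morphology = prof$morphology,
                      length_um = prof$length_um,
                      centromere_um = prof$centromere_frac * prof$length_um,
                      stringsAsFactors = FALSE)
    foci <- do.call(rbind, lapply(1:17, function(k) {
      n <- n_foci_per_sc[k]
      if (n == 0) return(NULL)
      pos <- seq(0.3, 0.9, length.out = n) * prof$length_um[k]
      data.frame(cell_id = id, sc_rank = k, focus_index = seq_len(n),
                 position_um = pos, stringsAsFactors = FALSE)
    }))
    list(scs = scs, foci = foci)
  }
  a <- mk_cell("A", rep(1L, 17))
  b <- mk_cell("B", c(3L, 2L, 2L, 2L, rep(1L, 12), 0L))
  cells <- data.frame(cell_id = c("A", "B"), animal_id = "a1",
                      temperature_C = 28, stage = "pachytene",
                      rpa_count = NA_real_, stringsAsFactors = FALSE)
  meio_dataset(cells, rbind(a$scs, b$scs), rbind(a$foci, b$foci))
}

# a single metacentric SC for position arithmetic: length 100, centromere 40
toy_metacentric <- function(foci_um) {
  cells <- data.frame(cell_id = "m1", animal_id = "a1", temperature_C = 28,
                      stage = "pachytene", rpa_count = NA_real_,
                      stringsAsFactors = FALSE)
  scs <- data.frame(cell_id = "m1", sc_rank = 1L, morphology = "metacentric",
                    length_um = 100, centromere_um = 40,
                    stringsAsFactors = FALSE)
  foci <- data.frame(cell_id = "m1", sc_rank = 1L,
                     focus_index = seq_along(foci_um),
                     position_um = sort(foci_um), stringsAsFactors = FALSE)
  meio_dataset(cells, scs, foci)
}

# the three temperature conditions the study contrasts, as simulator
# configurations: interference shape, per-cell MLH1 target and axis
# shrinkage relative to the 28 deg C grand mean
study_conditions <- function() {
  list(
    `20` = list(nu = 6.51, target = 22.93, shrinkage = 48.31 / 60.31,
                temperature_C = 20),
    `28` = list(nu = 8.35, target = 20.18, shrinkage = 1,
                temperature_C = 28),
    `30` = list(nu = 7.66, target = 21.86, shrinkage = 48.49 / 60.31,
                temperature_C = 30))
}

calibrated_config <- function(cond, n_cells, seed) {
  cfg <- sim_config(nu = cond$nu, target_mean_foci_per_cell = cond$target,
                    axis_shrinkage = cond$shrinkage,
                    temperature_C = cond$temperature_C,
                    n_cells = n_cells, seed = seed)
  cfg$intensity_per_um <- calibrate_intensity(cond$target, cfg)
  cfg
}

# quick config with a fixed plausible intensity so tests that do not assert
# the calibrated mean skip the calibration step
quick_config <- function(n_cells = 50, seed = 1, ...) {
  sim_config(n_cells = n_cells, seed = seed, intensity_per_um = 0.0147, ...)
}

# brute-force two-sample KS statistic: max ECDF gap over the pooled points
ks_stat_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
}

# naive double-loop CoC oracle over a list of per-arm positions
coc_brute <- function(arms, n_intervals) {
  n <- length(arms)
  occ <- matrix(FALSE, n, n_intervals)
  for (i in seq_len(n)) {
    p <- arms[[i]]
    if (length(p)) occ[i, pmin(floor(p * n_intervals), n_intervals - 1) + 1] <- TRUE
  }
  out <- list()
  for (d in 1:(n_intervals - 1)) {
    vals <- c()
    for (i in 1:(n_intervals - d)) {
      j <- i + d
      fi <- sum(occ[, i]) / n
      fj <- sum(occ[, j]) / n
      if (fi * fj == 0) next
      obs <- sum(occ[, i] & occ[, j]) / n
      vals <- c(vals, obs / (fi * fj))
    }
    if (length(vals))
      out[[length(out) + 1]] <- c(separation = d / n_intervals,
                                  coc = mean(vals), n_pairs = length(vals))
  }
  as.data.frame(do.call(rbind, out))
}

# grid-search ML oracle for the gamma shape (rate profiled at shape/mean)
gamma_shape_grid <- function(x, grid = seq(0.5, 20, by = 0.01)) {
  m <- mean(x)
  ll <- vapply(grid, function(s)
    sum(stats::dgamma(x, shape = s, rate = s / m, log = TRUE)), numeric(1))
  grid[which.max(ll)]
}
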