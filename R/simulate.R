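#' Reference SC length profile of the gecko karyotype
#'
#' The 17-bivalent profile used as the simulator default, anchored to the
#' 28 deg C reference morphometry: large SCs 1-4 (130.5 down to 111.9 µm,
#' linearly interpolated) with SCs 1 and 4 metacentric, and short SCs 5-17
#' decaying geometrically from 80.6 to 17.3 µm. The whole profile is scaled
#' so the grand mean SC length is exactly 60.31 µm. Metacentric centromeres
#' sit at 45% of the axis; acrocentric centromeres define the axis origin.
#'
#' @param grand_mean_um Target mean SC length across the 17 bivalents (µm).
#' @return Data frame with `sc_rank`, `length_um`, `morphology`,
#'   `centromere_frac` (centromere position as a fraction of axis length).
#' @export
gecko_sc_profile <- function(grand_mean_um = 60.31) {
  large <- seq(130.48, 111.86, length.out = 4)
  short <- 80.60 * (17.33 / 80.60)^(seq(0, 12) / 12)
  len <- c(large, short)
  len <- len * (17 * grand_mean_um / sum(len))
  morph <- rep("acrocentric", 17)
  morph[c(1, 4)] <- "metacentric"
  data.frame(sc_rank = 1:17, length_um = len, morphology = morph,
             centromere_frac = ifelse(morph == "metacentric", 0.45, 0),
             stringsAsFactors = FALSE)
}

default_rpa_means <- function() {
  # 28 deg C stage profile; early zygotene is unreported and set between its
  # neighbours (see the methods vignette)
  data.frame(stage = stage_levels(),
             mean = c(105.55, 85, 59.47, 19),
             sd = c(32.57, 30, 25.14, 30.35),
             stringsAsFactors = FALSE)
}

#' Simulator configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults are the
#' 28 deg C study conditions: interference shape `nu = 8.35`, per-cell MLH1
#' target 20.18 foci, obligate CO on, centromere suppression within 10% of
#' the arm with probability 0.9, and the [gecko_sc_profile()] axis profile
#' (grand mean 60.31 µm).
#'
#' @param nu Gamma shape of the inter-CO gap law (interference strength);
#'   `nu = 1` is the interference-free Poisson limit. Values below 1
#'   (clustering) are rejected.
#' @param target_mean_foci_per_cell Per-cell mean MLH1 focus count the
#'   intensity is calibrated to; ignored when `intensity_per_um` is given.
#' @param intensity_per_um Expected COs per µm of axis before obligate-CO
#'   conditioning and centromere suppression; `NULL` (default) means
#'   calibrate from `target_mean_foci_per_cell` at simulation time.
#' @param sc_length_profile_um SC profile data frame as from
#'   [gecko_sc_profile()]: exactly 17 rows with `length_um`, `morphology`,
#'   `centromere_frac`.
#' @param axis_shrinkage Multiplier on every SC length; models the
#'   temperature-induced axis shortening (e.g. 48.31/60.31 for a 20 deg
#'   C-like profile).
#' @param obligate_co Resample each SC until it carries at least one focus
#'   (chiasma assurance).
#' @param centromere_radius_frac Half-width of the pericentromeric
#'   suppression zone, as a fraction of arm length measured from the
#'   centromere; in `[0, 0.5]`.
#' @param centromere_suppression_p Probability that a focus falling inside
#'   the suppression zone is removed (independent thinning).
#' @param cell_length_cv,sc_length_cv Coefficients of variation of the
#'   lognormal multiplicative noise applied per cell and per SC to axis
#'   lengths (mean-one noise, so expected lengths follow the profile).
#' @param rpa_stage_means Data frame `stage`, `mean`, `sd` for RPA focus
#'   counts (negative-binomial moments) per prophase-I stage.
#' @param n_cells Number of pachytene cells to simulate.
#' @param temperature_C Condition label attached to the simulated cells.
#' @param animal_ids Animal identifiers cells are cycled over.
#' @param seed Integer seed; all simulator output is reproducible from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(nu = 8.35,
                       target_mean_foci_per_cell = 20.18,
                       intensity_per_um = NULL,
                       sc_length_profile_um = gecko_sc_profile(),
                       axis_shrinkage = 1,
                       obligate_co = TRUE,
                       centromere_radius_frac = 0.1,
                       centromere_suppression_p = 0.9,
                       cell_length_cv = 0.08,
                       sc_length_cv = 0.04,
                       rpa_stage_means = default_rpa_means(),
                       n_cells = 100,
                       temperature_C = 28,
                       animal_ids = c("a1", "a2"),
                       seed = 1L) {
  if (!is_pos_scalar(nu) || nu < 1)
    stopf("unsupported parameter: nu must be a finite scalar >= 1 (got %s)",
          format(nu))
  prof <- sc_length_profile_um
  if (!is.data.frame(prof) || nrow(prof) != 17 ||
      !all(c("length_um", "morphology", "centromere_frac") %in% names(prof)))
    stopf("sc_length_profile_um must have 17 rows with length_um, morphology, centromere_frac")
  if (any(prof$length_um <= 0)) stopf("SC profile lengths must be positive")
  if (!all(prof$morphology %in% morphology_levels()))
    stopf("unknown morphology in SC profile")
  if (!is_pos_scalar(axis_shrinkage)) stopf("axis_shrinkage must be positive")
  if (centromere_radius_frac < 0 || centromere_radius_frac > 0.5)
    stopf("centromere_radius_frac must lie in [0, 0.5]")
  if (centromere_suppression_p < 0 || centromere_suppression_p > 1)
    stopf("centromere_suppression_p must lie in [0, 1]")
  if (!is.null(intensity_per_um) && !is_pos_scalar(intensity_per_um))
    stopf("intensity_per_um must be positive")
  if (is.null(intensity_per_um) &&
      !is_pos_scalar(target_mean_foci_per_cell))
    stopf("calibration error: target_mean_foci_per_cell must be positive")
  structure(list(
    nu = nu, target_mean_foci_per_cell = target_mean_foci_per_cell,
    intensity_per_um = intensity_per_um,
    sc_length_profile_um = prof, axis_shrinkage = axis_shrinkage,
    obligate_co = isTRUE(obligate_co),
    centromere_radius_frac = centromere_radius_frac,
    centromere_suppression_p = centromere_suppression_p,
    cell_length_cv = cell_length_cv, sc_length_cv = sc_length_cv,
    rpa_stage_means = rpa_stage_means,
    n_cells = as.integer(n_cells), temperature_C = temperature_C,
    animal_ids = animal_ids, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate one realisation of a stationary gamma-renewal process
#'
#' Event positions on `[0, length]` with inter-event gaps i.i.d.
#' Gamma(shape `nu`, rate `nu * lambda`), where `lambda =
#' mean_events / length`, so the gap mean is `1/lambda` and the expected
#' event count on the interval is `mean_events` for every `nu`
#' (stationarity). The first event is drawn from the equilibrium (forward
#' recurrence) distribution, sampled as U * G with U uniform and G the
#' length-biased gap Gamma(`nu + 1`, `nu * lambda`); this avoids the
#' artefactual event enrichment at the origin an origin-anchored renewal
#' would create.
#'
#' @param nu Gamma shape (>= 1); `nu = 1` gives a homogeneous Poisson
#'   process.
#' @param mean_events Expected number of events on the interval (> 0).
#' @param length Interval length (default 1, i.e. positions are fractions).
#' @return Sorted numeric vector of event positions in `[0, length]`
#'   (possibly empty).
#' @export
simulate_gamma_renewal <- function(nu, mean_events, length = 1) {
  if (!is_pos_scalar(nu) || nu < 1)
    stopf("unsupported parameter: nu must be >= 1")
  if (!is_pos_scalar(mean_events)) stopf("mean_events must be positive")
  if (!is_pos_scalar(length)) stopf("length must be positive")
  rate <- nu * mean_events / length
  x <- stats::runif(1) * stats::rgamma(1, shape = nu + 1, rate = rate)
  out <- numeric(0)
  while (x <= length) {
    out <- c(out, x)
    x <- x + stats::rgamma(1, shape = nu, rate = rate)
  }
  out
}

# one arm: renewal placement + centromere thinning in [0, radius] arm fractions
# (arm coordinate 0 = centromere end for suppression purposes)
sim_arm <- function(nu, lambda_per_um, arm_len, radius_frac, suppr_p,
                    centromere_at_origin = TRUE) {
  if (arm_len <= 0) return(numeric(0))
  pos <- simulate_gamma_renewal(nu, mean_events = lambda_per_um * arm_len,
                                length = arm_len)
  if (length(pos) && suppr_p > 0 && radius_frac > 0) {
    d_cen <- if (centromere_at_origin) pos else arm_len - pos
    hit <- d_cen < radius_frac * arm_len
    kill <- hit & stats::runif(length(pos)) < suppr_p
    pos <- pos[!kill]
  }
  pos
}

#' Calibrate the CO intensity to a per-cell focus target
#'
#' Finds the per-µm placement intensity such that the simulated mean MLH1
#' focus count per cell matches `target` — accounting for obligate-CO
#' conditioning and centromere suppression when enabled — by bisection
#' against batched simulation at a fixed calibration seed.
#'
#' @param target Target mean foci per cell (> 0).
#' @param config A [sim_config()]; its `intensity_per_um` is ignored.
#' @param n_cells Cells per bisection evaluation.
#' @param tol Absolute tolerance on the evaluated mean.
#' @param max_iter Bisection iteration cap.
#' @return Intensity in expected COs per µm.
#' @export
calibrate_intensity <- function(target, config, n_cells = 400, tol = 0.05,
                                max_iter = 12) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_pos_scalar(target))
    stopf("calibration error: target must be positive")
  key <- paste(format(c(config$nu, config$axis_shrinkage,
                        config$centromere_radius_frac,
                        config$centromere_suppression_p,
                        config$cell_length_cv, config$sc_length_cv,
                        sum(config$sc_length_profile_um$length_um),
                        target, n_cells, tol), digits = 12),
               config$obligate_co, collapse = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  total_len <- sum(config$sc_length_profile_um$length_um) * config$axis_shrinkage
  cal_seed <- derive_seed(config$seed, 271828L)
  eval_mean <- function(lambda) {
    cfg <- config
    cfg$intensity_per_um <- lambda
    set.seed(cal_seed)
    mean(vapply(seq_len(n_cells),
                function(i) nrow(sim_cell_tables(cfg, paste0("cal", i), "a")$foci),
                numeric(1)))
  }
  lo <- target / total_len / 5
  hi <- target / total_len * 5
  f_lo <- eval_mean(lo); f_hi <- eval_mean(hi)
  if (f_lo > target + tol || f_hi < target - tol)
    stopf("calibration error: target %.3f foci/cell unreachable in intensity bracket [%.3g, %.3g] (means %.2f-%.2f)",
          target, lo, hi, f_lo, f_hi)
  lambda <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    lambda <- (lo + hi) / 2
    f <- eval_mean(lambda)
    if (abs(f - target) < tol) break
    if (f < target) lo <- lambda else hi <- lambda
  }
  .calibration_cache[[key]] <- lambda
  lambda
}

.calibration_cache <- new.env(parent = emptyenv())

# simulate the scs/foci tables of one cell; consumes the current RNG stream
sim_cell_tables <- function(config, cell_id, animal_id) {
  prof <- config$sc_length_profile_um
  lambda <- config$intensity_per_um
  if (is.null(lambda))
    stopf("intensity_per_um not set; run calibrate_intensity() or use simulate_dataset()")
  cv2sdlog <- function(cv) sqrt(log(1 + cv^2))
  s_cell <- cv2sdlog(config$cell_length_cv)
  s_sc <- cv2sdlog(config$sc_length_cv)
  cell_f <- stats::rlnorm(1, -s_cell^2 / 2, s_cell)
  sc_f <- stats::rlnorm(17, -s_sc^2 / 2, s_sc)
  len <- prof$length_um * config$axis_shrinkage * cell_f * sc_f
  cen <- prof$centromere_frac * len
  scs <- data.frame(cell_id = cell_id, sc_rank = prof$sc_rank,
                    morphology = prof$morphology, length_um = len,
                    centromere_um = cen, stringsAsFactors = FALSE)
  pos_by_sc <- vector("list", 17)
  for (k in 1:17) {
    meta <- prof$morphology[k] == "metacentric"
    draw_sc <- function() {
      if (meta) {
        # arms are independent renewal processes; p-arm stored as c - x
        p <- sim_arm(config$nu, lambda, cen[k], config$centromere_radius_frac,
                     config$centromere_suppression_p, centromere_at_origin = FALSE)
        q <- sim_arm(config$nu, lambda, len[k] - cen[k],
                     config$centromere_radius_frac,
                     config$centromere_suppression_p, centromere_at_origin = TRUE)
        sort(c(p, cen[k] + q))
      } else {
        sort(sim_arm(config$nu, lambda, len[k], config$centromere_radius_frac,
                     config$centromere_suppression_p, centromere_at_origin = TRUE))
      }
    }
    pos <- draw_sc()
    if (config$obligate_co) {
      tries <- 1L
      while (!length(pos)) {
        if (tries >= 10000L)
          stopf("obligate-CO resampling failed after 10000 attempts on SC %d", k)
        pos <- draw_sc()
        tries <- tries + 1L
      }
    }
    pos_by_sc[[k]] <- pos
  }
  n_per_sc <- lengths(pos_by_sc)
  foci <- data.frame(
    cell_id = rep(cell_id, sum(n_per_sc)),
    sc_rank = rep(prof$sc_rank, n_per_sc),
    focus_index = sequence(n_per_sc),
    position_um = unlist(pos_by_sc, use.names = FALSE) %||% numeric(0),
    stringsAsFactors = FALSE)
  list(scs = scs, foci = foci)
}

#' Simulate a pachytene cell
#'
#' Draws one fully scored cell (17 SCs with MLH1 focus positions) under a
#' [sim_config()], consuming the current RNG stream. Obligate-CO
#' conditioning resamples a whole SC (placement plus centromere thinning)
#' until at least one focus survives, so conditioning and suppression are
#' jointly respected.
#'
#' @param config A [sim_config()] with `intensity_per_um` set.
#' @param cell_id,animal_id Identifiers for the simulated cell.
#' @return A [meio_dataset()] holding the single cell.
#' @export
simulate_cell <- function(config, cell_id = "cell_1", animal_id = "a1") {
  stopifnot(inherits(config, "sim_config"))
  tabs <- sim_cell_tables(config, cell_id, animal_id)
  cells <- data.frame(cell_id = cell_id, animal_id = animal_id,
                      temperature_C = config$temperature_C,
                      stage = "pachytene", rpa_count = NA_real_,
                      stringsAsFactors = FALSE)
  meio_dataset(cells, tabs$scs, tabs$foci)
}

#' Simulate a pachytene dataset
#'
#' `n_cells` i.i.d. cells under the configuration; fully reproducible from
#' `config$seed`. If `intensity_per_um` is unset it is first calibrated to
#' `target_mean_foci_per_cell` via [calibrate_intensity()] (itself
#' seed-deterministic).
#'
#' @param config A [sim_config()].
#' @return A validated [meio_dataset()]; the resolved intensity and the
#'   configuration are recorded in `metadata`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$intensity_per_um))
    config$intensity_per_um <-
      calibrate_intensity(config$target_mean_foci_per_cell, config)
  set.seed(config$seed)
  ids <- sprintf("c%04d", seq_len(config$n_cells))
  animals <- rep_len(config$animal_ids, config$n_cells)
  scs <- vector("list", config$n_cells)
  foci <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    tabs <- sim_cell_tables(config, ids[i], animals[i])
    scs[[i]] <- tabs$scs
    foci[[i]] <- tabs$foci
  }
  cells <- data.frame(cell_id = ids, animal_id = animals,
                      temperature_C = config$temperature_C,
                      stage = "pachytene", rpa_count = NA_real_,
                      stringsAsFactors = FALSE)
  meio_dataset(cells, do.call(rbind, scs), do.call(rbind, foci),
               metadata = list(simulated = TRUE,
                               intensity_per_um = config$intensity_per_um,
                               nu = config$nu, seed = config$seed,
                               temperatures = config$temperature_C))
}

#' Simulate stage-labelled RPA focus counts
#'
#' Counts are drawn per prophase-I stage from a negative binomial whose
#' size parameter is solved from the configured (mean, sd) moments:
#' `size = mean^2 / (sd^2 - mean)`. When `sd^2 <= mean` the Poisson limit
#' (dispersion to infinity) is used.
#'
#' @param config A [sim_config()]; stage moments come from
#'   `config$rpa_stage_means`.
#' @param n_cells_per_stage Cells per stage (recycled across stages).
#' @return A [meio_dataset()] of cells with `rpa_count` set and no SC data.
#' @export
simulate_rpa_counts <- function(config, n_cells_per_stage = 50) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$rpa_stage_means
  if (any(m$mean <= 0)) stopf("parameter error: RPA stage means must be positive")
  set.seed(derive_seed(config$seed, 104729L))
  n_per <- rep_len(n_cells_per_stage, nrow(m))
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    mu <- m$mean[i]; v <- m$sd[i]^2
    counts <- if (v > mu) {
      stats::rnbinom(n_per[i], size = mu^2 / (v - mu), mu = mu)
    } else {
      stats::rpois(n_per[i], mu)
    }
    out[[i]] <- data.frame(
      cell_id = sprintf("rpa_%s_%03d", m$stage[i], seq_len(n_per[i])),
      animal_id = rep_len(config$animal_ids, n_per[i]),
      temperature_C = config$temperature_C, stage = m$stage[i],
      rpa_count = as.numeric(counts), stringsAsFactors = FALSE)
  }
  meio_dataset(do.call(rbind, out),
               metadata = list(simulated = TRUE, seed = config$seed,
                               temperatures = config$temperature_C))
}
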