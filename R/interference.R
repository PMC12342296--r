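#' Distances between the two MLH1 foci of two-CO SCs
#'
#' For every SC bearing exactly two foci, the distance between them. Only
#' two-focus SCs contribute (consecutive gaps of SCs with three or more
#' foci are not harvested). Distances default to µm: under a per-µm
#' renewal placement the gap law is common across SCs in µm, so raw
#' distances pool without mixing scales; `normalize = TRUE` divides by SC
#' length for the arm-relative variant.
#'
#' @inheritParams foci_per_cell
#' @param normalize Divide each distance by its SC's axis length.
#' @param include_metacentric Keep two-CO metacentric SCs, measuring the
#'   distance within the whole SC even when it spans the centromere
#'   (default). Set `FALSE` to restrict the harvest to acrocentric SCs:
#'   cross-centromere distances join two independently placed arm
#'   processes, carry no interference signal, and attenuate the fitted
#'   shape, so recovery studies exclude them.
#' @return Numeric vector of distances (µm, or fractions when normalized).
#' @export
inter_focus_distances <- function(dataset, temperature = NULL, animal = NULL,
                                  normalize = FALSE,
                                  include_metacentric = TRUE) {
  ds <- filter_cells(dataset, temperature = temperature, stage = "pachytene",
                     animal = animal)
  if (!include_metacentric) {
    keep <- ds$scs$morphology == "acrocentric"
    drop_key <- paste(ds$scs$cell_id, ds$scs$sc_rank)[!keep]
    ds$scs <- ds$scs[keep, , drop = FALSE]
    ds$foci <- ds$foci[!paste(ds$foci$cell_id, ds$foci$sc_rank) %in% drop_key,
                       , drop = FALSE]
  }
  if (!nrow(ds$foci)) stopf("empty result: no foci in selection")
  f <- ds$foci[order(ds$foci$cell_id, ds$foci$sc_rank, ds$foci$focus_index), ]
  key <- paste(f$cell_id, f$sc_rank)
  two <- names(which(table(key) == 2L))
  if (!length(two)) stopf("empty result: no SCs with exactly two foci")
  f <- f[key %in% two, ]
  pos <- split(f$position_um, paste(f$cell_id, f$sc_rank))
  d <- vapply(pos, function(p) abs(diff(p)), numeric(1))
  if (normalize) {
    s <- ds$scs
    len <- s$length_um[match(names(d), paste(s$cell_id, s$sc_rank))]
    d <- d / len
  }
  unname(d)
}

#' Maximum-likelihood gamma fit to inter-focus distances
#'
#' Fits a two-parameter gamma distribution by maximum likelihood. The
#' shape is the interference parameter: 1 is the interference-free null,
#' larger values mean more evenly spaced COs. The shape solves
#' `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))` (Newton
#' iteration from a moment start, tolerance 1e-8 on the gradient, with a
#' bisection fallback); the rate is `shape / mean(x)`. A Wald confidence
#' interval for the shape is derived from the profile observed
#' information.
#'
#' @param distances Positive distances (any consistent unit).
#' @param min_n Minimum sample size accepted (default 30).
#' @param conf_level Confidence level for the shape interval.
#' @return Object of class `gamma_fit`: `shape`, `rate`, `loglik`, `n`,
#'   `shape_ci`. Methods: `print`, `summary`, `coef`, `logLik`.
#' @export
fit_gamma_ml <- function(distances, min_n = 30, conf_level = 0.95) {
  x <- distances
  if (any(!is.finite(x)) || any(x <= 0)) stopf("distances must be positive and finite")
  if (length(x) < min_n)
    stopf("insufficient data: n = %d below the fit floor of %d", length(x), min_n)
  if (stats::sd(x) == 0) stopf("degenerate fit: all distances equal")
  m <- mean(x)
  c0 <- log(m) - mean(log(x))   # always > 0 for non-constant data
  s <- m^2 / stats::var(x)      # moment start
  g <- function(s) log(s) - digamma(s) - c0
  for (i in 1:100) {
    step <- g(s) / (1 / s - trigamma(s))
    s_new <- s - step
    if (!is.finite(s_new) || s_new <= 0) break
    s <- s_new
    if (abs(g(s)) < 1e-8) break
  }
  if (abs(g(s)) >= 1e-8)
    s <- stats::uniroot(g, lower = 1e-6, upper = 1e6, tol = 1e-12)$root
  rate <- s / m
  loglik <- sum(stats::dgamma(x, shape = s, rate = rate, log = TRUE))
  # profile information for the shape: I(s) = n (trigamma(s) - 1/s)
  se <- sqrt(1 / (length(x) * (trigamma(s) - 1 / s)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(shape = s, rate = rate, loglik = loglik, n = length(x),
                 shape_se = se, shape_ci = c(max(s - z * se, 0), s + z * se),
                 conf_level = conf_level),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("Gamma fit (ML): shape = %.3f (%.0f%% CI %.3f-%.3f), rate = %.4g, n = %d\n",
              x$shape, 100 * x$conf_level, x$shape_ci[1], x$shape_ci[2],
              x$rate, x$n))
  invisible(x)
}

#' @export
coef.gamma_fit <- function(object, ...) {
  c(shape = object$shape, rate = object$rate)
}

#' @export
logLik.gamma_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
summary.gamma_fit <- function(object, ...) {
  cat("Maximum-likelihood gamma fit to inter-crossover distances\n")
  print(object)
  cat(sprintf("  mean distance = %.4g, CV = %.3f (shape^-1/2)\n",
              object$shape / object$rate, object$shape^-0.5))
  cat(sprintf("  log-likelihood = %.2f\n", object$loglik))
  invisible(object)
}

# per-arm relative positions for CoC work: list of numeric vectors, one per
# arm (acrocentric SC = one arm; metacentric p and q arms separately),
# including arms carrying no focus
arm_position_list <- function(dataset, temperature = NULL, animal = NULL) {
  ds <- filter_cells(dataset, temperature = temperature, stage = "pachytene",
                     animal = animal)
  if (!nrow(ds$scs)) stopf("no arms: empty selection")
  rp <- if (nrow(ds$foci)) relative_positions(ds) else
    data.frame(cell_id = character(), sc_rank = integer(),
               arm = character(), pos_frac = numeric())
  s <- ds$scs
  arms <- rbind(
    data.frame(cell_id = s$cell_id, sc_rank = s$sc_rank,
               arm = ifelse(s$morphology == "metacentric", "p", "single"),
               stringsAsFactors = FALSE),
    data.frame(cell_id = s$cell_id[s$morphology == "metacentric"],
               sc_rank = s$sc_rank[s$morphology == "metacentric"],
               arm = "q", stringsAsFactors = FALSE))
  akey <- paste(arms$cell_id, arms$sc_rank, arms$arm)
  fkey <- paste(rp$cell_id, rp$sc_rank, rp$arm)
  out <- split(rp$pos_frac, factor(fkey, levels = akey))
  names(out) <- akey
  out
}

#' Coefficient-of-coincidence curve
#'
#' Each chromosome arm is scaled to its full length and divided into
#' `n_intervals` equal segments. Interval occupancy is binary (an arm
#' either has at least one CO in a segment or not). For every segment pair
#' (i < j) the observed frequency of arms with a CO in both segments is
#' divided by the product of the single-segment frequencies (the expected
#' double-CO frequency under independence); the CoC at separation
#' `d = (j - i) / n_intervals` is the average of the pair ratios at that
#' separation. Pairs with zero expected frequency are excluded and counted
#' in the diagnostics.
#'
#' @param x A [meio_dataset()] of ranked pachytene cells, or a list of
#'   per-arm relative position vectors in `[0, 1]` (arms without COs are
#'   empty vectors).
#' @param temperature,animal Condition filters (dataset input only).
#' @param n_intervals Segments per arm (default 20).
#' @param ... Passed between methods.
#' @return Object of class `coc_curve`: data.frame `separation`, `coc`,
#'   `n_pairs`; attributes `n_intervals`, `n_arms`, `n_excluded_pairs`.
#' @export
coc_curve <- function(x, ...) UseMethod("coc_curve")

#' @rdname coc_curve
#' @export
coc_curve.meio_dataset <- function(x, temperature = NULL, animal = NULL,
                                   n_intervals = 20, ...) {
  coc_curve(arm_position_list(x, temperature, animal),
            n_intervals = n_intervals)
}

#' @rdname coc_curve
#' @export
coc_curve.list <- function(x, n_intervals = 20, ...) {
  n_arms <- length(x)
  if (!n_arms) stopf("no arms supplied")
  occ <- matrix(0L, n_arms, n_intervals)
  for (i in seq_len(n_arms)) {
    p <- x[[i]]
    if (length(p)) {
      if (any(p < 0 | p > 1)) stopf("arm positions outside [0, 1]")
      occ[i, unique(pmin(floor(p * n_intervals), n_intervals - 1L) + 1L)] <- 1L
    }
  }
  f <- colMeans(occ)
  both <- crossprod(occ) / n_arms          # observed joint frequencies
  expd <- outer(f, f)
  seps <- integer(0); cocs <- numeric(0); npairs <- integer(0)
  n_excluded <- 0L
  for (d in seq_len(n_intervals - 1L)) {
    i <- seq_len(n_intervals - d)
    j <- i + d
    e <- expd[cbind(i, j)]
    o <- both[cbind(i, j)]
    ok <- e > 0
    n_excluded <- n_excluded + sum(!ok)
    if (!any(ok)) next
    seps <- c(seps, d)
    cocs <- c(cocs, mean(o[ok] / e[ok]))
    npairs <- c(npairs, sum(ok))
  }
  if (!length(seps)) stopf("all segment pairs degenerate (no expected doubles)")
  structure(data.frame(separation = seps / n_intervals, coc = cocs,
                       n_pairs = npairs),
            class = c("coc_curve", "data.frame"),
            n_intervals = n_intervals, n_arms = n_arms,
            n_excluded_pairs = n_excluded)
}

#' @export
print.coc_curve <- function(x, ...) {
  cat(sprintf("CoC curve: %d arms, %d intervals, %d separations (mean CoC %.3f)\n",
              attr(x, "n_arms"), attr(x, "n_intervals"), nrow(x),
              mean(x$coc)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.coc_curve <- function(x, ...) {
  graphics::plot(x$separation, x$coc, type = "b", pch = 16,
                 xlab = "Inter-interval distance (fraction of arm)",
                 ylab = "Coefficient of coincidence", ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}

#' Interference distance of a CoC curve
#'
#' The smallest inter-interval separation at which the CoC first reaches
#' `threshold` (default 1, i.e. where interference vanishes), located by
#' linear interpolation between adjacent curve points with no smoothing.
#' If the curve never reaches the threshold the maximum separation is
#' returned with `reached = FALSE`.
#'
#' @param curve A [coc_curve()].
#' @param threshold CoC level defining "no interference".
#' @return List with `distance` (separation fraction), `reached` (logical).
#' @export
interference_distance <- function(curve, threshold = 1) {
  if (!nrow(curve)) stopf("empty curve")
  s <- curve$separation; v <- curve$coc
  if (v[1] >= threshold) return(list(distance = s[1], reached = TRUE))
  above <- which(v >= threshold)
  if (!length(above)) return(list(distance = s[length(s)], reached = FALSE))
  k <- above[1]
  d <- s[k - 1] + (threshold - v[k - 1]) * (s[k] - s[k - 1]) / (v[k] - v[k - 1])
  list(distance = d, reached = TRUE)
}
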