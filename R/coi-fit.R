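#' Fit the crossover-interference model to a cytological dataset
#'
#' The package's central estimator. For one condition it
#'
#' 1. harvests the distances between the two MLH1 foci of two-CO SCs
#'    ([inter_focus_distances()]) and fits the gamma interference model by
#'    maximum likelihood ([fit_gamma_ml()]) — the fitted shape is the
#'    interference parameter (1 = no interference);
#' 2. computes the coefficient-of-coincidence curve over
#'    `n_intervals`-segment arms ([coc_curve()]) and the interference
#'    distance where the CoC first reaches 1
#'    ([interference_distance()]);
#' 3. summarises the per-cell MLH1 focus counts ([foci_per_cell()]).
#'
#' @param dataset A [meio_dataset()] of pachytene cells (ranked or not;
#'   ranking is not required for interference quantities).
#' @param temperature,animal Optional condition filters.
#' @param n_intervals Segments per arm for the CoC curve.
#' @param normalize Fit the gamma model to length-normalized distances
#'   instead of µm (see [inter_focus_distances()]).
#' @param include_metacentric Include two-CO metacentric SCs in the gamma
#'   harvest (see [inter_focus_distances()]).
#' @param min_n Minimum number of two-CO distances required for the fit.
#' @return Object of class `coi_fit` with components `gamma`
#'   (a [fit_gamma_ml()] result), `coc` (a [coc_curve()]),
#'   `interference_distance`, `foci` (a [foci_per_cell()] summary),
#'   `normalize`, `condition`. Methods: `print`, `summary`, `coef`,
#'   `logLik`, `plot`, `simulate`.
#' @examples
#' cfg <- sim_config(nu = 8.35, n_cells = 60, seed = 42,
#'                   intensity_per_um = 0.0197)
#' fit <- coi_fit(simulate_dataset(cfg))
#' fit
#' coef(fit)
#' @export
coi_fit <- function(dataset, temperature = NULL, animal = NULL,
                    n_intervals = 20, normalize = FALSE,
                    include_metacentric = TRUE, min_n = 30) {
  d <- inter_focus_distances(dataset, temperature, animal,
                             normalize = normalize,
                             include_metacentric = include_metacentric)
  gfit <- fit_gamma_ml(d, min_n = min_n)
  curve <- coc_curve(dataset, temperature = temperature, animal = animal,
                     n_intervals = n_intervals)
  idist <- interference_distance(curve)
  foci <- foci_per_cell(dataset, temperature, animal)
  structure(list(gamma = gfit, coc = curve, interference_distance = idist,
                 foci = foci, distances = d, normalize = normalize,
                 condition = temperature),
            class = "coi_fit")
}

#' @export
print.coi_fit <- function(x, ...) {
  cond <- if (is.null(x$condition)) "all conditions" else
    paste0(paste(x$condition, collapse = "/"), " deg C")
  cat(sprintf("Crossover-interference fit (%s)\n", cond))
  cat(sprintf("  MLH1 foci/cell: %.2f +/- %.2f (n = %d cells)\n",
              x$foci$mean, x$foci$sd, x$foci$n))
  cat(sprintf("  interference shape: %.2f (95%% CI %.2f-%.2f), n = %d two-CO SCs\n",
              x$gamma$shape, x$gamma$shape_ci[1], x$gamma$shape_ci[2],
              x$gamma$n))
  cat(sprintf("  interference distance (CoC = 1): %.2f of arm length%s\n",
              x$interference_distance$distance,
              if (x$interference_distance$reached) "" else " (not reached)"))
  invisible(x)
}

#' @export
summary.coi_fit <- function(object, ...) {
  print(object)
  cat("\nGamma component:\n")
  summary(object$gamma)
  cat(sprintf("\nCoC curve: %d separations over %d arms (mean CoC %.3f)\n",
              nrow(object$coc), attr(object$coc, "n_arms"),
              mean(object$coc$coc)))
  invisible(object)
}

#' @export
coef.coi_fit <- function(object, ...) coef(object$gamma)

#' @export
logLik.coi_fit <- function(object, ...) logLik(object$gamma)

#' @export
plot.coi_fit <- function(x, which = c("coc", "gamma"), ...) {
  which <- match.arg(which)
  if (which == "coc") {
    plot(x$coc, main = "Coefficient of coincidence", ...)
  } else {
    d <- x$distances
    graphics::hist(d, freq = FALSE, breaks = "FD",
                   xlab = if (x$normalize) "Inter-focus distance (fraction of SC)"
                          else "Inter-focus distance (um)",
                   main = "Two-CO inter-focus distances", ...)
    xs <- seq(min(d), max(d), length.out = 200)
    graphics::lines(xs, stats::dgamma(xs, x$gamma$shape, x$gamma$rate),
                    col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Simulate datasets from a fitted interference model
#'
#' Generates synthetic pachytene datasets whose gamma interference shape
#' equals the fitted shape and whose placement intensity is calibrated to
#' the observed per-cell MLH1 mean, so simulated data mimic the condition
#' the model was fitted to.
#'
#' @param object A [coi_fit()].
#' @param nsim Number of datasets.
#' @param seed Integer seed (required for reproducibility; defaults to 1).
#' @param n_cells Cells per simulated dataset (defaults to the fitted
#'   cell count).
#' @param ... Further arguments passed to [sim_config()].
#' @return A list of `nsim` [meio_dataset()] objects.
#' @export
simulate.coi_fit <- function(object, nsim = 1, seed = 1L, n_cells = NULL, ...) {
  n_cells <- n_cells %||% object$foci$n
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    cfg <- sim_config(nu = max(1, object$gamma$shape),
                      target_mean_foci_per_cell = object$foci$mean,
                      n_cells = n_cells,
                      seed = derive_seed(seed, i), ...)
    out[[i]] <- simulate_dataset(cfg)
  }
  if (nsim == 1) out[[1]] else out
}
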