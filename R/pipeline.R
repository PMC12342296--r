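#' Pipeline run configuration
#'
#' Describes a simulate-then-analyse (or load-then-analyse) run. Exactly
#' one of `input` (a CSV dataset directory) or `sim` (arguments for
#' [sim_config()]) must be given.
#'
#' @param input Path to a dataset directory readable by
#'   [read_meio_dataset()], or `NULL`.
#' @param sim Named list of [sim_config()] arguments, or `NULL`.
#' @param analyses Character subset of
#'   `c("cofreq", "positions", "interference", "rpa")`.
#' @param out_dir Output directory for the table bundle.
#' @param seed Global seed; fanned out to per-stage substreams.
#' @param path YAML file to read the configuration from (all other
#'   arguments then serve as defaults).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, sim = NULL,
                       analyses = c("cofreq", "positions", "interference", "rpa"),
                       out_dir = "coimeio_out", seed = 1L, path = NULL) {
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    input <- y$input %||% input
    sim <- y$sim %||% sim
    analyses <- y$analyses %||% analyses
    out_dir <- y$out_dir %||% out_dir
    seed <- y$seed %||% seed
  }
  if (is.null(input) == is.null(sim))
    stopf("exactly one of `input` or `sim` must be set")
  bad <- setdiff(analyses, c("cofreq", "positions", "interference", "rpa"))
  if (length(bad)) stopf("unknown analysis toggle(s): %s", paste(bad, collapse = ", "))
  structure(list(input = input, sim = sim, analyses = analyses,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline
#'
#' Simulates or loads a dataset, runs the toggled analyses in dependency
#' order, and writes one tidy CSV per result into `out_dir`. Every table
#' carries `config_hash` and `seed` columns, so identical configurations
#' produce byte-identical bundles.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the dataset, the per-analysis results
#'   and the manifest (files written, config hash, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory: %s", out)
  dataset <- if (!is.null(config$input)) {
    read_meio_dataset(config$input, "csv")
  } else {
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% derive_seed(config$seed, 1L)
    if (!is.null(sim_args$sc_length_profile_um) &&
        !is.data.frame(sim_args$sc_length_profile_um))
      sim_args$sc_length_profile_um <-
        as.data.frame(sim_args$sc_length_profile_um)
    simulate_dataset(do.call(sim_config, sim_args))
  }
  stamp <- function(tab) {
    tab$config_hash <- hash
    tab$seed <- config$seed
    tab
  }
  emit <- function(tab, file) {
    utils::write.csv(stamp(tab), file.path(out, file), row.names = FALSE)
    file
  }
  results <- list()
  files <- character(0)
  wrap_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  has_pachytene <- any(dataset$cells$stage == "pachytene" &
                         dataset$cells$cell_id %in% dataset$scs$cell_id)
  if ("cofreq" %in% config$analyses && has_pachytene) {
    wrap_stage("cofreq", {
      fpc <- foci_per_cell(dataset)
      results$cofreq <- fpc
      files <- c(files, emit(data.frame(mean_foci = fpc$mean, sd_foci = fpc$sd,
                                        n_cells = fpc$n), "cofreq_summary.csv"))
      files <- c(files, emit(fpc$counts, "cofreq_per_cell.csv"))
      dist <- foci_class_distribution(dataset)
      files <- c(files, emit(as.data.frame(dist), "foci_class.csv"))
    })
  }
  if ("positions" %in% config$analyses && has_pachytene) {
    wrap_stage("positions", {
      ranked <- rank_scs(dataset)
      lensum <- sc_length_summary(ranked)
      rp <- relative_positions(ranked)
      results$positions <- list(lengths = lensum, relative = rp)
      files <- c(files, emit(lensum$per_rank, "sc_length_per_rank.csv"))
      files <- c(files, emit(lensum$per_cell, "sc_length_per_cell.csv"))
      files <- c(files, emit(co_density(ranked)$per_rank, "co_density.csv"))
      files <- c(files, emit(bin_positions(rp, 10), "position_bins.csv"))
      ec <- stats::ecdf(rp$pos_frac)
      grid <- seq(0, 1, by = 0.02)
      files <- c(files, emit(data.frame(pos_frac = grid, ecdf = ec(grid)),
                              "cumulative_positions.csv"))
    })
  }
  if ("interference" %in% config$analyses && has_pachytene) {
    wrap_stage("interference", {
      fit <- coi_fit(dataset)
      results$interference <- fit
      files <- c(files, emit(data.frame(shape = fit$gamma$shape,
                                        rate = fit$gamma$rate,
                                        n = fit$gamma$n,
                                        loglik = fit$gamma$loglik),
                             "gamma_fit.csv"))
      files <- c(files, emit(as.data.frame(fit$coc), "coc_curve.csv"))
      files <- c(files, emit(data.frame(
        distance = fit$interference_distance$distance,
        reached = fit$interference_distance$reached),
        "interference_distance.csv"))
    })
  }
  if ("rpa" %in% config$analyses && any(!is.na(dataset$cells$rpa_count))) {
    wrap_stage("rpa", {
      summ <- rpa_stage_summary(dataset)
      results$rpa <- summ
      files <- c(files, emit(summ, "rpa_summary.csv"))
    })
  }
  manifest <- list(config_hash = hash, seed = config$seed,
                   analyses = config$analyses, files = sort(files))
  writeLines(yaml::as.yaml(manifest), file.path(out, "run_manifest.yaml"))
  invisible(list(dataset = dataset, results = results, manifest = manifest))
}

#' Render a markdown report of a pipeline bundle
#'
#' Summarises the tables a [run_pipeline()] call wrote into one
#' human-readable markdown document; tables that were not produced are
#' listed as absent rather than failing.
#'
#' @param bundle_dir Directory holding the pipeline output tables.
#' @param file Optional path to also write the report to.
#' @return The report, invisibly, as a character vector of lines.
#' @export
make_report <- function(bundle_dir, file = NULL) {
  if (!dir.exists(bundle_dir)) stopf("no such bundle directory: %s", bundle_dir)
  get_tab <- function(name) {
    p <- file.path(bundle_dir, name)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  lines <- c("# coimeio pipeline report", "")
  manifest <- file.path(bundle_dir, "run_manifest.yaml")
  if (file.exists(manifest)) {
    m <- yaml::read_yaml(manifest)
    lines <- c(lines, sprintf("config hash: `%s`, seed: %d", m$config_hash,
                              m$seed), "")
  }
  absent <- character(0)
  cof <- get_tab("cofreq_summary.csv")
  if (!is.null(cof)) {
    lines <- c(lines, "## Crossover frequency",
               sprintf("- MLH1 foci per cell: %.2f +/- %.2f (n = %d)",
                       cof$mean_foci, cof$sd_foci, cof$n_cells), "")
  } else absent <- c(absent, "cofreq_summary.csv")
  cls <- get_tab("foci_class.csv")
  if (!is.null(cls)) {
    lines <- c(lines, "## MLH1 class distribution per SC",
               sprintf("- class %s: %.3f", cls$class, cls$freq), "")
  } else absent <- c(absent, "foci_class.csv")
  len <- get_tab("sc_length_per_rank.csv")
  if (!is.null(len)) {
    lines <- c(lines, "## Axis morphometry",
               sprintf("- grand mean SC length: %.2f um",
                       stats::weighted.mean(len$mean_um, len$n)), "")
  } else absent <- c(absent, "sc_length_per_rank.csv")
  gf <- get_tab("gamma_fit.csv")
  idist <- get_tab("interference_distance.csv")
  if (!is.null(gf)) {
    lines <- c(lines, "## Crossover interference",
               sprintf("- gamma shape: %.2f (n = %d two-CO SCs)", gf$shape, gf$n))
    if (!is.null(idist))
      lines <- c(lines, sprintf("- interference distance (CoC = 1): %.2f%s",
                                idist$distance,
                                ifelse(idist$reached, "", " (not reached)")))
    lines <- c(lines, "")
  } else absent <- c(absent, "gamma_fit.csv")
  rpa <- get_tab("rpa_summary.csv")
  if (!is.null(rpa)) {
    lines <- c(lines, "## RPA dynamics",
               sprintf("- %s deg C, %s: %.2f +/- %.2f (n = %d)",
                       rpa$temperature_C, rpa$stage, rpa$mean, rpa$sd,
                       rpa$n_cells), "")
  } else absent <- c(absent, "rpa_summary.csv")
  if (length(absent))
    lines <- c(lines, "## Absent tables", paste0("- ", absent), "")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
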