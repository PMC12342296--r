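#' Reference karyotype for SC ranking
#'
#' The ranked 28 deg C reference profile: rank order, expected lengths,
#' morphology (ranks 1 and 4 metacentric) and the large/short
#' classification frozen against the reference lengths (ranks 1-4 large,
#' 5-17 short).
#'
#' @return Data frame `sc_rank`, `length_um`, `morphology`, `size_class`.
#' @export
gecko_reference_karyotype <- function() {
  prof <- gecko_sc_profile()
  prof$size_class <- ifelse(prof$sc_rank <= 4, "large", "short")
  prof
}

#' Rank the SCs of every cell against a reference karyotype
#'
#' Ranks 1-17 are assigned per cell by descending axis length, with the
#' constraint that metacentric SCs land on the reference's metacentric
#' ranks (taken in length order when distinguishable). Ties are broken by
#' centromere position (the more metacentric — centromere closer to the
#' axis midpoint — first), then by input order, so ranking is
#' deterministic. Cells not carrying exactly 17 scored SCs are excluded
#' and logged.
#'
#' @param dataset A [meio_dataset()].
#' @param reference Reference karyotype, as [gecko_reference_karyotype()].
#' @return The dataset with `sc_rank` reassigned in `scs` and `foci`
#'   (foci are remapped with their SC); excluded cell ids are attached as
#'   attribute `"excluded_cells"`.
#' @export
rank_scs <- function(dataset, reference = gecko_reference_karyotype()) {
  stopifnot(inherits(dataset, "meio_dataset"))
  meta_ranks <- reference$sc_rank[reference$morphology == "metacentric"]
  acro_ranks <- reference$sc_rank[reference$morphology == "acrocentric"]
  scs <- split(dataset$scs, dataset$scs$cell_id)
  n_sc <- vapply(scs, nrow, integer(1))
  excluded <- names(scs)[n_sc != 17L]
  if (length(excluded))
    message(sprintf("rank_scs: excluding %d cell(s) without exactly 17 SCs: %s",
                    length(excluded),
                    paste(utils::head(excluded, 5), collapse = ", ")))
  scs <- scs[n_sc == 17L]
  if (!length(scs)) stopf("no fully scored (17-SC) cells to rank")
  new_scs <- vector("list", length(scs))
  key_map <- vector("list", length(scs))
  for (i in seq_along(scs)) {
    cell <- scs[[i]]
    n_meta <- sum(cell$morphology == "metacentric")
    if (n_meta != length(meta_ranks))
      stopf("cell %s has %d metacentric SCs; reference expects %d",
            cell$cell_id[1], n_meta, length(meta_ranks))
    # deterministic order: longer first, centromere nearer midpoint first,
    # then input order
    cen_dev <- abs(cell$centromere_um / cell$length_um - 0.5)
    ord <- order(-cell$length_um, cen_dev, seq_len(nrow(cell)))
    new_rank <- integer(17)
    is_meta <- cell$morphology[ord] == "metacentric"
    new_rank[ord[is_meta]] <- meta_ranks
    new_rank[ord[!is_meta]] <- acro_ranks
    old <- cell$sc_rank
    cell$sc_rank <- new_rank
    key_map[[i]] <- data.frame(cell_id = cell$cell_id,
                               old = old, new = new_rank,
                               stringsAsFactors = FALSE)
    new_scs[[i]] <- cell[order(cell$sc_rank), ]
  }
  scs_tab <- do.call(rbind, new_scs)
  map <- do.call(rbind, key_map)
  foci <- dataset$foci[dataset$foci$cell_id %in% scs_tab$cell_id, , drop = FALSE]
  idx <- match(paste(foci$cell_id, foci$sc_rank), paste(map$cell_id, map$old))
  foci$sc_rank <- map$new[idx]
  cells <- dataset$cells[dataset$cells$cell_id %in% scs_tab$cell_id |
                           dataset$cells$stage != "pachytene", , drop = FALSE]
  out <- meio_dataset(cells, scs_tab, foci, dataset$metadata)
  attr(out, "excluded_cells") <- excluded
  out
}

#' SC axis-length morphometry
#'
#' Per-rank and overall summaries of SC axis length, plus per-cell totals.
#' Because the "SC size per cell" of box-plot figures can mean either the
#' per-SC lengths or the per-cell average, both are returned.
#'
#' @inheritParams foci_per_cell
#' @return List of class `sc_length_summary`: `per_rank` (`sc_rank`,
#'   `mean_um`, `sd_um`, `n`), `per_cell` (`cell_id`, `total_um`,
#'   `mean_um`), `grand_mean_um`, `grand_sd_um`, `n_cells`, `n_scs`.
#' @export
sc_length_summary <- function(dataset, temperature = NULL, animal = NULL) {
  ds <- filter_cells(dataset, temperature = temperature, stage = "pachytene",
                     animal = animal)
  if (!nrow(ds$scs)) stopf("empty selection: no scored SCs")
  s <- ds$scs
  per_rank <- do.call(rbind, lapply(split(s$length_um, s$sc_rank), function(x)
    data.frame(mean_um = mean(x), sd_um = if (length(x) > 1) stats::sd(x) else 0,
               n = length(x))))
  per_rank <- cbind(sc_rank = as.integer(rownames(per_rank)), per_rank)
  rownames(per_rank) <- NULL
  totals <- vapply(split(s$length_um, s$cell_id), sum, numeric(1))
  per_cell <- data.frame(cell_id = names(totals), total_um = unname(totals),
                         mean_um = unname(totals) /
                           as.integer(table(s$cell_id)[names(totals)]),
                         stringsAsFactors = FALSE)
  structure(list(per_rank = per_rank[order(per_rank$sc_rank), ],
                 per_cell = per_cell,
                 grand_mean_um = mean(s$length_um),
                 grand_sd_um = stats::sd(s$length_um),
                 n_cells = length(totals), n_scs = nrow(s)),
            class = "sc_length_summary")
}

#' @export
print.sc_length_summary <- function(x, ...) {
  cat(sprintf("SC length: grand mean %.2f +/- %.2f um over %d SCs in %d cells\n",
              x$grand_mean_um, x$grand_sd_um, x$n_scs, x$n_cells))
  invisible(x)
}

#' Crossover density along the karyotype
#'
#' Per-rank CO density (mean MLH1 foci per SC divided by mean SC length,
#' foci per µm) plus the per-SC densities for dispersion work.
#'
#' @inheritParams foci_per_cell
#' @return List with `per_rank` (`sc_rank`, `mean_foci`, `mean_length_um`,
#'   `density_per_um`) and `per_sc` (`cell_id`, `sc_rank`, `n_foci`,
#'   `length_um`, `density_per_um`).
#' @export
co_density <- function(dataset, temperature = NULL, animal = NULL) {
  ds <- filter_cells(dataset, temperature = temperature, stage = "pachytene",
                     animal = animal)
  if (!nrow(ds$scs)) stopf("empty selection: no scored SCs")
  s <- ds$scs
  key <- paste(s$cell_id, s$sc_rank)
  nf <- as.integer(table(factor(paste(ds$foci$cell_id, ds$foci$sc_rank),
                                levels = key)))
  per_sc <- data.frame(cell_id = s$cell_id, sc_rank = s$sc_rank, n_foci = nf,
                       length_um = s$length_um,
                       density_per_um = nf / s$length_um,
                       stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(per_sc, per_sc$sc_rank), function(d)
    data.frame(sc_rank = d$sc_rank[1], mean_foci = mean(d$n_foci),
               mean_length_um = mean(d$length_um),
               density_per_um = mean(d$n_foci) / mean(d$length_um))))
  rownames(agg) <- NULL
  list(per_rank = agg[order(agg$sc_rank), ], per_sc = per_sc)
}

#' Centromere-referenced relative CO positions
#'
#' Converts stored µm focus positions to fractions of arm length measured
#' from the centromere. Acrocentric SCs are a single arm with the origin at
#' the centromeric end (`pos_frac = position_um / length_um`). Metacentric
#' foci are assigned to the p or q arm by comparison with the centromere
#' position (a focus exactly at the centromere goes to the q arm by
#' convention) and scaled by that arm's length.
#'
#' @inheritParams foci_per_cell
#' @return Data frame `cell_id`, `sc_rank`, `arm` (`"single"`, `"p"`,
#'   `"q"`), `pos_frac` in `[0, 1]`.
#' @export
relative_positions <- function(dataset, temperature = NULL, animal = NULL) {
  ds <- filter_cells(dataset, temperature = temperature, stage = "pachytene",
                     animal = animal)
  f <- ds$foci
  if (!nrow(f)) stopf("empty selection: no foci")
  s <- ds$scs
  idx <- match(paste(f$cell_id, f$sc_rank), paste(s$cell_id, s$sc_rank))
  len <- s$length_um[idx]; cen <- s$centromere_um[idx]
  meta <- s$morphology[idx] == "metacentric"
  arm <- ifelse(!meta, "single", ifelse(f$position_um < cen, "p", "q"))
  pos_frac <- ifelse(!meta, f$position_um / len,
              ifelse(arm == "p", (cen - f$position_um) / cen,
                     (f$position_um - cen) / (len - cen)))
  data.frame(cell_id = f$cell_id, sc_rank = f$sc_rank, arm = arm,
             pos_frac = pos_frac, stringsAsFactors = FALSE)
}

#' Bin relative positions into equal intervals
#'
#' Half-open left-closed bins `[k/n, (k+1)/n)` with the last bin closed so
#' that `pos_frac = 1` is countable. Frequencies sum to 1.
#'
#' @param pos_frac Numeric vector of positions in `[0, 1]` (or the output
#'   of [relative_positions()], whose `pos_frac` column is used).
#' @param n_bins Number of intervals (default 10, i.e. 10% intervals).
#' @return Data frame `bin` (1-based), `lower`, `upper`, `count`, `freq`.
#' @export
bin_positions <- function(pos_frac, n_bins = 10) {
  if (is.data.frame(pos_frac)) pos_frac <- pos_frac$pos_frac
  if (!length(pos_frac)) stopf("empty input: no positions to bin")
  if (any(pos_frac < 0 | pos_frac > 1)) stopf("pos_frac outside [0, 1]")
  bin <- pmin(floor(pos_frac * n_bins), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  data.frame(bin = seq_len(n_bins),
             lower = (seq_len(n_bins) - 1) / n_bins,
             upper = seq_len(n_bins) / n_bins,
             count = counts, freq = counts / length(pos_frac))
}

#' Two-sample Kolmogorov-Smirnov comparison of position distributions
#'
#' Compares two sets of relative CO positions (pooled `pos_frac` values;
#' run separately per morphology class when mirroring cumulative-curve
#' figures).
#'
#' @param a,b Numeric vectors of positions (each `n >= 5`).
#' @return List with `D` (max ECDF gap) and `p_value`.
#' @export
compare_position_distributions_ks <- function(a, b) {
  if (is.data.frame(a)) a <- a$pos_frac
  if (is.data.frame(b)) b <- b$pos_frac
  if (length(a) < 5 || length(b) < 5) stopf("each sample needs n >= 5")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Centromere-effect suppression index
#'
#' Ratio of the observed frequency of positions within `window_frac` of
#' the centromere to the `window_frac` expected under a uniform
#' distribution along the arm. Values below 1 indicate suppression; 0 is
#' complete exclusion.
#'
#' @param pos_frac Relative positions (vector or [relative_positions()]
#'   output).
#' @param window_frac Pericentromeric window as a fraction of arm length.
#' @return The suppression index (scalar).
#' @export
centromere_effect <- function(pos_frac, window_frac = 0.1) {
  if (is.data.frame(pos_frac)) pos_frac <- pos_frac$pos_frac
  if (!length(pos_frac)) stopf("empty input: no positions")
  mean(pos_frac < window_frac) / window_frac
}
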