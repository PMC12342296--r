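#' Assemble a cytological meiotic dataset
#'
#' A `meio_dataset` is the package's container for per-cell cytological
#' measurements. It holds three linked tables mirroring how such data are
#' scored on spread spermatocytes:
#'
#' * `cells`: one row per cell — `cell_id`, `animal_id`, `temperature_C`,
#'   `stage` (one of [stage_levels()]), `rpa_count` (RPA focus count, `NA`
#'   when the cell was not scored for DSB markers).
#' * `scs`: one row per synaptonemal complex (SC) — `cell_id`, `sc_rank`
#'   (within-cell SC index, 1–17 once ranked), `morphology`
#'   (`"acrocentric"`/`"metacentric"`), `length_um` (axis length, µm),
#'   `centromere_um` (centromere position in µm from the axis origin).
#' * `foci`: one row per MLH1 focus — `cell_id`, `sc_rank`, `focus_index`
#'   (1-based, in ascending position order), `position_um` (µm from the
#'   axis origin).
#'
#' Coordinate convention: positions are stored in µm from a fixed axis
#' origin. For acrocentric SCs the origin is the centromeric end
#' (`centromere_um = 0`); for metacentric SCs the origin is the p-arm
#' telomere, so `0 < centromere_um < length_um`. Relative (fractional)
#' coordinates are always derived downstream, never stored.
#'
#' @param cells,scs,foci Data frames with the columns listed above. `scs`
#'   and `foci` may be `NULL`/empty (e.g. RPA-only datasets).
#' @param metadata Named list of free-form dataset metadata (species,
#'   karyotype, provenance, simulation config, ...).
#' @return An object of class `meio_dataset`.
#' @seealso [validate_dataset()], [read_meio_dataset()], [simulate_dataset()]
#' @export
meio_dataset <- function(cells, scs = NULL, foci = NULL, metadata = list()) {
  cells <- check_table(cells, "cells",
    required = c("cell_id", "animal_id", "temperature_C", "stage"),
    optional = c(rpa_count = NA_real_))
  scs <- check_table(scs, "scs",
    required = c("cell_id", "sc_rank", "morphology", "length_um", "centromere_um"))
  foci <- check_table(foci, "foci",
    required = c("cell_id", "sc_rank", "focus_index", "position_um"))
  cells$cell_id <- as.character(cells$cell_id)
  cells$animal_id <- as.character(cells$animal_id)
  cells$stage <- as.character(cells$stage)
  for (nm in c("scs", "foci")) {
    tab <- get(nm)
    tab$cell_id <- as.character(tab$cell_id)
    tab$sc_rank <- as.integer(tab$sc_rank)
    assign(nm, tab)
  }
  structure(list(cells = cells, scs = scs, foci = foci, metadata = metadata),
            class = "meio_dataset")
}

# structural (column-level) checks only; invariants live in validate_dataset()
check_table <- function(x, name, required, optional = NULL) {
  if (is.null(x)) {
    x <- as.data.frame(
      stats::setNames(rep(list(logical(0)), length(required)), required))
  }
  if (!is.data.frame(x)) stopf("`%s` must be a data.frame", name)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stopf("schema error: `%s` lacks required column(s): %s",
          name, paste(missing_cols, collapse = ", "))
  for (nm in names(optional)) if (!nm %in% names(x)) x[[nm]] <- optional[[nm]]
  rownames(x) <- NULL
  x[, c(required, names(optional)), drop = FALSE]
}

#' @export
print.meio_dataset <- function(x, ...) {
  n_cells <- nrow(x$cells)
  temps <- sort(unique(x$cells$temperature_C))
  cat("<meio_dataset>\n")
  cat(sprintf("  cells: %d  (stages: %s)\n", n_cells,
              paste(sort(unique(x$cells$stage)), collapse = ", ")))
  cat(sprintf("  temperatures (deg C): %s\n", paste(temps, collapse = ", ")))
  cat(sprintf("  SCs: %d   MLH1 foci: %d   RPA-scored cells: %d\n",
              nrow(x$scs), nrow(x$foci), sum(!is.na(x$cells$rpa_count))))
  invisible(x)
}

#' Validate a meiotic dataset against its invariants
#'
#' Checks every invariant the analyses rely on and returns a report, one row
#' per violation, rather than failing on the first problem. An empty report
#' means the dataset is valid.
#'
#' Checked rules: unique `cell_id`s; known stage labels; positive SC
#' lengths; `0 <= centromere_um <= length_um`; acrocentric SCs have
#' `centromere_um == 0` and metacentric SCs have the centromere strictly
#' interior; focus positions inside `[0, length_um]`; foci sorted ascending
#' by `focus_index` within each SC; foci referencing an existing SC;
#' nonnegative integer `rpa_count`; pachytene cells with any scored SCs
#' carrying exactly 17 of them.
#'
#' @param dataset A [meio_dataset()].
#' @return A data.frame with columns `table`, `cell_id`, `sc_rank`, `rule`,
#'   `message`, `severity`; zero rows iff the dataset is valid. Severity is
#'   `"error"` for invariant violations and `"note"` for completeness
#'   issues (a partially scored pachytene cell), which strict I/O ignores.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "meio_dataset"))
  v <- list()
  add <- function(table, cell_id, sc_rank, rule, message, severity = "error") {
    if (!length(cell_id)) return()
    v[[length(v) + 1L]] <<- data.frame(
      table = table, cell_id = as.character(cell_id),
      sc_rank = as.integer(sc_rank), rule = rule, message = message,
      severity = severity, stringsAsFactors = FALSE)
  }
  cells <- dataset$cells; scs <- dataset$scs; foci <- dataset$foci

  dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
  add("cells", dup, NA, "duplicate_cell_id", "cell_id appears more than once")

  bad_stage <- cells$cell_id[!cells$stage %in% stage_levels()]
  add("cells", bad_stage, NA, "unknown_stage",
      paste("stage not one of:", paste(stage_levels(), collapse = ", ")))

  rpa <- cells$rpa_count
  bad_rpa <- cells$cell_id[!is.na(rpa) & (rpa < 0 | rpa != round(rpa))]
  add("cells", bad_rpa, NA, "rpa_count", "rpa_count must be a nonnegative integer")

  declared <- dataset$metadata$temperatures
  if (!is.null(declared)) {
    bad_t <- cells$cell_id[!cells$temperature_C %in% declared]
    add("cells", bad_t, NA, "undeclared_temperature",
        "temperature_C not in metadata$temperatures")
  }

  if (nrow(scs)) {
    bad_len <- !is.finite(scs$length_um) | scs$length_um <= 0
    add("scs", scs$cell_id[bad_len], scs$sc_rank[bad_len], "nonpositive_length",
        "length_um must be positive")
    bad_cen <- !bad_len &
      (scs$centromere_um < 0 | scs$centromere_um > scs$length_um)
    add("scs", scs$cell_id[bad_cen], scs$sc_rank[bad_cen], "centromere_range",
        "centromere_um outside [0, length_um]")
    bad_morph <- !scs$morphology %in% morphology_levels()
    add("scs", scs$cell_id[bad_morph], scs$sc_rank[bad_morph], "morphology",
        "morphology must be acrocentric or metacentric")
    acro_off <- scs$morphology == "acrocentric" & scs$centromere_um != 0
    add("scs", scs$cell_id[acro_off], scs$sc_rank[acro_off], "acrocentric_origin",
        "acrocentric SCs use the centromeric end as origin (centromere_um = 0)")
    meta_edge <- !bad_len & scs$morphology == "metacentric" &
      (scs$centromere_um <= 0 | scs$centromere_um >= scs$length_um)
    add("scs", scs$cell_id[meta_edge], scs$sc_rank[meta_edge], "metacentric_centromere",
        "metacentric centromere must be strictly interior")
    dup_sc <- duplicated(scs[c("cell_id", "sc_rank")])
    add("scs", scs$cell_id[dup_sc], scs$sc_rank[dup_sc], "duplicate_sc",
        "duplicate (cell_id, sc_rank)")
  }

  if (nrow(foci)) {
    key <- paste(foci$cell_id, foci$sc_rank)
    sc_key <- paste(scs$cell_id, scs$sc_rank)
    orphan <- !key %in% sc_key
    add("foci", foci$cell_id[orphan], foci$sc_rank[orphan], "orphan_focus",
        "focus references an SC absent from `scs`")
    idx <- match(key, sc_key)
    len <- scs$length_um[idx]
    bad_pos <- !orphan & (foci$position_um < 0 | foci$position_um > len)
    add("foci", foci$cell_id[bad_pos], foci$sc_rank[bad_pos], "position_range",
        "focus position outside [0, length_um] of its SC")
    ord <- order(foci$cell_id, foci$sc_rank, foci$focus_index)
    f <- foci[ord, ]
    same_sc <- c(FALSE, paste(f$cell_id, f$sc_rank)[-1] ==
                          paste(f$cell_id, f$sc_rank)[-nrow(f)])
    unsorted <- same_sc & c(FALSE, diff(f$position_um) < 0)
    add("foci", f$cell_id[unsorted], f$sc_rank[unsorted], "unsorted_foci",
        "foci positions not ascending in focus_index order")
  }

  pach <- unique(cells$cell_id[cells$stage == "pachytene"])
  if (length(pach) && nrow(scs)) {
    n_sc <- table(factor(scs$cell_id, levels = pach))
    partial <- names(n_sc)[n_sc != 0L & n_sc != 17L]
    # partially scored cells are excluded by rank_scs(), not invalid per se
    add("cells", partial, NA, "sc_count",
        "pachytene cell scored with a number of SCs other than 17",
        severity = "note")
  }

  if (length(v)) do.call(rbind, v) else
    data.frame(table = character(), cell_id = character(),
               sc_rank = integer(), rule = character(), message = character(),
               severity = character(), stringsAsFactors = FALSE)
}

#' Subset a dataset by condition
#'
#' @param dataset A [meio_dataset()].
#' @param temperature Optional numeric vector of temperatures (deg C) to keep.
#' @param stage Optional character vector of stages to keep.
#' @param animal Optional character vector of animal ids to keep.
#' @return A [meio_dataset()] restricted to the matching cells.
#' @export
filter_cells <- function(dataset, temperature = NULL, stage = NULL, animal = NULL) {
  stopifnot(inherits(dataset, "meio_dataset"))
  keep <- rep(TRUE, nrow(dataset$cells))
  if (!is.null(temperature)) keep <- keep & dataset$cells$temperature_C %in% temperature
  if (!is.null(stage)) keep <- keep & dataset$cells$stage %in% stage
  if (!is.null(animal)) keep <- keep & dataset$cells$animal_id %in% animal
  ids <- dataset$cells$cell_id[keep]
  meio_dataset(dataset$cells[keep, , drop = FALSE],
               dataset$scs[dataset$scs$cell_id %in% ids, , drop = FALSE],
               dataset$foci[dataset$foci$cell_id %in% ids, , drop = FALSE],
               dataset$metadata)
}
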