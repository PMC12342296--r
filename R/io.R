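#' Read a meiotic dataset from disk
#'
#' Two on-disk layouts are supported:
#'
#' * `format = "csv"` — a directory holding `cells.csv`, `scs.csv` and
#'   `foci.csv` with the documented schemas (see [meio_dataset()]); this is
#'   the layout [write_meio_dataset()] produces.
#' * `format = "xlsx"` — a supplementary-style workbook with one sheet per
#'   condition and one row per SC. Because published supplementary tables
#'   vary in their headers, the column mapping is supplied by the caller
#'   via `header_map` rather than hard-coded.
#'
#' @param path Directory (csv) or workbook file (xlsx).
#' @param format `"csv"` or `"xlsx"`.
#' @param header_map For xlsx: named list mapping canonical fields to the
#'   workbook's actual headers. Required entries: `cell`, `length`; optional:
#'   `sc` (SC index column), `morphology`, `centromere`, `foci_prefix`
#'   (prefix shared by the focus-position columns, e.g. `"mlh1_"`),
#'   `animal`, `stage` (constant label applied to every row, default
#'   `"pachytene"`), `sheet_temperature_C` (named numeric vector mapping
#'   sheet name to temperature; by default the first number in the sheet
#'   name is used). May also be the path to a YAML file holding the same.
#' @param strict If `TRUE` (default) any invariant violation aborts with
#'   row-level diagnostics; if `FALSE` the offending rows are dropped with
#'   a warning and the report attached as attribute `"dropped"`.
#' @return A validated [meio_dataset()].
#' @export
read_meio_dataset <- function(path, format = c("csv", "xlsx"),
                              header_map = NULL, strict = TRUE) {
  format <- match.arg(format)
  ds <- switch(format,
    csv = read_csv_layout(path),
    xlsx = read_xlsx_layout(path, header_map))
  report <- validate_dataset(ds)
  report <- report[report$severity == "error", , drop = FALSE]
  if (nrow(report)) {
    msg <- paste0(utils::head(sprintf("  [%s] cell %s sc %s: %s", report$rule,
                                      report$cell_id, report$sc_rank,
                                      report$message), 10L), collapse = "\n")
    if (strict)
      stopf("validation error: %d row(s) violate dataset invariants:\n%s",
            nrow(report), msg)
    warning(sprintf("dropping %d invalid row(s)", nrow(report)), call. = FALSE)
    bad_sc <- report[report$table == "scs", ]
    bad_foci <- report[report$table == "foci", ]
    drop_sc <- paste(ds$scs$cell_id, ds$scs$sc_rank) %in%
      paste(bad_sc$cell_id, bad_sc$sc_rank)
    drop_f <- paste(ds$foci$cell_id, ds$foci$sc_rank) %in%
      c(paste(bad_sc$cell_id, bad_sc$sc_rank),
        paste(bad_foci$cell_id, bad_foci$sc_rank))
    ds <- meio_dataset(ds$cells[!ds$cells$cell_id %in%
                                  report$cell_id[report$table == "cells"], ],
                       ds$scs[!drop_sc, ], ds$foci[!drop_f, ], ds$metadata)
    attr(ds, "dropped") <- report
  }
  ds
}

read_csv_layout <- function(path) {
  if (!dir.exists(path)) stopf("no such directory: %s", path)
  need <- file.path(path, c("cells.csv", "scs.csv", "foci.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stopf("schema error: missing file(s): %s", paste(missing, collapse = ", "))
  cells <- utils::read.csv(need[1], stringsAsFactors = FALSE,
                           colClasses = c(cell_id = "character"))
  scs <- utils::read.csv(need[2], stringsAsFactors = FALSE,
                         colClasses = c(cell_id = "character"))
  foci <- utils::read.csv(need[3], stringsAsFactors = FALSE,
                          colClasses = c(cell_id = "character"))
  meta_file <- file.path(path, "metadata.yaml")
  metadata <- if (file.exists(meta_file)) yaml::read_yaml(meta_file) else list()
  meio_dataset(cells, scs, foci, metadata)
}

read_xlsx_layout <- function(path, header_map) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (!requireNamespace("readxl", quietly = TRUE))
    stopf("xlsx import requires the readxl package")
  if (is.character(header_map) && length(header_map) == 1L)
    header_map <- yaml::read_yaml(header_map)
  if (is.null(header_map$cell) || is.null(header_map$length))
    stopf("schema error: header_map must define at least `cell` and `length`")
  sheets <- readxl::excel_sheets(path)
  cells <- scs <- foci <- list()
  for (sh in sheets) {
    tab <- as.data.frame(readxl::read_excel(path, sheet = sh),
                         stringsAsFactors = FALSE)
    req <- c(header_map$cell, header_map$length)
    miss <- setdiff(req, names(tab))
    if (length(miss))
      stopf("schema error: sheet '%s' lacks column(s): %s", sh,
            paste(miss, collapse = ", "))
    temp <- header_map$sheet_temperature_C[[sh]] %||%
      as.numeric(regmatches(sh, regexpr("[0-9]+\\.?[0-9]*", sh)))
    if (!length(temp) || is.na(temp))
      stopf("cannot infer temperature for sheet '%s'; supply sheet_temperature_C", sh)
    cid <- paste0(sh, ":", as.character(tab[[header_map$cell]]))
    rank <- if (!is.null(header_map$sc)) as.integer(tab[[header_map$sc]]) else
      stats::ave(seq_along(cid), cid, FUN = seq_along)
    morph <- if (!is.null(header_map$morphology))
      as.character(tab[[header_map$morphology]]) else "acrocentric"
    cen <- if (!is.null(header_map$centromere))
      as.numeric(tab[[header_map$centromere]]) else 0
    animal <- if (!is.null(header_map$animal))
      as.character(tab[[header_map$animal]]) else sh
    sc_tab <- data.frame(cell_id = cid, sc_rank = rank, morphology = morph,
                         length_um = as.numeric(tab[[header_map$length]]),
                         centromere_um = cen, stringsAsFactors = FALSE)
    cell_tab <- unique(data.frame(cell_id = cid, animal_id = animal,
                                  temperature_C = temp,
                                  stage = header_map$stage %||% "pachytene",
                                  rpa_count = NA_real_, stringsAsFactors = FALSE))
    fcols <- if (!is.null(header_map$foci_prefix))
      grep(paste0("^", header_map$foci_prefix), names(tab), value = TRUE)
    else character(0)
    if (length(fcols)) {
      pos <- as.matrix(tab[fcols])
      f <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
        p <- sort(as.numeric(pos[i, ]))
        p <- p[is.finite(p)]
        if (!length(p)) return(NULL)
        data.frame(cell_id = cid[i], sc_rank = rank[i],
                   focus_index = seq_along(p), position_um = p,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(f)) foci[[sh]] <- f
    }
    cells[[sh]] <- cell_tab
    scs[[sh]] <- sc_tab
  }
  meio_dataset(do.call(rbind, cells), do.call(rbind, scs),
               if (length(foci)) do.call(rbind, foci) else NULL,
               metadata = list(source = path))
}

#' Write a meiotic dataset to a directory of CSV files
#'
#' Emits `cells.csv`, `scs.csv`, `foci.csv` (stable column order, no row
#' names) plus `metadata.yaml` when metadata are present. Output is
#' byte-reproducible for identical input, and [read_meio_dataset()] on the
#' result round-trips all values (exactly for identifiers and integers, to
#' full printed double precision for measurements).
#'
#' @param dataset A valid [meio_dataset()].
#' @param path Output directory; created if absent.
#' @return `path`, invisibly.
#' @export
write_meio_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "meio_dataset"))
  report <- validate_dataset(dataset)
  report <- report[report$severity == "error", , drop = FALSE]
  if (nrow(report))
    stopf("refusing to write an invalid dataset (%d violation(s)); see validate_dataset()",
          nrow(report))
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory: %s", path)
  wr <- function(tab, file) {
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], function(x) {
      out <- vapply(x, function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE),
        character(1))
      out
    })
    utils::write.csv(tab, file.path(path, file), row.names = FALSE, quote = TRUE,
                     na = "")
  }
  wr(dataset$cells, "cells.csv")
  wr(dataset$scs, "scs.csv")
  wr(dataset$foci, "foci.csv")
  if (length(dataset$metadata))
    writeLines(yaml::as.yaml(dataset$metadata), file.path(path, "metadata.yaml"))
  invisible(path)
}
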