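#' Per-stage RPA focus summaries
#'
#' Mean, SD and cell count of RPA foci per prophase-I stage, grouped by
#' temperature. Stages are ordered leptotene to pachytene; groups with a
#' single cell get `sd = 0` and are flagged.
#'
#' @param dataset A [meio_dataset()] whose cells carry `rpa_count`.
#' @param temperature Optional temperature filter.
#' @return Data frame `temperature_C`, `stage`, `mean`, `sd`, `n_cells`,
#'   `single_cell` (logical flag), ordered by temperature then stage.
#' @export
rpa_stage_summary <- function(dataset, temperature = NULL) {
  ds <- filter_cells(dataset, temperature = temperature)
  cells <- ds$cells[!is.na(ds$cells$rpa_count), , drop = FALSE]
  if (!nrow(cells)) stopf("empty selection: no RPA-scored cells")
  bad <- setdiff(unique(cells$stage), stage_levels())
  if (length(bad)) stopf("validation error: unknown stage label(s): %s",
                         paste(bad, collapse = ", "))
  grp <- split(cells$rpa_count,
               list(cells$temperature_C,
                    factor(cells$stage, levels = stage_levels())),
               drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(names(grp), "\r", fixed = TRUE))
  out <- data.frame(
    temperature_C = as.numeric(keys[, 1]), stage = keys[, 2],
    mean = vapply(grp, mean, numeric(1)),
    sd = vapply(grp, function(x) if (length(x) > 1) stats::sd(x) else 0,
                numeric(1)),
    n_cells = vapply(grp, length, integer(1)),
    stringsAsFactors = FALSE)
  out$single_cell <- out$n_cells == 1L
  out <- out[order(out$temperature_C,
                   match(out$stage, stage_levels())), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tukey HSD pairwise comparison of groups
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference test
#' (studentized-range distribution), giving family-wise adjusted p-values
#' for every pair of groups.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each
#'   `n >= 2`).
#' @return Data frame `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
compare_groups_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stopf("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2)) stopf("each group needs n >= 2")
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = dat)
  tk <- stats::TukeyHSD(fit)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' RPA comparisons across conditions or stages
#'
#' Convenience wrapper running [compare_groups_tukey()] either across
#' temperatures within one stage (the usual comparison axis) or across
#' stages within one temperature.
#'
#' @param dataset A [meio_dataset()] with RPA-scored cells.
#' @param stage Stage to compare across temperatures (mode
#'   `"across_temperature"`).
#' @param temperature Temperature to compare across stages (mode
#'   `"across_stage"`).
#' @param mode Comparison axis.
#' @return Data frame as [compare_groups_tukey()], with a `stage` or
#'   `temperature_C` column prepended.
#' @export
rpa_tukey <- function(dataset, stage = NULL, temperature = NULL,
                      mode = c("across_temperature", "across_stage")) {
  mode <- match.arg(mode)
  cells <- dataset$cells[!is.na(dataset$cells$rpa_count), , drop = FALSE]
  if (mode == "across_temperature") {
    if (is.null(stage)) stopf("supply `stage` for across-temperature mode")
    cells <- cells[cells$stage == stage, , drop = FALSE]
    groups <- split(cells$rpa_count, paste0(cells$temperature_C, "C"))
    out <- compare_groups_tukey(groups)
    cbind(stage = stage, out, stringsAsFactors = FALSE)
  } else {
    if (is.null(temperature)) stopf("supply `temperature` for across-stage mode")
    cells <- cells[cells$temperature_C == temperature, , drop = FALSE]
    groups <- split(cells$rpa_count, factor(cells$stage, levels = stage_levels()))
    groups <- groups[lengths(groups) > 0]
    out <- compare_groups_tukey(groups)
    cbind(temperature_C = temperature, out, stringsAsFactors = FALSE)
  }
}
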