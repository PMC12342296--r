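#' Per-cell MLH1 focus counts
#'
#' Counts MLH1 foci per pachytene cell (the sum over its SCs) and
#' summarises the selection. Animals within a condition are pooled by
#' default, mirroring the study design; pass `animal` to stratify.
#'
#' @param dataset A [meio_dataset()].
#' @param temperature,animal Optional condition filters (see
#'   [filter_cells()]); only pachytene cells with scored SCs are counted.
#' @return A list of class `foci_per_cell`: `counts` (data.frame `cell_id`,
#'   `n_foci`), `mean`, `sd`, `n`.
#' @export
foci_per_cell <- function(dataset, temperature = NULL, animal = NULL) {
  ds <- filter_cells(dataset, temperature = temperature, stage = "pachytene",
                     animal = animal)
  scored <- unique(ds$scs$cell_id)
  if (!length(scored)) stopf("empty selection: no pachytene cells with scored SCs")
  n_foci <- table(factor(ds$foci$cell_id, levels = scored))
  counts <- data.frame(cell_id = scored, n_foci = as.integer(n_foci),
                       stringsAsFactors = FALSE)
  structure(list(counts = counts, mean = mean(counts$n_foci),
                 sd = stats::sd(counts$n_foci), n = nrow(counts),
                 temperature = temperature),
            class = "foci_per_cell")
}

#' @export
print.foci_per_cell <- function(x, ...) {
  cat(sprintf("MLH1 foci per cell: %.2f +/- %.2f (n = %d cells%s)\n",
              x$mean, x$sd, x$n,
              if (is.null(x$temperature)) "" else
                sprintf(", %s deg C", paste(x$temperature, collapse = "/"))))
  invisible(x)
}

#' Distribution of MLH1 focus classes per SC
#'
#' Relative frequency of SCs bearing 0, 1, 2, 3 or >= 4 foci, optionally
#' stratified by SC rank. The open-ended top class avoids discarding
#' heavily loaded SCs.
#'
#' @inheritParams foci_per_cell
#' @param by_rank If `TRUE`, return one distribution row per `sc_rank`.
#' @return An object of class `foci_distribution`: data.frame with
#'   `class` (`"0"`,`"1"`,`"2"`,`"3"`,`"4+"`), `count`, `freq` (and
#'   `sc_rank` when stratified); attribute `n_scs`.
#' @export
foci_class_distribution <- function(dataset, temperature = NULL,
                                    animal = NULL, by_rank = FALSE) {
  ds <- filter_cells(dataset, temperature = temperature, stage = "pachytene",
                     animal = animal)
  if (!nrow(ds$scs)) stopf("empty selection: no scored SCs")
  sc_key <- paste(ds$scs$cell_id, ds$scs$sc_rank)
  per_sc <- table(factor(paste(ds$foci$cell_id, ds$foci$sc_rank),
                         levels = sc_key))
  cls <- cut(as.integer(per_sc), breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf),
             labels = c("0", "1", "2", "3", "4+"))
  tab_one <- function(cl) {
    counts <- table(cl)
    data.frame(class = names(counts), count = as.integer(counts),
               freq = as.integer(counts) / length(cl),
               stringsAsFactors = FALSE)
  }
  out <- if (by_rank) {
    ranks <- ds$scs$sc_rank
    do.call(rbind, lapply(sort(unique(ranks)), function(r) {
      d <- tab_one(cls[ranks == r]); d$sc_rank <- r; d
    }))
  } else tab_one(cls)
  structure(out, class = c("foci_distribution", "data.frame"),
            n_scs = length(cls), temperature = temperature)
}

#' Compare mean focus counts between two conditions (t-test)
#'
#' Two-tailed Welch (unequal-variance) t-test by default; set
#' `var_equal = TRUE` for the pooled-variance version. When both samples
#' are constant and equal the comparison is degenerate and `p = 1` is
#' returned by convention (`p = 0` if constant but different).
#'
#' @param a,b Numeric vectors of per-cell counts (each `n >= 2`).
#' @param var_equal Use the pooled-variance t-test.
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_means_ttest <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stopf("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else Inf, df = NA_real_,
                p_value = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Compare two focus-class distributions (chi-squared)
#'
#' Contingency chi-squared (no continuity correction) on the class counts
#' of two [foci_class_distribution()] results. Classes whose expected count
#' falls below `pool_threshold` are pooled into the adjacent lower class
#' before testing (sparse top classes collapse downwards), preserving the
#' total count.
#'
#' @param a,b `foci_distribution` objects (unstratified) or data frames
#'   with `class` and `count`.
#' @param pool_threshold Minimum expected count per class (default 5).
#' @return List with `statistic`, `df`, `p_value`, and the pooled `table`.
#' @export
compare_class_distribution_chisq <- function(a, b, pool_threshold = 5) {
  grab <- function(x) {
    if (!all(c("class", "count") %in% names(x)))
      stopf("need absolute class counts (columns `class`, `count`)")
    stats::setNames(x$count, x$class)
  }
  ca <- grab(a); cb <- grab(b)
  classes <- union(names(ca), names(cb))
  m <- rbind(a = ca[classes], b = cb[classes])
  m[is.na(m)] <- 0
  colnames(m) <- classes
  # pool sparse classes (expected < threshold) into the adjacent lower class
  repeat {
    if (ncol(m) <= 2) break
    exp_m <- outer(rowSums(m), colSums(m)) / sum(m)
    low <- which(apply(exp_m, 2, min) < pool_threshold)
    if (!length(low)) break
    j <- max(low)
    tgt <- if (j > 1) j - 1L else j + 1L
    m[, tgt] <- m[, tgt] + m[, j]
    colnames(m)[tgt] <- paste(colnames(m)[min(tgt, j)], colnames(m)[max(tgt, j)],
                              sep = "+")
    m <- m[, -j, drop = FALSE]
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2)
    stopf("not testable: fewer than 2 non-empty classes after pooling")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = m)
}
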