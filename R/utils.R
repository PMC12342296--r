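`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prophase I stage labels, in meiotic order
#'
#' @return Character vector of the four scored substages of prophase I,
#'   ordered leptotene to pachytene.
#' @export
stage_levels <- function() {
  c("leptotene", "early_zygotene", "late_zygotene", "pachytene")
}

morphology_levels <- function() c("acrocentric", "metacentric")

# positive scalar check used across constructors
is_pos_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

# small deterministic integer derived from a user seed, kept inside .Machine$integer.max
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
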