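# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an expression-GC fit
#'
#' @param x An `est_gc_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @export
tidy.est_gc_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row fit summary of an expression-GC fit
#'
#' @param x An `est_gc_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `n`, `rss`, `f_statistic`, `p_value`.
#' @export
glance.est_gc_fit <- function(x, ...) {
  tibble(model = x$model, n = x$n, rss = x$rss,
         f_statistic = x$f_statistic, p_value = x$p_value)
}

#' Tidy a correspondence analysis
#'
#' @param x An `est_coa` object.
#' @param which `"genes"` (row coordinates) or `"codons"` (column
#'   coordinates).
#' @param ... Unused.
#' @return A tibble of coordinates on the retained axes.
#' @export
tidy.est_coa <- function(x, which = c("codons", "genes"), ...) {
  which <- match.arg(which)
  if (which == "codons") x$col_coords else x$row_coords
}

#' One-row summary of a correspondence analysis
#'
#' @param x An `est_coa` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_codons`, `total_inertia`,
#'   `axis1_inertia`.
#' @export
glance.est_coa <- function(x, ...) {
  tibble(n_genes = nrow(x$row_coords), n_codons = nrow(x$col_coords),
         total_inertia = x$total_inertia, axis1_inertia = x$inertia[1])
}
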