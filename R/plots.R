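# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_hline
#'   labs theme_minimal autoplot
#' @export
ggplot2::autoplot

#' Plot an expression-GC fit
#'
#' Observed GC against the expression proxy with the fitted curve overlaid.
#'
#' @param object An `est_gc_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.est_gc_fit <- function(object, ...) {
  df <- object$data
  ord <- order(df$x)
  fit_df <- tibble(x = df$x[ord], y = object$fitted[ord])
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.6) +
    geom_line(data = fit_df, colour = "firebrick", linewidth = 0.8) +
    labs(x = "expression proxy (copy number)", y = "GC fraction",
         title = paste0("Expression-GC fit (", object$model, ")")) +
    theme_minimal()
}

#' Plot a correspondence analysis
#'
#' Codon loadings (labelled) and gene scores on the first two axes.
#'
#' @param object An `est_coa` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.est_coa <- function(object, ...) {
  genes <- object$row_coords
  codons <- object$col_coords
  ggplot(genes, aes(x = .data$axis1, y = .data$axis2)) +
    geom_point(colour = "grey60", alpha = 0.7) +
    ggplot2::geom_text(data = codons,
                       aes(label = .data$codon), colour = "firebrick",
                       size = 2.6) +
    labs(x = sprintf("axis 1 (%.1f%% inertia)", 100 * object$inertia[1]),
         y = sprintf("axis 2 (%.1f%% inertia)", 100 * object$inertia[2]),
         title = "Codon-usage correspondence analysis") +
    theme_minimal()
}

#' Plot an ROC table from cutoff optimization
#'
#' @param opt Result of [optimize_cutoff()].
#' @return A ggplot of sensitivity and specificity against the cutoff.
#' @export
plot_roc_table <- function(opt) {
  df <- tidyr::pivot_longer(opt$roc, c("sensitivity", "specificity"),
                            names_to = "measure", values_to = "value")
  ggplot(df, aes(x = .data$cutoff, y = .data$value, colour = .data$measure)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = opt$cutoff, linetype = 2) +
    labs(x = "score cutoff", y = NULL,
         title = "Coding-score cutoff optimization") +
    theme_minimal()
}

#' Plot the unigene size distribution of an assembly
#'
#' @param assembly Result of [assemble_reads()].
#' @return A ggplot histogram of member counts.
#' @export
plot_assembly_sizes <- function(assembly) {
  ggplot(assembly$unigenes, aes(x = .data$n_members)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::scale_x_log10() +
    labs(x = "reads per unigene", y = "unigenes",
         title = "Unigene size distribution") +
    theme_minimal()
}
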