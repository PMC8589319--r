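#' Volcano plot of a permutation-FDR differential result
#'
#' Log2 fold change against the magnitude of the S0-modified statistic,
#' colored by significance and, when annotation is present, shaped by
#' mitochondrial membership.
#'
#' @param x A `perm_fdr` object or the annotated result tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, ...) {
  res <- if (inherits(x, "perm_fdr")) tidy(x) else x
  p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$log2fc, y = abs(.data$d),
                                         color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "|d| (S0-modified Welch)",
                  color = "significant") +
    ggplot2::theme_minimal()
  if ("mito" %in% names(res) && !all(is.na(res$mito))) {
    p <- p + ggplot2::aes(shape = .data$mito) +
      ggplot2::labs(shape = "mitochondrial")
  }
  p
}

#' @export
autoplot.perm_fdr <- function(object, ...) plot_volcano(object, ...)

#' Rank-abundance plot of copy-number estimates
#'
#' Classic proteomic-ruler display: copies per cell (log10) against
#' abundance rank.
#'
#' @param copy_numbers Copy-number tibble from [proteomic_ruler_copies()].
#' @param highlight Optional character vector of accessions to label.
#' @return A ggplot object.
#' @export
plot_rank_abundance <- function(copy_numbers, highlight = NULL) {
  p <- ggplot2::ggplot(copy_numbers,
                       ggplot2::aes(x = .data$rank, y = .data$copies)) +
    ggplot2::geom_point(size = 0.8, color = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance rank", y = "copies per cell") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    sel <- copy_numbers[copy_numbers$protein %in% highlight, , drop = FALSE]
    p <- p + ggplot2::geom_point(data = sel, color = "firebrick") +
      ggplot2::geom_text(data = sel, ggplot2::aes(label = .data$protein),
                         vjust = -0.6, size = 3)
  }
  p
}

#' Bar plot of an AQUA linkage profile
#'
#' Per-locus absolute abundance with standard-error bars, faceted by
#' condition.
#'
#' @param object An `aqua_profile` from [quantify_aqua()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aqua_profile <- function(object, ...) {
  ggplot2::ggplot(object$by_locus,
                  ggplot2::aes(x = .data$locus, y = .data$fmol)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fmol - .data$sem,
                                        ymax = .data$fmol + .data$sem),
                           width = 0.3) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "abundance (fmol)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
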