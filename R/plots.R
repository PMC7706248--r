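#' Scatter of variant VAF against carrier counts
#'
#' The classic overview of a pooled amplicon experiment: each variant's
#' summary VAF against the number of accessions carrying it, with the
#' cumulative percentage of variants overlaid, so statements like "75% of
#' variants have a VAF of 0.05 or lower" can be read off.
#'
#' @param summary A [summarize_variants()] table.
#' @param stat Per-variant statistic on the x axis.
#' @return A ggplot.
#' @export
plot_vaf_overview <- function(summary, stat = "mean_vaf") {
  curve <- vaf_cumulative_curve(summary, stat)
  max_n <- max(summary$n_accessions)
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data[[stat]], y = .data$n_accessions)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$vaf,
                                    y = .data$cum_pct / 100 * max_n),
                       colour = "red") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / max_n * 100,
                                   name = "cumulative % of variants")) +
    ggplot2::labs(x = "VAF", y = "accessions carrying variant")
}

#' @rdname pcoa_ordination
#' @param object A `pool_pcoa` object.
#' @param axes Which two axes to draw.
#' @method autoplot pool_pcoa
#' @export
autoplot.pool_pcoa <- function(object, axes = c(1, 2), ...) {
  co <- tidy(object)
  ax <- paste0("Axis", axes)
  if (!all(ax %in% names(co))) abort("requested axes not available")
  pos <- pmax(object$eigenvalues, 0)
  pct <- round(100 * pos[axes] / sum(pos), 1)
  ggplot2::ggplot(co, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]])) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$accession),
                       vjust = -0.6, size = 2.5) +
    ggplot2::labs(x = paste0(ax[1], " (", pct[1], "%)"),
                  y = paste0(ax[2], " (", pct[2], "%)"))
}

#' Strip/violin display of per-accession VAF distributions
#'
#' @param vafs A named list of VAF vectors or accessions-by-variants
#'   matrix.
#' @param drop_zeros Show only nonzero VAFs in the violins (the zero
#'   fraction is better read from [vaf_distribution_summary()]).
#' @return A ggplot.
#' @export
plot_vaf_violin <- function(vafs, drop_zeros = TRUE) {
  if (is.matrix(vafs)) {
    vafs <- setNames(lapply(seq_len(nrow(vafs)), function(i) vafs[i, ]),
                     rownames(vafs))
  }
  df <- list_rbind(imap(vafs, ~ tibble(accession = .y, vaf = .x)))
  if (drop_zeros) df <- filter(df, .data$vaf != 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accession, y = .data$vaf)) +
    ggplot2::geom_violin(scale = "width", fill = "grey85") +
    ggplot2::geom_jitter(width = 0.12, size = 0.4, alpha = 0.5) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.5,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "VAF") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of the pairwise significance matrix
#'
#' @param m A [pairwise_significance()] matrix.
#' @return A ggplot.
#' @export
plot_significance_matrix <- function(m) {
  df <- tidy.nei_dist(unclass(m))
  names(df)[3] <- "different"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item1, y = .data$item2,
                                   fill = factor(.data$different))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "grey20"),
                               name = "different") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
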