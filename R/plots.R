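# ggplot2 visualizations for the result objects.

#' Plot an isotype-score histogram
#'
#' Bar chart of binned isotype scores, stacked by curation category when the
#' histogram was built from curated calls, with dotted guides at the triage
#' decision thresholds.
#'
#' @param object A `trna_score_histogram` from [score_histogram()].
#' @param band_low,band_high Threshold guides (defaults 60 and 90).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.trna_score_histogram <- function(object, band_low = 60,
                                          band_high = 90, ...) {
  df <- unclass_keep_cols(object)
  catcols <- grep("^n_", names(df), value = TRUE)
  p <- if (length(catcols) > 0) {
    long <- df |>
      tidyr::pivot_longer(cols = all_of(catcols), names_to = "category",
                          values_to = "n", names_prefix = "n_") |>
      mutate(n = replace_na(.data$n, 0L))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_start + (.data$bin_end - .data$bin_start) / 2,
                                       y = .data$n, fill = .data$category)) +
      ggplot2::geom_col(width = df$bin_end[1] - df$bin_start[1])
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start + (.data$bin_end - .data$bin_start) / 2,
                                     y = .data$count)) +
      ggplot2::geom_col(width = df$bin_end[1] - df$bin_start[1])
  }
  p +
    ggplot2::geom_vline(xintercept = c(band_low, band_high), linetype = "dotted") +
    ggplot2::labs(x = "isotype score (bits)", y = "tRNA genes") +
    ggplot2::theme_minimal()
}

#' Plot a gene-set count matrix as a heatmap
#'
#' Genomes-by-types tile plot; deviant genomes are marked with an asterisk.
#'
#' @param object A `trna_geneset_matrix` from [build_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.trna_geneset_matrix <- function(object, ...) {
  long <- tidy(object) |>
    mutate(genome_label = ifelse(.data$deviant, paste0(.data$genome_id, " *"),
                                 .data$genome_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$genome_label,
                                     fill = factor(.data$n))) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "gene copies") +
    ggplot2::labs(x = "tRNA type", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}

#' Plot curation calls along the genome
#'
#' One segment per gene, colored by category, faceted by contig.
#'
#' @param object A `trna_curation` from [curate_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.trna_curation <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$category, yend = .data$category,
                                   color = .data$category)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::facet_wrap(~seq_id, scales = "free_x") +
    ggplot2::labs(x = "genomic position (bp)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
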