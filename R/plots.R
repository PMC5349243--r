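# ggplot2 views of the main result types.

#' @describeIn call_cnv tile plot of the call matrix (genotypes x regions);
#'   intended for panels small enough to read, e.g. a region subset.
#' @param object A `cnv_calls` object.
#' @method autoplot cnv_calls
#' @export
autoplot.cnv_calls <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_id, y = .data$genotype_id,
                                   fill = .data$call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(deletion = "#D55E00",
                                          normal = "grey85",
                                          duplication = "#0072B2",
                                          no_call = "white")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Histogram of the population CNV frequency spectrum
#'
#' Carrier frequencies of all segregating (region, type) CNVs, with the
#' rare-CNV threshold marked.
#'
#' @param freq A `cnv_freq` object from [cnv_frequency_spectrum()].
#' @param binwidth Histogram bin width on the frequency axis.
#' @return A ggplot object.
#' @export
plot_frequency_spectrum <- function(freq, binwidth = 0.025) {
  ggplot2::ggplot(freq$frequencies,
                  ggplot2::aes(x = .data$frequency, fill = .data$call)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "stack") +
    ggplot2::geom_vline(xintercept = freq$rare_threshold, linetype = 2) +
    ggplot2::labs(x = "carrier frequency", y = "CNVs",
                  subtitle = sprintf("%.0f%% below the %.2f rare threshold",
                                     100 * freq$fraction_rare,
                                     freq$rare_threshold)) +
    ggplot2::theme_minimal()
}

#' Bar chart of simple-event counts per subgenome and scope
#'
#' @param summary A `subgenome_summary` from [subgenome_event_counts()].
#' @return A ggplot object.
#' @export
plot_subgenome_summary <- function(summary) {
  df <- summary$simple
  df$scope <- factor(df$scope, levels = c("all", "genic", "target"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subgenome, y = .data$n,
                                   fill = .data$event_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "subgenome", y = "events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of HNRT counts per ordered chromosome pair
#'
#' @param landscape An `hnrt_landscape` from [hnrt_landscape()].
#' @param top Show at most this many pairs (highest counts first).
#' @return A ggplot object.
#' @export
plot_hnrt_landscape <- function(landscape, top = 20) {
  df <- head(landscape$pairs, top)
  df$pair <- paste(df$from_chrom, df$to_chrom, sep = " → ")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pair, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "HNRT events") +
    ggplot2::theme_minimal()
}

#' @describeIn qc_report dot plot of per-genotype enrichment metrics,
#'   optionally coloured by morphotype.
#' @param object A `qc_report`.
#' @param ... Unused.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  metric_cols <- setdiff(names(object$per_genotype),
                         c("genotype_id", "morphotype"))
  df <- tidyr::pivot_longer(object$per_genotype,
                            dplyr::all_of(metric_cols),
                            names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value))
  if ("morphotype" %in% names(object$per_genotype)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                          fill = .data$morphotype))
  }
  p +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "genotypes") +
    ggplot2::theme_minimal()
}
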