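# ggplot2 displays for the result objects.

#' Plot a TPM histogram
#'
#' Mixed-width binning: width 1 up to 100 TPM, width 100 above.
#'
#' @param x A `quant_result` or a tibble from [tpm_histogram()].
#' @return A ggplot.
#' @export
plot_tpm_histogram <- function(x) {
  h <- if (inherits(x, "quant_result")) attr(x$expression, "histogram") else x
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_low + (.data$bin_high - .data$bin_low) / 2,
                                  y = .data$count,
                                  width = .data$bin_high - .data$bin_low)) +
    ggplot2::geom_col(fill = "steelblue", colour = NA) +
    ggplot2::labs(x = "TPM", y = "Contigs",
                  title = "Expression distribution") +
    ggplot2::theme_minimal()
}

#' Plot a contig length histogram
#'
#' @param x An `assembly_stats` object or a tibble from
#'   [length_histogram()].
#' @return A ggplot.
#' @export
plot_length_histogram <- function(x) {
  h <- if (inherits(x, "assembly_stats")) attr(x, "histogram") else x
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_low + (.data$bin_high - .data$bin_low) / 2,
                                  y = .data$count,
                                  width = .data$bin_high - .data$bin_low)) +
    ggplot2::geom_col(fill = "darkseagreen4", colour = NA) +
    ggplot2::labs(x = "Contig length (bp)", y = "Contigs",
                  title = "Assembly length distribution") +
    ggplot2::theme_minimal()
}

#' @rdname plot_tpm_histogram
#' @param object A `quant_result`.
#' @param ... Unused.
#' @method autoplot quant_result
#' @export
autoplot.quant_result <- function(object, ...) plot_tpm_histogram(object)

#' @rdname plot_length_histogram
#' @param object An `assembly_stats` object.
#' @param ... Unused.
#' @method autoplot assembly_stats
#' @export
autoplot.assembly_stats <- function(object, ...) plot_length_histogram(object)

#' Domain-architecture diagram for pheromone calls
#'
#' One horizontal track per classified protein with its annotated
#' domains (signal peptide, complete/partial TFD, low-complexity tail)
#' drawn as spans.
#'
#' @param calls A call tibble from [annotate_pheromones()].
#' @return A ggplot.
#' @export
plot_domain_map <- function(calls) {
  calls <- calls[calls$class_label != "none", , drop = FALSE]
  if (nrow(calls) == 0L) stop("no classified proteins to plot")
  dom <- dplyr::bind_rows(purrr::map2(calls$orf_id, calls$domains,
                                      function(id, d) {
                                        d$orf_id <- id
                                        d
                                      }))
  ggplot2::ggplot(dom,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$orf_id, fill = .data$kind)) +
    ggplot2::geom_tile(ggplot2::aes(width = .data$end - .data$start),
                       height = 0.6) +
    ggplot2::labs(x = "Residue", y = NULL, fill = "Domain",
                  title = "Pheromone domain architecture") +
    ggplot2::theme_minimal()
}
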