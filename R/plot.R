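#' Plot a k-mer spectrum
#'
#' Bar-style spectrum plot: distinct k-mers per multiplicity bin. An
#' optional fitted curve (from [autofit()] or [manual_curve()]) is
#' overlaid in red.
#'
#' @param object A `kmer_spectrum`.
#' @param curve Optional tibble with `multiplicity` and `expected` columns.
#' @param log_y Plot counts on a log10 axis (often useful: the error tail
#'   dwarfs the coverage peaks).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kmer_spectrum
#' @export
autoplot.kmer_spectrum <- function(object, curve = NULL, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$multiplicity, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey55") +
    ggplot2::labs(x = "k-mer multiplicity", y = "distinct k-mers",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(x = .data$multiplicity,
                                             y = .data$expected),
                                colour = "red", linewidth = 0.8)
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a fitted spectrum model over the data
#'
#' Observed counts in the fit window with the fitted expected curve, plus
#' the rest of the spectrum in lighter grey for context.
#'
#' @param object A `kmerploidy_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kmerploidy_fit
#' @export
autoplot.kmerploidy_fit <- function(object, ...) {
  full <- object$spectrum
  d <- object$data
  ggplot2::ggplot() +
    ggplot2::geom_col(data = full,
                      ggplot2::aes(x = .data$multiplicity, y = .data$count),
                      width = 1, fill = "grey85") +
    ggplot2::geom_col(data = d,
                      ggplot2::aes(x = .data$multiplicity, y = .data$observed),
                      width = 1, fill = "grey55") +
    ggplot2::geom_line(data = d,
                       ggplot2::aes(x = .data$multiplicity, y = .data$fitted),
                       colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "k-mer multiplicity", y = "distinct k-mers",
                  title = sprintf("%s fit (window %d-%d)",
                                  object$params$model,
                                  object$window[1L], object$window[2L])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Convenience wrapper around the spectrum autoplot
#'
#' @inheritParams autoplot.kmer_spectrum
#' @param spectrum A `kmer_spectrum`.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, curve = NULL, log_y = FALSE) {
  autoplot.kmer_spectrum(spectrum, curve = curve, log_y = log_y)
}
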