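#' Plot the telomere class distribution of a read set
#'
#' @param annotation Per-read annotation from [classify_reads()].
#' @return A ggplot.
#' @export
plot_read_classes <- function(annotation) {
  lv <- c("none", "five_prime", "three_prime", "both_ends", "internal_only")
  ggplot2::ggplot(annotation,
                  ggplot2::aes(x = factor(.data$cls, levels = lv))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "telomere class", y = "reads") +
    ggplot2::theme_minimal()
}

#' Plot the ATAS support-count distribution
#'
#' Most ATASs are expected to be supported by a single read; the support
#' distribution is shown on a log10 count scale.
#'
#' @param calls Call tibble from [call_atas()].
#' @return A ggplot.
#' @export
plot_atas_support <- function(calls) {
  calls <- calls[!calls$is_terminus, , drop = FALSE]
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$n_support)) +
    ggplot2::geom_bar() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "supporting telomere-junction reads", y = "ATASs") +
    ggplot2::theme_minimal()
}

#' Plot a fold-change ranking curve
#'
#' @param fc Ranking tibble from [fold_change()].
#' @param k Optional top-set size to mark.
#' @return A ggplot.
#' @export
plot_fc_rank <- function(fc, k = NULL) {
  p <- ggplot2::ggplot(fc, ggplot2::aes(x = .data$rank, y = .data$fc)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "fold change (target / baseline mean)") +
    ggplot2::theme_minimal()
  if (!is.null(k)) {
    p <- p + ggplot2::geom_vline(xintercept = k, linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bootstrap distribution of a spacing estimate
#'
#' Histogram of the bootstrap draws with the point estimate and CI marked.
#'
#' @param object A [mean_spacing()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.spacing_estimate <- function(object, ...) {
  df <- tibble(m = object$boot[!is.na(object$boot)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$m_hat) +
    ggplot2::geom_vline(xintercept = c(object$ci_lower, object$ci_upper),
                        linetype = 2) +
    ggplot2::labs(x = "bootstrap mean molecule length (bp)", y = "draws") +
    ggplot2::theme_minimal()
}
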