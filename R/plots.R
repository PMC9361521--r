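# Quick-look plots for per-residue / per-peptide results.

#' Butterfly-style plot of per-peptide uptake differences
#'
#' @param summary Per-peptide summary from [delta_uptake()] or
#'   [wald_fdr()].
#' @return A ggplot.
#' @export
plot_uptake_difference <- function(summary) {
  d <- dplyr::mutate(summary, mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$avg_delta))
  if ("significant" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$significant))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$end,
      y = .data$avg_delta, yend = .data$avg_delta
    )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "residue", y = "average Δuptake (%)")
}

#' Per-residue chemical shift perturbation plot
#'
#' @param records Classified CSP records from [classify_csp()].
#' @param thresholds Threshold lines to draw (ppm).
#' @return A ggplot.
#' @export
plot_csp <- function(records, thresholds = c(0.07, 0.14)) {
  ggplot2::ggplot(
    dplyr::filter(records, !.data$missing),
    ggplot2::aes(x = .data$residue, y = .data$csp)
  ) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$category)) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = 3) +
    ggplot2::labs(x = "residue", y = "CSP (ppm)")
}
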