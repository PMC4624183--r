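#' Plot a coverage profile
#'
#' Windowed min/mean/max read depth along the genome, the standard
#' way mitochondrial RNA-Seq coverage is displayed (tRNA coverage
#' drops under poly(A) enrichment are directly visible).
#'
#' @param object A `coverage_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_profile <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = .data$start)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min, ymax = .data$max),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$mean),
      colour = "steelblue4"
    ) +
    ggplot2::labs(
      x = "genomic position (bp)",
      y = sprintf("read depth (%d-bp windows)", object$window)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot polyadenylation sites along the genome
#'
#' Read support of each site at its genomic coordinate, by strand;
#' the analogue of the poly(A) end-read distribution track.
#'
#' @param sites Site tibble from [aggregate_sites()] (or a
#'   `mitotail_run`).
#' @param min_support Draw a guide line at this support level.
#' @return A ggplot object.
#' @export
plot_sites <- function(sites, min_support = 3L) {
  if (inherits(sites, "mitotail_run")) sites <- sites$sites
  ggplot2::ggplot(
    sites,
    ggplot2::aes(
      x = .data$position, y = .data$support, colour = .data$strand
    )
  ) +
    ggplot2::geom_segment(ggplot2::aes(
      xend = .data$position, yend = 0
    )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = min_support, linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(
      x = "genomic position (bp)", y = "poly(A) end-read support",
      colour = "strand"
    ) +
    ggplot2::theme_minimal()
}
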