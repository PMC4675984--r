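#' Plot a TSS-anchored aggregate profile
#'
#' @param object a `bruuv_profile` from [aggregate_tss_profile()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bruuv_profile <- function(object, ...) {
  ylab <- if (isTRUE(attr(object, "normalized")))
    "median RPKM (relative to reference)" else "median RPKM"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset / 1000,
                                       y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "distance from TSS (kb)", y = ylab,
                  subtitle = sprintf("%d genes", attr(object, "n_regions"))) +
    ggplot2::theme_minimal()
}

#' Plot a per-gene TSS-anchored heat map
#'
#' @param object a `bruuv_heatmap` from [heatmap_matrix()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bruuv_heatmap <- function(object, ...) {
  df <- tibble(
    row = rep(seq_len(nrow(object$values)), each = ncol(object$values)),
    offset = rep(object$bin_offsets, nrow(object$values)),
    value = as.vector(t(object$values)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset / 1000, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "scaled\nsignal") +
    ggplot2::labs(x = "distance from TSS (kb)",
                  y = "genes (sorted by first-5-kb signal)") +
    ggplot2::theme_minimal()
}

#' Plot TSS activity calls
#'
#' Histogram of the Viterbi switch offsets relative to the annotated TSS,
#' split by activity call; the shaded band is the activity window.
#'
#' @param object a `bruuv_tss_fit` from [call_active_tss()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bruuv_tss_fit <- function(object, ...) {
  d <- filter(object$calls, !is.na(.data$transition_offset))
  wbp <- object$cfg$activity_window_bp
  ggplot2::ggplot(d, ggplot2::aes(x = .data$transition_offset,
                                  fill = .data$active)) +
    ggplot2::annotate("rect", xmin = -wbp, xmax = wbp,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_histogram(binwidth = object$cfg$bin_width,
                            boundary = 0) +
    ggplot2::labs(x = "state 1 -> 2 switch offset from TSS (bp)",
                  y = "TSS entries", fill = "active") +
    ggplot2::theme_minimal()
}

#' Plot a UV-enhancement segmentation
#'
#' Per-bin UV read fraction along one chromosome with called UVE peaks
#' shaded.
#'
#' @param object a `bruuv_uve_fit` from [call_uve_peaks()].
#' @param chrom chromosome to display (default: the first).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bruuv_uve_fit <- function(object, chrom = NULL, ...) {
  chrom <- chrom %||% object$states$chrom[1]
  st <- filter(object$states, .data$chrom == .env$chrom,
               !is.na(.data$fuv))
  pk <- filter(object$peaks, .data$chrom == .env$chrom)
  p <- ggplot2::ggplot(st, ggplot2::aes(x = .data$start / 1e6,
                                        y = .data$fuv)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_hline(
      yintercept = with(object$params$uvr, alpha / (alpha + beta)),
      linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom),
                  y = "UV read fraction per bin") +
    ggplot2::theme_minimal()
  if (nrow(pk) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = pk$start / 1e6,
                               xmax = pk$end / 1e6, ymin = -Inf,
                               ymax = Inf, alpha = 0.2, fill = "firebrick")
  }
  p
}
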