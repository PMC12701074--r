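# ggplot2 views of the main result types.

#' Plot the Calpha-Calpha distance distribution of mapped linkages
#'
#' @param records Distance records from [map_linkages()] (minimal distance
#'   per linkage is plotted).
#' @param threshold Satisfaction threshold line (default 30 A).
#' @param by Optional grouping column for facetting (e.g. `"intra"`).
#' @return A ggplot object.
#' @export
plot_distance_distribution <- function(records, threshold = 30, by = NULL) {
  m <- minimal_distances(records)
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = 2, boundary = 0, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Calpha-Calpha distance (A)", y = "linkages") +
    ggplot2::theme_minimal()
  if (!is.null(by)) p <- p + ggplot2::facet_wrap(by)
  p
}

#' Plot the score-vs-FDR curve of a target-decoy estimate
#'
#' @param x A `kcx_fdr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kcx_fdr <- function(x, ...) {
  d <- x$csms
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$q)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.01, linetype = "dotted") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "score threshold", y = "q-value",
                  title = sprintf("target-decoy FDR (%s level)", x$level)) +
    ggplot2::theme_minimal()
}

#' Plot a spectrum with optional theoretical annotations
#'
#' @param run A run tibble.
#' @param scan Scan id to plot.
#' @param annotate Optional tibble with columns `mz` and `label` for marker
#'   lines (e.g. signature fragment m/z values).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(run, scan, annotate = NULL) {
  row <- run[run$scan == scan, ]
  if (!nrow(row)) rlang::abort(paste0("no scan ", scan, " in run"))
  pk <- row$peaks[[1]]
  p <- ggplot2::ggplot(pk, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                        y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment(colour = "grey30") +
    ggplot2::labs(x = "m/z", y = "intensity",
                  title = sprintf("scan %d (MS%d)", row$scan, row$ms_level)) +
    ggplot2::theme_minimal()
  if (!is.null(annotate)) {
    p <- p + ggplot2::geom_vline(data = annotate,
                                 ggplot2::aes(xintercept = .data$mz),
                                 colour = "firebrick", linetype = "dashed")
  }
  p
}

#' Plot per-complex subunit recovery
#'
#' @param coverage Output of [complex_coverage()].
#' @return A ggplot object.
#' @export
plot_complex_coverage <- function(coverage) {
  ggplot2::ggplot(coverage$histogram,
                  ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "recovered subunit fraction", y = "complexes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
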