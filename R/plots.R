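#' Barplot of per-sample fusion category fractions
#'
#' @param fractions data.frame from [category_fractions()].
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_category_fractions <- function(fractions, ...) {
  m <- t(as.matrix(fractions[, fusion_classes()]))
  colnames(m) <- fractions$sample_id
  graphics::barplot(m, legend.text = rownames(m),
                    ylab = "fraction of fusion calls",
                    col = c("firebrick", "grey60", "steelblue"), ...)
}

#' Histogram of junction exon ranks
#'
#' @param hist_result list from [exon_position_histogram()].
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_exon_position_histogram <- function(hist_result, ...) {
  graphics::barplot(hist_result$counts, xlab = "exon rank",
                    ylab = "fusion junctions", col = "steelblue", ...)
}

#' Empirical CDFs of a sample against its genome background
#'
#' @param sample,background numeric vectors (e.g. intergenic distances of
#'   final pairs vs all same-strand immediate pairs).
#' @param xlab x-axis label.
#' @param log_x plot on a log10 x axis (default TRUE; zeros offset by 1).
#' @return Invisibly, NULL.
#' @export
plot_background_ecdf <- function(sample, background,
                                 xlab = "intergenic distance (bp)",
                                 log_x = TRUE) {
  tx <- if (log_x) function(v) log10(v + 1) else identity
  graphics::plot(stats::ecdf(tx(background)), main = "",
                 xlab = if (log_x) paste0("log10 ", xlab) else xlab,
                 ylab = "cumulative fraction", col = "grey40")
  graphics::lines(stats::ecdf(tx(sample)), col = "firebrick")
  graphics::legend("bottomright", legend = c("background", "sample"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(NULL)
}
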