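## Base-graphics plotting helpers.  Every figure is backed by a tabular
## result object, so tests and downstream analyses read the data, never the
## image.

#' Rank histogram of per-chromosome DEG percentages
#'
#' Descending barplot of DEG percentages with the X chromosome highlighted —
#' the standard ranking view of a chromosome-level response.
#'
#' @param x `chrom_summary`.
#' @param class `"up"`, `"down"` or `"deg"`.
#' @param x_chrom chromosome highlighted in red.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.chrom_summary <- function(x, class = c("up", "down", "deg"),
                               x_chrom = "chrX", ...) {
  class <- match.arg(class)
  pct <- x[[paste0("pct_", class)]]
  ord <- order(x[[paste0("rank_", class)]])
  cols <- ifelse(x$chrom[ord] == x_chrom, "firebrick", "grey60")
  graphics::barplot(pct[ord], names.arg = sub("^chr", "", x$chrom[ord]),
                    col = cols, las = 2,
                    ylab = sprintf("%% %sregulated DEGs",
                                   ifelse(class == "deg", "", class)),
                    ...)
  invisible(x)
}

#' Empirical CDF comparison of fold-change groups
#'
#' Overlaid empirical cumulative distributions of per-gene log2 fold changes,
#' the visual companion of the Kolmogorov-Smirnov comparisons.
#'
#' @param groups named list of numeric vectors (e.g. X, control chromosome,
#'   autosomes).
#' @param xlim x-axis limits (defaults to the pooled range, trimmed).
#' @param ... passed through to [graphics::plot()].
#' @export
plot_cdf <- function(groups, xlim = NULL, ...) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  vals <- unlist(groups)
  if (is.null(xlim)) xlim <- stats::quantile(vals, c(0.005, 0.995), na.rm = TRUE)
  cols <- grDevices::hcl.colors(length(groups), "Dark 2")
  graphics::plot(NA, xlim = xlim, ylim = c(0, 1),
                 xlab = "log2 fold change", ylab = "cumulative fraction", ...)
  for (i in seq_along(groups)) {
    f <- stats::ecdf(groups[[i]])
    xs <- sort(groups[[i]])
    graphics::lines(xs, f(xs), col = cols[i], lwd = 2, type = "s")
  }
  graphics::legend("bottomright", legend = names(groups), col = cols,
                   lwd = 2, bty = "n")
  invisible(NULL)
}

#' Windowed density track profile
#' @param x `density_track`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.density_track <- function(x, ...) {
  graphics::plot((x$start + x$end) / 2 / 1e6, x$value, type = "l",
                 xlab = sprintf("%s position (Mbp)", attr(x, "chrom")),
                 ylab = sprintf("density (%s)", attr(x, "mode")), ...)
  invisible(x)
}

#' Scatter plot of X-linked DEGs along the chromosome
#'
#' log2 fold change against genomic position; upregulated DEGs in red
#' (escape genes orange), downregulated in blue (escape cyan), XIST in
#' green.
#'
#' @param pos_table output of [deg_position_table()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_deg_positions <- function(pos_table, ...) {
  col <- ifelse(pos_table$is_xist, "darkgreen",
         ifelse(pos_table$direction == "up",
                ifelse(pos_table$escape, "orange", "firebrick"),
                ifelse(pos_table$escape, "cyan3", "steelblue")))
  graphics::plot(pos_table$position / 1e6, pos_table$log2fc, pch = 19,
                 col = col, xlab = "position (Mbp)",
                 ylab = "log2 fold change", ...)
  graphics::abline(h = c(-0.58, 0.58), lty = 3, col = "grey50")
  if (any(pos_table$is_xist))
    graphics::text(pos_table$position[pos_table$is_xist] / 1e6,
                   pos_table$log2fc[pos_table$is_xist], "XIST", pos = 3)
  invisible(pos_table)
}
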