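## density: sliding-window density tracks along a chromosome and the
## Pearson / partial / cross-dataset correlation layer on top of them.
## Default grid: 1 Mbp windows advanced in 250 kbp steps, so each position
## falls in up to four overlapping windows.

#' Gene midpoint
#'
#' `floor((start + end) / 2)` on the internal half-open interval — genomic
#' positions for scatter plots and count-mode density tracks.
#'
#' @param start,end interval bounds (bp, `start < end`); vectorized.
#' @return integer midpoint(s).
#' @export
midpoint <- function(start, end) {
  if (any(start >= end)) stopf("midpoint needs start < end")
  floor((start + end) / 2)
}

#' Sliding windows along a chromosome
#'
#' Full windows only: starts at `0, step, 2*step, ...` with
#' `floor((L - window)/step) + 1` windows for `L >= window`; a chromosome
#' shorter than one window yields a single truncated window `[0, L)`.
#'
#' @param chrom_length chromosome length in bp.
#' @param window window size in bp (default 1 Mbp).
#' @param step step size in bp (default 250 kbp; must not exceed `window`).
#' @return data.frame with `start`, `end`; attributes `window`, `step`,
#'   `truncated`.
#' @examples
#' nrow(make_windows(2e6))  # 5
#' @export
make_windows <- function(chrom_length, window = 1e6, step = 2.5e5) {
  if (window <= 0 || step <= 0) stopf("window and step must be positive")
  if (step > window) stopf("step must not exceed window")
  if (chrom_length < window) {
    out <- data.frame(start = 0, end = chrom_length)
    attr(out, "truncated") <- TRUE
  } else {
    starts <- seq(0, by = step, length.out = floor((chrom_length - window) / step) + 1)
    out <- data.frame(start = starts, end = starts + window)
    attr(out, "truncated") <- FALSE
  }
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Windowed density track of genomic features
#'
#' `count` mode counts feature midpoints falling in `[start, start + window)`
#' (a midpoint contributes to every overlapping window); `coverage` mode is
#' overlapped base pairs divided by window size.
#'
#' @param features data.frame with `start`, `end` (and optionally `chrom`) on
#'   one chromosome, or a numeric vector of midpoints (count mode only).
#' @param windows window grid from [make_windows()].
#' @param mode `"count"` or `"coverage"`.
#' @param chrom chromosome label stored on the track.
#' @return data.frame of class `density_track` with `start`, `end`, `value`;
#'   attributes `window`, `step`, `mode`, `chrom`.
#' @export
density_track <- function(features, windows, mode = c("count", "coverage"),
                          chrom = NA_character_) {
  mode <- match.arg(mode)
  if (is.numeric(features) && is.null(dim(features))) {
    if (mode == "coverage") stopf("coverage mode needs start/end intervals")
    mids <- features
  } else {
    if (!is.null(features$chrom) && length(unique(features$chrom)) > 1)
      stopf("features span multiple chromosomes; track one at a time")
    mids <- if (mode == "count") midpoint(features$start, features$end) else NULL
  }
  if (mode == "count") {
    mids <- sort(mids)
    # half-open membership via counts of midpoints strictly below each bound
    value <- findInterval(windows$end - 0.5, mids) -
             findInterval(windows$start - 0.5, mids)
  } else {
    value <- vapply(seq_len(nrow(windows)), function(i) {
      ov <- pmin(features$end, windows$end[i]) - pmax(features$start, windows$start[i])
      sum(pmax(ov, 0)) / (windows$end[i] - windows$start[i])
    }, 1.0)
  }
  out <- data.frame(start = windows$start, end = windows$end, value = value)
  attr(out, "window") <- attr(windows, "window")
  attr(out, "step") <- attr(windows, "step")
  attr(out, "mode") <- mode
  attr(out, "chrom") <- chrom
  class(out) <- c("density_track", "data.frame")
  out
}

correlation_result <- function(r, p, n, kind, controlled_for = NA_character_) {
  structure(list(r = r, p = p, n = n, kind = kind,
                 controlled_for = controlled_for),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  ctl <- if (!is.na(x$controlled_for)) sprintf(" | %s", x$controlled_for) else ""
  cat(sprintf("%s correlation%s: R = %.4f, p = %.3g (n = %d)\n",
              x$kind, ctl, x$r, x$p, x$n))
  invisible(x)
}

#' Pearson correlation of two density tracks
#'
#' Sample Pearson r with a two-sided p from the t distribution on `n - 2`
#' degrees of freedom. Constant input is an error (r undefined).
#'
#' @param x,y equal-length numeric vectors (or `density_track`s).
#' @return `correlation_result` with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  x <- track_values(x); y <- track_values(y)
  if (length(x) != length(y)) stopf("tracks must have equal length")
  if (length(x) < 3) stopf("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  correlation_result(unname(ct$estimate), ct$p.value, length(x), "pearson")
}

#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, the
#' correlation between x and y after removing the linear effect of z
#' (identically, the Pearson correlation of the least-squares residuals of x
#' on z and y on z). Two-sided p from the t distribution on `n - 3` degrees
#' of freedom.
#'
#' @param x,y,z equal-length numeric vectors (or `density_track`s), n >= 4.
#' @param controlled_for label recorded on the result.
#' @return `correlation_result` of kind `"partial"`.
#' @examples
#' # from the pairwise correlations alone:
#' # r_xy = 0.9, r_xz = r_yz = 0.8  ->  0.26 / 0.36 = 0.7222
#' @export
partial_correlation <- function(x, y, z, controlled_for = "z") {
  x <- track_values(x); y <- track_values(y); z <- track_values(z)
  n <- length(x)
  if (length(y) != n || length(z) != n) stopf("vectors must have equal length")
  if (n < 4) stopf("partial correlation needs n >= 4")
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stopf("control variable is collinear with an input; partial correlation undefined")
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- max(min(r, 1), -1)
  tt <- r * sqrt((n - 3) / (1 - r^2))
  correlation_result(r, 2 * stats::pt(-abs(tt), df = n - 3), n, "partial",
                     controlled_for)
}

track_values <- function(x) {
  if (inherits(x, "density_track")) x$value else as.numeric(x)
}

#' X-linked DEG positions for scatter plots
#'
#' One row per DEG on the chosen chromosome: genomic position (midpoint of
#' the gene), log2 fold change, direction, XCI-escape flag, and a flag for
#' the XIST gene itself (conventionally highlighted).
#'
#' @param de `de_table` with `deg_class` filled.
#' @param ann [genome_annotation()].
#' @param chrom chromosome (default `"chrX"`).
#' @param xci optional named XCI status vector.
#' @param xist_gene gene id/symbol to flag as XIST.
#' @return data.frame `gene_id`, `position`, `log2fc`, `direction`,
#'   `escape`, `is_xist`, ordered by position.
#' @export
deg_position_table <- function(de, ann, chrom = "chrX", xci = NULL,
                               xist_gene = "XIST") {
  g <- ann$genes
  degs <- de[de$deg_class %in% c("up", "down"), ]
  idx <- match(degs$gene_id, g$gene_id)
  on_chrom <- !is.na(idx) & g$chrom[idx] == chrom
  degs <- degs[on_chrom, ]; idx <- idx[on_chrom]
  if (nrow(degs) == 0)
    return(data.frame(gene_id = character(), position = numeric(),
                      log2fc = numeric(), direction = character(),
                      escape = logical(), is_xist = logical()))
  out <- data.frame(gene_id = degs$gene_id,
                    position = midpoint(g$start[idx], g$end[idx]),
                    log2fc = degs$log2fc, direction = degs$deg_class,
                    stringsAsFactors = FALSE)
  out$escape <- if (is.null(xci)) FALSE
                else !is.na(xci[out$gene_id]) & xci[out$gene_id] == "escape"
  out$is_xist <- out$gene_id == xist_gene
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  out
}

#' Correlation of one density track across datasets
#'
#' Pearson correlation of two tracks (e.g. X-linked DEG densities of two
#' clonal lines) on an identical window grid.
#'
#' @param track_a,track_b `density_track`s on the same grid.
#' @return `correlation_result`.
#' @export
cross_dataset_correlation <- function(track_a, track_b) {
  if (!identical(track_a$start, track_b$start) ||
      !identical(track_a$end, track_b$end))
    stopf("window grids differ; rebuild tracks with a shared window/step")
  pearson(track_a, track_b)
}

#' Density tracks and correlations for one dataset's X chromosome
#'
#' Builds the windowed density tracks used in the positional analysis — DEGs
#' (all, up, down), all genes, SINEs and LINEs — and correlates each DEG
#' track with gene, SINE and LINE density, plus the partial correlation of
#' each DEG track with SINE density controlling for gene density, and the
#' SINE-LINE correlation.
#'
#' @param de `de_table`.
#' @param ann [genome_annotation()].
#' @param repeats `repeat_track` (may be `NULL`: repeat correlations skipped).
#' @param chrom chromosome analyzed (default `"chrX"`).
#' @param window,step window grid in bp.
#' @param mode density mode for repeats (`"count"` or `"coverage"`); gene and
#'   DEG tracks always use midpoint counts.
#' @return list of class `density_analysis`: `tracks` (named list of
#'   `density_track`s), `correlations` (data.frame).
#' @export
density_correlations <- function(de, ann, repeats = NULL, chrom = "chrX",
                                 window = 1e6, step = 2.5e5,
                                 mode = c("count", "coverage")) {
  mode <- match.arg(mode)
  g <- ann$genes[ann$genes$chrom == chrom, ]
  if (nrow(g) == 0) stopf("no genes on %s", chrom)
  win <- make_windows(ann$chrom_lengths[[chrom]], window = window, step = step)
  dc <- de$deg_class[match(g$gene_id, de$gene_id)]
  dc[is.na(dc)] <- "none"
  tracks <- list(
    genes = density_track(g, win, "count", chrom = chrom),
    deg_all = density_track(g[dc %in% c("up", "down"), ], win, "count", chrom = chrom),
    deg_up = density_track(g[dc == "up", ], win, "count", chrom = chrom),
    deg_down = density_track(g[dc == "down", ], win, "count", chrom = chrom)
  )
  if (!is.null(repeats)) {
    rc <- repeats[repeats$chrom == chrom, ]
    tracks$sine <- density_track(rc[rc$repeat_class == "SINE", ], win, mode,
                                 chrom = chrom)
    tracks$line <- density_track(rc[rc$repeat_class == "LINE", ], win, mode,
                                 chrom = chrom)
  }
  rows <- list()
  add <- function(label, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      pair = label, kind = res$kind, controlled_for = res$controlled_for,
      r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
  }
  safe_pearson <- function(a, b) tryCatch(pearson(a, b), error = function(e) NULL)
  for (deg in c("deg_all", "deg_up", "deg_down")) {
    others <- c("genes", if (!is.null(repeats)) c("sine", "line"))
    for (other in others) {
      res <- safe_pearson(tracks[[deg]], tracks[[other]])
      if (!is.null(res)) add(paste(deg, "vs", other), res)
    }
    if (!is.null(repeats)) {
      res <- tryCatch(
        partial_correlation(tracks[[deg]], tracks$sine, tracks$genes,
                            controlled_for = "genes"),
        error = function(e) NULL)
      if (!is.null(res)) add(paste(deg, "vs sine"), res)
    }
  }
  if (!is.null(repeats)) {
    res <- safe_pearson(tracks$sine, tracks$line)
    if (!is.null(res)) add("sine vs line", res)
  }
  structure(list(tracks = tracks,
                 correlations = do.call(rbind, rows)),
            class = "density_analysis")
}

#' @export
print.density_analysis <- function(x, ...) {
  cat(sprintf("density_analysis on %s: %d windows, tracks: %s\n",
              attr(x$tracks[[1]], "chrom"), nrow(x$tracks[[1]]),
              paste(names(x$tracks), collapse = ", ")))
  df <- x$correlations
  df$r <- round(df$r, 4); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
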