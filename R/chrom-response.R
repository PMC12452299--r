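## chrom_response: per-chromosome DEG percentages and rankings, two-proportion
## Z tests of the X against pooled autosomes, control-chromosome selection and
## Kolmogorov-Smirnov distribution-shift comparisons of per-gene fold changes.

#' Per-chromosome DEG percentages and rankings
#'
#' For each chromosome, the percentage of DEGs (up, down, and combined) is the
#' number of DEGs on the chromosome divided by the total number of annotated
#' genes on it, times 100. Chromosomes are ranked by descending percentage
#' (rank 1 = highest); ties break by chromosome name order. The Y chromosome
#' and mitochondrial/unplaced sequences are excluded from the ranking universe
#' (the X is ranked among 23 chromosomes in human-like annotations, 20 in
#' mouse-like ones). DE genes absent from the annotation are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param de `de_table` with `deg_class` filled.
#' @param ann [genome_annotation()].
#' @param exclude chromosomes dropped from the universe.
#' @return data.frame of class `chrom_summary` with one row per chromosome:
#'   `chrom`, `n_genes`, `n_up`, `n_down`, `n_deg`, `pct_up`, `pct_down`,
#'   `pct_deg`, `rank_up`, `rank_down`, `rank_deg`.
#' @export
chrom_deg_percentages <- function(de, ann, exclude = c("chrY", "chrM", "chrMT")) {
  genes <- ann$genes[!(ann$genes$chrom %in% exclude), ]
  chroms <- sort_chroms(unique(genes$chrom))
  idx <- match(de$gene_id, genes$gene_id)
  n_excluded <- sum(is.na(idx))
  de_chrom <- genes$chrom[idx]
  cnt <- function(cls) {
    hit <- de$deg_class == cls & !is.na(idx)
    tab <- table(factor(de_chrom[hit], levels = chroms))
    as.integer(tab)
  }
  n_genes <- as.integer(table(factor(genes$chrom, levels = chroms)))
  out <- data.frame(chrom = chroms, n_genes = n_genes,
                    n_up = cnt("up"), n_down = cnt("down"),
                    stringsAsFactors = FALSE)
  out$n_deg <- out$n_up + out$n_down
  for (cls in c("up", "down", "deg")) {
    pct <- 100 * out[[paste0("n_", cls)]] / out$n_genes
    out[[paste0("pct_", cls)]] <- pct
    # descending percentage; ties broken by natural chromosome name order,
    # which is already the row order
    out[[paste0("rank_", cls)]] <- rank_descending(pct)
  }
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("chrom_summary", "data.frame")
  out
}

rank_descending <- function(pct) {
  ord <- order(-pct, seq_along(pct))
  rk <- integer(length(pct))
  rk[ord] <- seq_along(pct)
  rk
}

#' @export
print.chrom_summary <- function(x, ...) {
  cat(sprintf("chrom_summary: %d chromosomes, %d DEGs mapped (%d excluded)\n",
              nrow(x), sum(x$n_deg), attr(x, "n_excluded") %||% 0L))
  df <- as.data.frame(x)
  for (col in intersect(c("pct_up", "pct_down", "pct_deg"), names(df)))
    df[[col]] <- round(df[[col]], 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pooled two-proportion Z test
#'
#' `z = (k1/n1 - k2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled
#' proportion `p = (k1 + k2)/(n1 + n2)`; two-sided p from the standard
#' normal. The two-sided p equals the p of a chi-square test without
#' continuity correction on the same 2x2 table. A degenerate pooled
#' proportion of 0 or 1 yields `z = 0`, `p = 1`, flagged via the
#' `degenerate` field.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `z`, `p`, `p1`, `p2`, `degenerate`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p_hat <- (k1 + k2) / (n1 + n2)
  if (p_hat == 0 || p_hat == 1)
    return(list(z = 0, p = 1, p1 = k1 / n1, p2 = k2 / n2, degenerate = TRUE))
  z <- (k1 / n1 - k2 / n2) / sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = k1 / n1, p2 = k2 / n2,
       degenerate = FALSE)
}

#' Z tests of the X chromosome and of the top-ranked chromosome
#'
#' For each DEG class (up, down, combined), tests (a) the X chromosome's DEG
#' proportion against the pooled autosomes and (b) the top-ranked
#' chromosome's proportion against the pooled remaining chromosomes.
#'
#' @param summary `chrom_summary` from [chrom_deg_percentages()].
#' @param x_chrom name of the X chromosome.
#' @return data.frame with one row per (comparison, class): `comparison`,
#'   `class`, `chrom`, `z`, `p`, `degenerate`.
#' @export
x_vs_autosome_tests <- function(summary, x_chrom = "chrX") {
  if (!(x_chrom %in% summary$chrom)) stopf("%s not in summary", x_chrom)
  auto <- summary[is_autosome(summary$chrom), ]
  xrow <- summary[summary$chrom == x_chrom, ]
  rows <- list()
  for (cls in c("up", "down", "deg")) {
    k <- paste0("n_", cls)
    zt <- two_proportion_z(xrow[[k]], xrow$n_genes, sum(auto[[k]]), sum(auto$n_genes))
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "X_vs_autosomes", class = cls, chrom = x_chrom,
      z = zt$z, p = zt$p, degenerate = zt$degenerate)
    top <- summary$chrom[summary[[paste0("rank_", cls)]] == 1]
    rest <- summary[summary$chrom != top, ]
    trow <- summary[summary$chrom == top, ]
    zt2 <- two_proportion_z(trow[[k]], trow$n_genes, sum(rest[[k]]), sum(rest$n_genes))
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "top_vs_rest", class = cls, chrom = top,
      z = zt2$z, p = zt2$p, degenerate = zt2$degenerate)
  }
  do.call(rbind, rows)
}

#' Pick the autosome with gene count closest to the X
#'
#' The analysis contrasts the X with a control autosome of similar gene
#' content (chromosome 9 in human annotations, chromosome 10 in mouse).
#' Ties break by chromosome name order.
#'
#' @param ann [genome_annotation()].
#' @param target chromosome whose gene count is matched.
#' @return chromosome name.
#' @export
pick_control_chromosome <- function(ann, target = "chrX") {
  tab <- table(ann$genes$chrom)
  if (!(target %in% names(tab))) stopf("target chromosome %s has no genes", target)
  autos <- names(tab)[is_autosome(names(tab))]
  if (length(autos) == 0) stopf("no autosome in annotation")
  autos <- sort_chroms(autos)
  d <- abs(as.numeric(tab[autos]) - as.numeric(tab[target]))
  autos[which.min(d)]  # which.min takes the first minimum = name-order winner
}

#' Two-sample Kolmogorov-Smirnov distribution comparison
#'
#' Compares two sets of per-gene log2 fold changes (e.g. X-linked vs
#' autosomal) with the exact two-sample D statistic and the asymptotic
#' two-sided p. `median_shift` is `median(a) - median(b)`; the direction is
#' `"right"` (A shifted up) or `"left"` only when the test is significant at
#' `alpha`.
#'
#' @param a,b numeric vectors (non-empty; NAs dropped).
#' @param labels length-2 character vector naming the groups.
#' @param alpha significance level gating the direction call.
#' @return list of class `distribution_comparison`: `labels`, `D`, `p`,
#'   `median_shift`, `direction`, `n`.
#' @export
compare_distributions <- function(a, b, labels = c("A", "B"), alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stopf("both groups must be non-empty")
  ks <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  shift <- stats::median(a) - stats::median(b)
  direction <- if (ks$p.value < alpha && shift > 0) "right"
               else if (ks$p.value < alpha && shift < 0) "left" else "none"
  structure(list(labels = labels, D = unname(ks$statistic),
                 p = ks$p.value, median_shift = shift,
                 direction = direction, n = c(length(a), length(b))),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("KS %s (n=%d) vs %s (n=%d): D = %.4f, p = %.3g, median shift %+.4f [%s]\n",
              x$labels[1], x$n[1], x$labels[2], x$n[2], x$D, x$p,
              x$median_shift, x$direction))
  invisible(x)
}

#' Panel of KS comparisons for one dataset
#'
#' The three pairwise fold-change distribution comparisons run per dataset:
#' X vs pooled autosomes, control chromosome vs the other autosomes, and X vs
#' control chromosome. The fold-change universe is every gene with a
#' non-missing log2 fold change (optionally restricted to an
#' expressed-gene subset).
#'
#' @param de `de_table`.
#' @param ann [genome_annotation()].
#' @param control_chrom control autosome; `"auto"` picks via
#'   [pick_control_chromosome()].
#' @param x_chrom X chromosome name.
#' @param universe optional character vector of gene ids restricting the
#'   comparison (e.g. expressed genes only).
#' @return list of three `distribution_comparison` objects named
#'   `X_vs_autosomes`, `control_vs_autosomes`, `X_vs_control`.
#' @export
ks_panel <- function(de, ann, control_chrom = "auto", x_chrom = "chrX",
                     universe = NULL) {
  if (identical(control_chrom, "auto"))
    control_chrom <- pick_control_chromosome(ann, target = x_chrom)
  keep <- !is.na(de$log2fc)
  if (!is.null(universe)) keep <- keep & de$gene_id %in% universe
  chrom <- ann$genes$chrom[match(de$gene_id, ann$genes$gene_id)]
  keep <- keep & !is.na(chrom)
  lfc <- de$log2fc[keep]; chrom <- chrom[keep]
  x_vals <- lfc[chrom == x_chrom]
  c_vals <- lfc[chrom == control_chrom]
  auto_vals <- lfc[is_autosome(chrom)]
  # pooled autosomes exclude the compared chromosome itself
  auto_minus_c <- lfc[is_autosome(chrom) & chrom != control_chrom]
  list(
    X_vs_autosomes = compare_distributions(x_vals, auto_vals,
                                           c(x_chrom, "autosomes")),
    control_vs_autosomes = compare_distributions(c_vals, auto_minus_c,
                                                 c(control_chrom, "autosomes")),
    X_vs_control = compare_distributions(x_vals, c_vals,
                                         c(x_chrom, control_chrom))
  )
}

#' Tabulate a KS panel
#' @param panel list returned by [ks_panel()].
#' @return data.frame with one row per comparison.
#' @export
ks_panel_table <- function(panel) {
  do.call(rbind, lapply(names(panel), function(nm) {
    p <- panel[[nm]]
    data.frame(comparison = nm, group_a = p$labels[1], group_b = p$labels[2],
               n_a = p$n[1], n_b = p$n[2], D = p$D, p = p$p,
               median_shift = p$median_shift, direction = p$direction)
  }))
}
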