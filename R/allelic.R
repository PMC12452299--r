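## allelic: allele-specific expression.  The allelic ratio
## AR = min(refCount, altCount) / (refCount + altCount) folds the minor allele
## fraction into [0, 0.5]: 0 = fully monoallelic, 0.5 = balanced biallelic.

#' Per-SNP allelic ratio
#'
#' `min(ref, alt) / (ref + alt)`, missing when the total read count is below
#' `min_total` (default 10, the usual informative-SNP cutoff). Symmetric in
#' ref/alt by construction.
#'
#' @param ref,alt non-negative read counts (vectorized).
#' @param min_total minimum total reads for an informative SNP.
#' @return allelic ratio in `[0, 0.5]`, or `NA` below the cutoff.
#' @examples
#' allelic_ratio(30, 10)  # 0.25
#' allelic_ratio(4, 5)    # NA, total below 10
#' @export
allelic_ratio <- function(ref, alt, min_total = 10) {
  if (any(ref < 0 | alt < 0, na.rm = TRUE)) stopf("negative read counts")
  total <- ref + alt
  ifelse(total >= min_total & total > 0, pmin(ref, alt) / total, NA_real_)
}

#' Aggregate SNP-level allelic ratios to one gene-level AR
#'
#' Two aggregation modes. `weighted_mean` (default): read-count-weighted mean
#' of per-SNP ARs — robust to SNPs skewed toward opposite alleles.
#' `sum_counts`: fold the summed ref/alt counts — pooling min-folded counts
#' across SNPs with opposite skews can fabricate biallelic signal, which is
#' why it is not the default. Only SNPs passing `min_total` contribute.
#'
#' @param ref,alt per-SNP read counts for one gene in one sample.
#' @param aggregation `"weighted_mean"` or `"sum_counts"`.
#' @param min_total per-SNP total-read cutoff.
#' @return gene-level AR, or `NA` when no SNP passes.
#' @export
gene_ar <- function(ref, alt, aggregation = c("weighted_mean", "sum_counts"),
                    min_total = 10) {
  aggregation <- match.arg(aggregation)
  ar <- allelic_ratio(ref, alt, min_total = min_total)
  pass <- !is.na(ar)
  if (!any(pass)) return(NA_real_)
  if (aggregation == "weighted_mean") {
    w <- (ref + alt)[pass]
    sum(w * ar[pass]) / sum(w)
  } else {
    r <- sum(ref[pass]); a <- sum(alt[pass])
    min(r, a) / (r + a)
  }
}

#' Per-gene allelic-ratio table with knockdown deltas and classification
#'
#' Aggregates an allele-count table to one AR per gene and sample, computes
#' `dAR = AR_KD - AR_CTRL` for every knockdown clone, classifies each gene's
#' AR change ([classify_ar_change()]) and attaches XCI status. Genes where
#' the two aggregation modes disagree by more than 0.05 are flagged
#' (`aggregation_disagrees`), surfacing phase-blind pooling hazards.
#'
#' @param ac [allele_counts()] table.
#' @param xci named status vector from [read_xci_status()] (optional).
#' @param control control sample id.
#' @param kd_samples character vector of knockdown sample ids.
#' @param min_total per-SNP total-read cutoff.
#' @param aggregation per-gene SNP aggregation mode (see [gene_ar()]).
#' @return data.frame of class `ar_table`: one row per gene with `ar_ctrl`,
#'   `ar_<kd>` and `dar_<kd>` columns per clone, `n_snps`, `total_reads`,
#'   `xci_status`, `ar_class`, `aggregation_disagrees`.
#' @export
ar_table <- function(ac, xci = NULL, control, kd_samples,
                     min_total = 10, aggregation = "weighted_mean") {
  samples <- c(control, kd_samples)
  absent <- setdiff(samples, unique(ac$sample_id))
  if (length(absent) > 0)
    stopf("sample(s) absent from allele counts: %s", paste(absent, collapse = ", "))
  genes <- sort(unique(ac$gene_id))
  per_sample <- function(s, mode) {
    sub <- ac[ac$sample_id == s, ]
    vapply(genes, function(g) {
      rows <- sub[sub$gene_id == g, ]
      if (nrow(rows) == 0) return(NA_real_)
      gene_ar(rows$ref_count, rows$alt_count, aggregation = mode,
              min_total = min_total)
    }, 1.0)
  }
  ar <- vapply(samples, per_sample, numeric(length(genes)), mode = aggregation)
  ar_other <- vapply(samples, per_sample, numeric(length(genes)),
                     mode = setdiff(c("weighted_mean", "sum_counts"), aggregation))
  if (length(genes) == 1) {
    ar <- matrix(ar, nrow = 1, dimnames = list(NULL, samples))
    ar_other <- matrix(ar_other, nrow = 1, dimnames = list(NULL, samples))
  }
  ctrl_sub <- ac[ac$sample_id == control, ]
  n_snps <- vapply(genes, function(g) sum(ctrl_sub$gene_id == g), 1L)
  reads <- vapply(genes, function(g) {
    r <- ac[ac$gene_id == g, ]; sum(r$ref_count + r$alt_count)
  }, 1.0)
  out <- data.frame(gene_id = genes, n_snps = n_snps, total_reads = reads,
                    ar_ctrl = ar[, control], stringsAsFactors = FALSE)
  for (s in kd_samples) {
    out[[paste0("ar_", s)]] <- ar[, s]
    out[[paste0("dar_", s)]] <- ar[, s] - ar[, control]
  }
  out$ar_class <- vapply(seq_along(genes), function(i)
    classify_ar_change(ar[i, control], ar[i, kd_samples]), "")
  out$aggregation_disagrees <- apply(abs(ar - ar_other) > 0.05, 1, any,
                                     na.rm = TRUE)
  out$xci_status <- if (is.null(xci)) "unknown"
                    else unname(ifelse(is.na(xci[genes]), "unknown", xci[genes]))
  rownames(out) <- NULL
  attr(out, "control") <- control
  attr(out, "kd_samples") <- kd_samples
  class(out) <- c("ar_table", "data.frame")
  out
}

#' Classify a gene's allelic-ratio change across knockdown clones
#'
#' `"up"` iff every clone's dAR is strictly positive, `"down"` iff every one
#' is strictly negative, `"discordant"` otherwise (including any exact zero),
#' `"incomplete"` when the control AR or any clone AR is missing.
#'
#' @param ar_ctrl control AR.
#' @param ar_kd numeric vector of per-clone ARs.
#' @return one of `"up"`, `"down"`, `"discordant"`, `"incomplete"`.
#' @export
classify_ar_change <- function(ar_ctrl, ar_kd) {
  if (is.na(ar_ctrl) || any(is.na(ar_kd))) return("incomplete")
  d <- ar_kd - ar_ctrl
  if (all(d > 0)) "up" else if (all(d < 0)) "down" else "discordant"
}

#' Escape-vs-inactive contingency table and Fisher's exact test
#'
#' Cross-tabulates concordant AR changes (up/down in all clones) against XCI
#' status (escape vs inactive; variable/unknown excluded). Reports the sample
#' odds ratio `ad/bc` alongside the exact two-sided Fisher p (sum of
#' hypergeometric outcomes no more likely than the observed table). A zero
#' margin leaves the odds ratio undefined (`NA`) but the p is still computed.
#'
#' @param ar_tab `ar_table`, or a 2x2 matrix (rows escape/inactive, columns
#'   up/down).
#' @return list of class `xci_contingency`: `table`, `odds_ratio`, `p`.
#' @export
xci_contingency <- function(ar_tab) {
  if (inherits(ar_tab, "ar_table") || is.data.frame(ar_tab)) {
    sub <- ar_tab[ar_tab$xci_status %in% c("escape", "inactive") &
                  ar_tab$ar_class %in% c("up", "down"), ]
    tab <- table(factor(sub$xci_status, levels = c("escape", "inactive")),
                 factor(sub$ar_class, levels = c("up", "down")))
    tab <- matrix(as.integer(tab), 2, 2,
                  dimnames = list(c("escape", "inactive"), c("up", "down")))
  } else {
    tab <- as.matrix(ar_tab)
    stopifnot(all(dim(tab) == c(2, 2)))
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b == 0 || c_ == 0 || a + b == 0 || c_ + d == 0 ||
            a + c_ == 0 || b + d == 0) {
    if (b * c_ > 0) (a * d) / (b * c_) else NA_real_
  } else (a * d) / (b * c_)
  p <- if (sum(tab) == 0) 1 else stats::fisher.test(tab)$p.value
  structure(list(table = tab, odds_ratio = or, p = p),
            class = "xci_contingency")
}

#' @export
print.xci_contingency <- function(x, ...) {
  print(x$table)
  cat(sprintf("sample odds ratio = %s, Fisher exact two-sided p = %.4g\n",
              ifelse(is.na(x$odds_ratio), "undefined",
                     sprintf("%.4f", x$odds_ratio)), x$p))
  invisible(x)
}

#' Compare dAR between escape and inactive genes
#'
#' Per-group Shapiro-Wilk normality p (reported, never gating) and a
#' two-sided Mann-Whitney U test of the dAR values.
#'
#' @param dar_escape,dar_inactive numeric dAR vectors (NAs dropped; at least
#'   2 values per group, 3 for the Shapiro-Wilk p to be available).
#' @return list: `shapiro_p` (named length-2), `mann_whitney_p`, `U`, `n`.
#' @export
delta_ar_test <- function(dar_escape, dar_inactive) {
  dar_escape <- dar_escape[!is.na(dar_escape)]
  dar_inactive <- dar_inactive[!is.na(dar_inactive)]
  if (length(dar_escape) < 2 || length(dar_inactive) < 2)
    stopf("need at least 2 dAR values per group")
  sw <- function(x) {
    if (length(x) < 3 || length(unique(x)) < 3) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  mw <- suppressWarnings(stats::wilcox.test(dar_escape, dar_inactive,
                                            alternative = "two.sided"))
  list(shapiro_p = c(escape = sw(dar_escape), inactive = sw(dar_inactive)),
       mann_whitney_p = mw$p.value, U = unname(mw$statistic),
       n = c(escape = length(dar_escape), inactive = length(dar_inactive)))
}
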