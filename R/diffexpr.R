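## diffexpr: normalization, expression summaries, DEG classification and a
## minimal negative-binomial Wald test for simulated counts.  The minimal test
## is deliberately NOT a full DE-tool clone (no independent filtering, no fold
## change shrinkage, method-of-moments dispersion); real datasets are ingested
## as precomputed DE tables via read_de_table().

#' Median-of-ratios size factors
#'
#' The standard count-normalization estimator: each sample's factor is the
#' median across reference genes of its count divided by the gene's geometric
#' mean over samples. Genes with a zero count in any sample are excluded from
#' the reference set.
#'
#' @param counts non-negative matrix (genes x samples) or [count_matrix()].
#' @return positive numeric vector, one factor per sample.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' rownames(m) <- paste0("g", 1:3)
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  eligible <- rowSums(counts == 0) == 0
  if (!any(eligible))
    stopf(paste("no gene has nonzero counts in every sample; median-of-ratios",
                "needs at least one such reference gene (consider a",
                "pseudo-reference fallback upstream)"))
  lg <- log(counts[eligible, , drop = FALSE])
  log_geo <- rowMeans(lg)
  # median of log ratios (geometric interpolation at even gene counts)
  sf <- exp(apply(sweep(lg, 1, log_geo, "-"), 2, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Transcripts per million
#'
#' `tpm_g = 1e6 * (c_g / L_g) / sum_h(c_h / L_h)` per sample; each column sums
#' to one million.
#'
#' @param counts genes x samples matrix or [count_matrix()].
#' @param lengths gene lengths in bp, aligned with rows (or named).
#' @return matrix of TPM values with the dimensions of `counts`.
#' @export
tpm <- function(counts, lengths) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  lengths <- align_lengths(counts, lengths)
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stopf("sample(s) with all-zero counts: TPM undefined")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Fragments per kilobase per million
#'
#' `fpkm_g = 1e9 * c_g / (L_g * N)` with `N` the per-sample library size
#' (total counts unless given).
#'
#' @inheritParams tpm
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return matrix of FPKM values.
#' @export
fpkm <- function(counts, lengths, lib_sizes = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  lengths <- align_lengths(counts, lengths)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stopf("library sizes must be positive")
  sweep(counts / lengths, 2, lib_sizes, "/") * 1e9
}

align_lengths <- function(counts, lengths) {
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing) > 0)
      stopf("no length for gene(s): %s", paste(utils::head(missing, 5), collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    stopf("lengths must align with count matrix rows")
  if (any(lengths <= 0)) stopf("gene lengths must be positive")
  as.numeric(lengths)
}

#' Percentage reduction of expression in deficient vs control cells
#'
#' `100 * (1 - deficient / control)`. Negative values (upregulation) are
#' reported as negative reductions, not clamped.
#'
#' @param control mean control expression (e.g. TPM); must be > 0.
#' @param deficient mean expression in the deficient condition.
#' @return percentage reduction.
#' @examples
#' percent_reduction(100, 8)  # 92
#' @export
percent_reduction <- function(control, deficient) {
  if (any(control <= 0)) stopf("control mean must be > 0 for percent reduction")
  100 * (1 - deficient / control)
}

#' Minimal negative-binomial Wald differential-expression test
#'
#' A compact NB Wald analysis for simulated counts: median-of-ratios
#' normalization, per-gene method-of-moments dispersion moderated toward the
#' genome-wide median (weights `n1 + n2 - 2` residual vs `prior_df` prior
#' degrees of freedom, the standard shrinkage device for few-replicate
#' designs), log2 fold change of normalized condition means with a
#' pseudocount, and a Wald statistic referred to a t distribution with
#' `n1 + n2 - 2 + prior_df` degrees of freedom so the null rejection rate
#' stays at the nominal level. Adjusted p-values are Benjamini-Hochberg over
#' genes with a non-missing p. Genes with zero counts everywhere get missing
#' p/padj and `deg_class = "none"`.
#'
#' @param cm [count_matrix()] with at least two samples per condition.
#' @param pseudocount added to normalized condition means before the log2
#'   ratio (default 0.5).
#' @param dispersion_floor lower bound for the dispersion estimate.
#' @param prior_df strength of dispersion moderation in prior degrees of
#'   freedom.
#' @param up_lfc,down_lfc,alpha DEG thresholds passed to [classify_degs()].
#' @return `de_table` with columns `gene_id`, `base_mean`, `log2fc`,
#'   `pvalue`, `padj`, `deg_class`.
#' @export
de_test <- function(cm, pseudocount = 0.5, dispersion_floor = 1e-8,
                    prior_df = 20, up_lfc = 0.58, down_lfc = -0.58,
                    alpha = 0.05) {
  if (!inherits(cm, "count_matrix")) stopf("de_test expects a count_matrix")
  cond <- cm$samples$condition
  n0 <- sum(cond == "control"); n1 <- sum(cond == "deficient")
  if (n0 < 2 || n1 < 2) stopf("need >= 2 samples per condition")
  sf <- size_factors(cm$counts)
  q <- sweep(cm$counts, 2, sf, "/")
  q0 <- q[, cond == "control", drop = FALSE]
  q1 <- q[, cond == "deficient", drop = FALSE]
  m0 <- rowMeans(q0); m1 <- rowMeans(q1)
  v0 <- apply(q0, 1, stats::var); v1 <- apply(q1, 1, stats::var)
  v_pool <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  m_pool <- (n0 * m0 + n1 * m1) / (n0 + n1)
  disp_raw <- pmax((v_pool - m_pool) / pmax(m_pool, 1e-12)^2, 0)
  resid_df <- n0 + n1 - 2
  disp_prior <- mean(disp_raw[m_pool > 5], trim = 0.05, na.rm = TRUE)
  if (!is.finite(disp_prior)) disp_prior <- 0.01
  disp <- pmax((resid_df * disp_raw + prior_df * disp_prior) /
                 (resid_df + prior_df), dispersion_floor)
  a0 <- m0 + pseudocount; a1 <- m1 + pseudocount
  log2fc <- log2(a1 / a0)
  se <- sqrt(((1 / a0 + disp) / n0 + (1 / a1 + disp) / n1)) / log(2)
  stat <- log2fc / se
  pvalue <- 2 * stats::pt(-abs(stat), df = resid_df + prior_df)
  zero <- m0 == 0 & m1 == 0
  pvalue[zero] <- NA_real_
  log2fc[zero] <- 0
  padj <- rep(NA_real_, length(pvalue))
  ok <- !is.na(pvalue)
  padj[ok] <- stats::p.adjust(pvalue[ok], method = "BH")
  de <- data.frame(gene_id = rownames(cm$counts),
                   base_mean = rowMeans(q), log2fc = log2fc,
                   pvalue = pvalue, padj = padj, stringsAsFactors = FALSE)
  attr(de, "size_factors") <- sf
  classify_degs(de_table(de), up_lfc = up_lfc, down_lfc = down_lfc, alpha = alpha)
}

#' Classify genes as up/down DEGs
#'
#' Strict inequalities exactly as the cutoffs are stated: `up` iff
#' `padj < alpha` and `log2fc > up_lfc`; `down` iff `padj < alpha` and
#' `log2fc < down_lfc`; everything else (including missing `padj`) is
#' `"none"`. The default log2 cutoff 0.58 corresponds to a ~1.5-fold change
#' (2^0.58 = 1.495).
#'
#' @param de `de_table`.
#' @param up_lfc,down_lfc log2 fold-change cutoffs.
#' @param alpha adjusted-p cutoff.
#' @return the table with `deg_class` filled.
#' @export
classify_degs <- function(de, up_lfc = 0.58, down_lfc = -0.58, alpha = 0.05) {
  stopifnot(is.finite(up_lfc), is.finite(down_lfc), alpha > 0, alpha < 1)
  sig <- !is.na(de$padj) & de$padj < alpha & !is.na(de$log2fc)
  de$deg_class <- ifelse(sig & de$log2fc > up_lfc, "up",
                         ifelse(sig & de$log2fc < down_lfc, "down", "none"))
  de
}

#' Fold change from paired replicate FPKMs
#'
#' Mean over replicate pairs of the per-pair KO/WT ratio (average of ratios,
#' not ratio of averages). Pairs with a WT FPKM of zero are skipped with a
#' warning; if every pair is skipped the result is missing.
#'
#' @param wt,ko numeric vectors of paired replicate FPKMs.
#' @return fold change (KO over WT), or `NA` if no usable pair.
#' @examples
#' fc_from_fpkm(c(2, 1), c(4, 1))  # mean(2, 1) = 1.5
#' @export
fc_from_fpkm <- function(wt, ko) {
  if (length(wt) != length(ko)) stopf("WT and KO replicate vectors must pair up")
  usable <- wt > 0
  if (!all(usable)) warnf("%d replicate pair(s) skipped (WT FPKM = 0)", sum(!usable))
  if (!any(usable)) return(NA_real_)
  mean(ko[usable] / wt[usable])
}

#' Keep actively expressed genes
#'
#' Genes whose mean FPKM meets the threshold (inclusive; `FPKM >= 1` by
#' default).
#'
#' @param fpkm_mat genes x samples FPKM matrix with row names.
#' @param threshold inclusive lower bound on the per-gene mean.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(fpkm_mat, threshold = 1) {
  fpkm_mat <- as.matrix(fpkm_mat)
  if (nrow(fpkm_mat) == 0) return(character())
  rownames(fpkm_mat)[rowMeans(fpkm_mat) >= threshold]
}
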