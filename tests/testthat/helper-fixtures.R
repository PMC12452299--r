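# Shared fixtures, all built in code.

# Minimal two-chromosome annotation: chrA with 10 genes, chrB with 20.
tiny_annotation <- function() {
  genes <- rbind(
    data.frame(gene_id = sprintf("a%02d", 1:10), chrom = "chrA",
               start = seq(0, 9000, by = 1000), end = seq(500, 9500, by = 1000),
               strand = "+"),
    data.frame(gene_id = sprintf("b%02d", 1:20), chrom = "chrB",
               start = seq(0, 19000, by = 1000), end = seq(400, 19400, by = 1000),
               strand = "-"))
  genome_annotation(genes, chrom_lengths = c(chrA = 20000, chrB = 30000))
}

# DE table over the tiny annotation with chosen DEG gene ids.
tiny_de <- function(up = character(), down = character()) {
  ids <- tiny_annotation()$genes$gene_id
  lfc <- rep(0, length(ids)); padj <- rep(0.9, length(ids))
  lfc[ids %in% up] <- 1.5; padj[ids %in% up] <- 0.001
  lfc[ids %in% down] <- -1.5; padj[ids %in% down] <- 0.001
  de_table(data.frame(gene_id = ids, log2fc = lfc, pvalue = padj, padj = padj))
}

# Human-like annotation skeleton where one autosome has the gene count
# closest to the X: per-chromosome gene counts are given directly.
count_annotation <- function(counts) {
  genes <- do.call(rbind, lapply(names(counts), function(ch) {
    n <- counts[[ch]]
    data.frame(gene_id = sprintf("%s_g%03d", ch, seq_len(n)), chrom = ch,
               start = seq(0, by = 1000, length.out = n),
               end = seq(800, by = 1000, length.out = n), strand = "+")
  }))
  genome_annotation(genes)
}

# Construct vectors with an exact sample correlation structure from a target
# correlation triple, via an orthonormal basis of centered vectors.
exact_correlation_vectors <- function(r_xy, r_xz, r_yz, n = 16, seed = 7) {
  set.seed(seed)
  m <- matrix(rnorm(n * 3), n, 3)
  m <- sweep(m, 2, colMeans(m))
  u <- qr.Q(qr(m))
  u <- sweep(u, 2, colMeans(u))       # re-center (constant is ~orthogonal already)
  u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
  x <- u[, 1]
  z <- r_xz * u[, 1] + sqrt(1 - r_xz^2) * u[, 2]
  a <- r_xy
  b <- (r_yz - r_xy * r_xz) / sqrt(1 - r_xz^2)
  stopifnot(1 - a^2 - b^2 >= 0)
  y <- a * u[, 1] + b * u[, 2] + sqrt(1 - a^2 - b^2) * u[, 3]
  list(x = x, y = y, z = z)
}

# Brute-force two-sided Fisher exact p (minimum-likelihood convention) by
# hypergeometric enumeration over all tables with the observed margins.
fisher_p_enum <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Textbook Benjamini-Hochberg: sort ascending, p * m / rank, cumulative
# minimum from the largest rank, restored to input order, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# Small, fast simulation config used where the full genome is unnecessary.
small_config <- function(...) {
  simulation_config(n_autosomes = 4, autosome_length = 3e7, x_length = 4e7,
                    n_genes = 600, snps_per_gene = 1, ...)
}
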