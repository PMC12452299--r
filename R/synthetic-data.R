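## synthetic_data: generator emulating the statistical structure the analysis
## assumes, with known ground truth.  Gene positions are clustered along each
## chromosome (kernel-mixture intensity); SINE density is positively and LINE
## density negatively coupled to gene density through a Gaussian-copula latent
## field whose mixing weight is calibrated so the REALIZED window-count
## correlation (after Poisson-level sampling noise, which is substantial at
## ~1-2 genes per 1 Mbp window) hits the configured target; counts are
## negative binomial with sample size factors; allelic counts are binomial
## with a low minor-allele fraction for inactive genes and a higher one for
## escape genes, shifted on knockdown for reactivated / monoallelized
## subsets.

#' Simulation configuration
#'
#' Defaults describe a human-like desk-scale genome: 22 autosomes of 130 Mbp
#' plus a 156 Mbp X (giving ~621 overlapping 1 Mbp / 250 kbp windows on the
#' X), 5000 genes, negative-binomial expression with lognormal means (median
#' 200) and typical bulk RNA-seq dispersions (median 0.03), three replicates
#' per condition. The `"stem"` scenario upregulates a fraction `f_x` of
#' X-linked genes by `delta` log2 units; `"differentiated"` places the same
#' number of affected genes uniformly across the genome; `"null"` has no
#' effect (the designated XIST gene is only knocked down outside the null
#' scenario).
#'
#' @param ... overrides for any default listed below.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    # genome
    n_autosomes = 22, autosome_length = 1.3e8, x_length = 1.56e8,
    n_genes = 5000, cluster_spacing = 1e7, cluster_bw = 2e6,
    background_frac = 0.2, cluster_weight_sdlog = 0.75,
    gene_len_meanlog = log(2e4), gene_len_sdlog = 0.8,
    # repeats and density coupling
    rho_gene_sine = 0.6, rho_gene_line = -0.5,
    sine_per_mb = 60, line_per_mb = 40, other_per_mb = 10,
    sine_len = 300, line_len = 3000, other_len = 500,
    repeat_sigma = 0.8,
    window = 1e6, step = 2.5e5,
    # expression
    scenario = "stem", f_x = 0.15, delta = 1.0, n_reps = 3,
    mu_meanlog = log(200), mu_sdlog = 1.0,
    disp_meanlog = log(0.03), disp_sdlog = 0.5,
    sf_sdlog = 0.15, xist_mu = 500, xist_lfc = -3.5,
    # XCI and allele model
    frac_escape = 0.25, frac_variable = 0.05,
    p_inactive = 0.02, p_escape = 0.25, p_jitter_sd = 0.01,
    dp_kd = 0.2, reads_per_snp = 60, snps_per_gene = 2,
    n_kd_clones = 2, frac_reactivated = 0.3, frac_monoallelized = 0.3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$f_x >= 0, cfg$f_x <= 1,
            abs(cfg$rho_gene_sine) <= 1, abs(cfg$rho_gene_line) <= 1,
            cfg$scenario %in% c("stem", "differentiated", "null"),
            cfg$autosome_length > 0, cfg$x_length > 0)
  structure(cfg, class = "simulation_config")
}

roll_sum <- function(v, k) {
  if (k == 1) return(v)
  s <- as.numeric(stats::filter(v, rep(1, k), sides = 1))
  s[k:length(v)]
}

gaussian_smooth <- function(x, sd_bins) {
  half <- max(1L, ceiling(3 * sd_bins))
  kern <- stats::dnorm(seq(-half, half), sd = sd_bins)
  kern <- kern / sum(kern)
  n <- length(x)
  padded <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1]))
  as.numeric(stats::filter(padded, kern, sides = 2))[(half + 1):(half + n)]
}

## Predicted realized correlation between the OBSERVED gene window counts
## (fixed at calibration time) and the window counts of a repeat class drawn
## from bin intensities lamR.  Repeat sampling is ~Poisson per bin,
## independent across bins, so
##   cor = cov(LG, LR) / sqrt(var(LG) (var(LR) + mean(LR)))
## with LG the observed gene window counts and LR the window-level expected
## repeat counts.
predicted_track_cor <- function(LG, lamR, k) {
  LR <- roll_sum(lamR, k)
  stats::cov(LG, LR) / sqrt(stats::var(LG) * (stats::var(LR) + mean(LR)))
}

## Solve the copula mixing weight a so that the predicted realized window
## correlation between the observed gene counts and the repeat counts hits
## `target`.  The repeat latent field mixes the standardized (smoothed)
## realized gene density zG with independent smooth noise eR, so only the
## repeat-level Poisson noise attenuates the realized correlation.  Warns
## when the target is infeasible.
solve_mixing <- function(zG, eR, sigma, gene_counts, n_repeat, k, target) {
  LG <- roll_sum(gene_counts, k)
  intensity <- function(a) {
    zR <- a * zG + sqrt(1 - a^2) * eR
    I <- exp(sigma * zR)
    I / sum(I) * n_repeat
  }
  pred <- function(a) predicted_track_cor(LG, intensity(a), k)
  if (target == 0) return(list(a = 0, achieved = pred(0)))
  amax <- 0.9999 * sign(target)
  p_max <- pred(amax); p_0 <- pred(0)
  if ((target > 0 && p_max < target) || (target < 0 && p_max > target)) {
    warnf("density-coupling target %.2f infeasible; achieving %.2f",
          target, p_max)
    return(list(a = amax, achieved = p_max))
  }
  if ((target > 0 && p_0 > target) || (target < 0 && p_0 < target))
    return(list(a = 0, achieved = p_0))
  root <- stats::uniroot(function(a) pred(a) - target,
                         interval = sort(c(0, amax)), tol = 1e-4)
  list(a = root$root, achieved = pred(root$root))
}

#' Simulate a clustered gene annotation with coupled repeat densities
#'
#' Gene midpoints are drawn from a kernel-mixture intensity (cluster centers
#' ~10 Mbp apart with lognormal weights over a uniform background); SINE and
#' LINE element intensities are exponentiated Gaussian latent fields that
#' mix the standardized realized gene density with independent smooth noise
#' at calibrated weights, positively for SINEs and negatively for LINEs.
#' Identical seeds give identical output.
#'
#' @param config [simulation_config()].
#' @param seed integer seed.
#' @return list with `annotation` ([genome_annotation()]), `repeats`
#'   (`repeat_track`), and `mixing` (per-chromosome calibration diagnostics:
#'   mixing weights and predicted realized correlations).
#' @export
simulate_annotation <- function(config = simulation_config(), seed = 1) {
  with_seed(derive_seed(seed, "annotation"), {
    chroms <- c(paste0("chr", seq_len(config$n_autosomes)), "chrX")
    lens <- stats::setNames(c(rep(config$autosome_length, config$n_autosomes),
                              config$x_length), chroms)
    n_per_chrom <- stats::setNames(
      as.integer(stats::rmultinom(1, config$n_genes, lens / sum(lens))), chroms)
    bin <- config$step
    k <- as.integer(round(config$window / config$step))
    genes <- list(); reps <- list(); mix <- list()
    for (chrom in chroms) {
      L <- lens[[chrom]]
      B <- floor(L / bin)
      centers <- stats::runif(max(1, round(L / config$cluster_spacing)), 0, L)
      weights <- stats::rlnorm(length(centers), 0, config$cluster_weight_sdlog)
      t_b <- (seq_len(B) - 0.5) * bin
      G0 <- colSums(weights * vapply(t_b, function(t)
        stats::dnorm(t, centers, config$cluster_bw), numeric(length(centers))))
      G0 <- G0 / sum(G0)
      G <- config$background_frac / B + (1 - config$background_frac) * G0
      nG <- n_per_chrom[[chrom]]
      # genes first: the repeat fields couple to the realized gene density
      gbin <- sample.int(B, nG, replace = TRUE, prob = G)
      gene_counts <- tabulate(gbin, nbins = B)
      zG <- gaussian_smooth(gene_counts, 2)
      zG <- (zG - mean(zG)) / stats::sd(zG)
      bw_bins <- config$cluster_bw / bin
      eS <- gaussian_smooth(stats::rnorm(B), bw_bins)
      eS <- (eS - mean(eS)) / stats::sd(eS)
      eL <- gaussian_smooth(stats::rnorm(B), bw_bins)
      eL <- (eL - mean(eL)) / stats::sd(eL)
      n_sine <- round(config$sine_per_mb * L / 1e6)
      n_line <- round(config$line_per_mb * L / 1e6)
      mS <- solve_mixing(zG, eS, config$repeat_sigma, gene_counts, n_sine, k,
                         config$rho_gene_sine)
      mL <- solve_mixing(zG, eL, config$repeat_sigma, gene_counts, n_line, k,
                         config$rho_gene_line)
      mix[[chrom]] <- data.frame(chrom = chrom, a_sine = mS$a, a_line = mL$a,
                                 predicted_r_sine = mS$achieved,
                                 predicted_r_line = mL$achieved)
      mid <- (gbin - 1) * bin + stats::runif(nG, 0, bin)
      glen <- pmin(pmax(round(stats::rlnorm(nG, config$gene_len_meanlog,
                                            config$gene_len_sdlog)), 200), 2e5)
      start <- pmax(0, round(mid - glen / 2))
      end <- pmin(L, start + glen)
      start <- pmin(start, end - 1)
      genes[[chrom]] <- data.frame(
        gene_id = sprintf("G%s_%04d", sub("^chr", "", chrom), seq_len(nG)),
        chrom = chrom, start = start, end = end,
        strand = sample(c("+", "-"), nG, replace = TRUE),
        stringsAsFactors = FALSE)
      # repeats
      place <- function(n, intensity, len, cls) {
        b <- sample.int(B, n, replace = TRUE, prob = intensity)
        s <- pmin((b - 1) * bin + round(stats::runif(n, 0, bin)), L - len)
        data.frame(chrom = chrom, start = s, end = s + len,
                   repeat_class = cls, stringsAsFactors = FALSE)
      }
      int_of <- function(a, e) exp(config$repeat_sigma *
                                     (a * zG + sqrt(1 - a^2) * e))
      reps[[chrom]] <- rbind(
        place(n_sine, int_of(mS$a, eS), config$sine_len, "SINE"),
        place(n_line, int_of(mL$a, eL), config$line_len, "LINE"),
        place(round(config$other_per_mb * L / 1e6), rep(1, B),
              config$other_len, "other"))
    }
    gene_df <- do.call(rbind, genes)
    # designate the X gene nearest 73.8 Mbp (the XIST locus neighborhood in a
    # human-scaled X) as XIST so knockdown semantics have a target
    on_x <- which(gene_df$chrom == "chrX")
    if (length(on_x) > 0) {
      mids <- (gene_df$start[on_x] + gene_df$end[on_x]) / 2
      gene_df$gene_id[on_x[which.min(abs(mids - 7.38e7))]] <- "XIST"
    }
    rownames(gene_df) <- NULL
    list(annotation = genome_annotation(gene_df, chrom_lengths = lens),
         repeats = repeat_track(do.call(rbind, reps)),
         mixing = do.call(rbind, mix))
  })
}

#' Simulate a count matrix with a known differential-expression truth
#'
#' Counts are NB(`mu_g * sf_j * 2^(lfc_g)` in the deficient condition,
#' dispersion `alpha_g`) with lognormal gene means, lognormal dispersions and
#' lognormal sample size factors. In the `"stem"` scenario a fraction `f_x`
#' of X-linked genes carries a true log2 fold change `delta`; in
#' `"differentiated"` the same number of affected genes is placed uniformly
#' across the genome; in `"null"` nothing is affected. Outside the null
#' scenario the designated XIST gene is strongly downregulated
#' (`xist_lfc`), emulating the knockdown target itself.
#'
#' @param ann annotation from [simulate_annotation()] (the
#'   [genome_annotation()] element).
#' @param config [simulation_config()].
#' @param seed integer seed.
#' @return list with `counts` ([count_matrix()]) and `truth` (data.frame
#'   `gene_id`, `chrom`, `true_lfc`, `affected`).
#' @export
simulate_counts <- function(ann, config = simulation_config(), seed = 1) {
  with_seed(derive_seed(seed, "counts"), {
    g <- ann$genes
    n <- nrow(g)
    mu <- stats::rlnorm(n, config$mu_meanlog, config$mu_sdlog)
    disp <- stats::rlnorm(n, config$disp_meanlog, config$disp_sdlog)
    is_xist <- g$gene_id == "XIST"
    mu[is_xist] <- config$xist_mu
    true_lfc <- numeric(n)
    x_idx <- which(g$chrom == "chrX")
    n_affect <- round(config$f_x * length(x_idx))
    pool <- if (config$scenario == "stem") setdiff(x_idx, which(is_xist))
            else setdiff(seq_len(n), which(is_xist))
    affected <- integer(0)
    if (config$scenario != "null" && n_affect > 0) {
      affected <- sample(pool, min(n_affect, length(pool)))
      true_lfc[affected] <- config$delta
    }
    if (config$scenario != "null") true_lfc[is_xist] <- config$xist_lfc
    n_samp <- 2 * config$n_reps
    cond <- rep(c("control", "deficient"), each = config$n_reps)
    sf <- stats::rlnorm(n_samp, 0, config$sf_sdlog)
    counts <- vapply(seq_len(n_samp), function(j) {
      m <- mu * sf[j] * if (cond[j] == "deficient") 2^true_lfc else 1
      stats::rnbinom(n, mu = m, size = 1 / disp)
    }, numeric(n))
    rownames(counts) <- g$gene_id
    colnames(counts) <- paste0(ifelse(cond == "control", "ctrl_", "kd_"),
                               rep(seq_len(config$n_reps), 2))
    list(counts = count_matrix(counts, cond),
         truth = data.frame(gene_id = g$gene_id, chrom = g$chrom,
                            true_lfc = true_lfc,
                            affected = seq_len(n) %in% affected,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate XCI status for X-linked genes
#'
#' Assigns escape / variable / inactive labels to X-linked genes at the
#' configured fractions (defaults emulate the 15-25% human escape rate).
#'
#' @inheritParams simulate_counts
#' @return named character vector gene id -> status for X-linked genes.
#' @export
simulate_xci_status <- function(ann, config = simulation_config(), seed = 1) {
  with_seed(derive_seed(seed, "xci"), {
    x_genes <- ann$genes$gene_id[ann$genes$chrom == "chrX"]
    status <- sample(c("escape", "variable", "inactive"), length(x_genes),
                     replace = TRUE,
                     prob = c(config$frac_escape, config$frac_variable,
                              1 - config$frac_escape - config$frac_variable))
    stats::setNames(status, x_genes)
  })
}

#' Simulate per-SNP allelic read counts with a known truth
#'
#' Per SNP, minor-allele reads are Binomial(n, p) with p near
#' `p_inactive` (monoallelic) for inactive genes and `p_escape` (partially
#' biallelic) for escape genes in the control; knockdown shifts p by
#' `+dp_kd` for a reactivated subset and `-dp_kd` for a monoallelized
#' subset, clamped to `[0, 0.5]` (with a warning when clamping occurs).
#' Ref/alt orientation is randomized per SNP; the allelic ratio folds it
#' back.
#'
#' @param ann annotation ([genome_annotation()]).
#' @param xci named status vector (see [simulate_xci_status()]).
#' @param config [simulation_config()].
#' @param seed integer seed.
#' @return list with `allele_counts` ([allele_counts()]) and `truth`
#'   (data.frame `gene_id`, `status`, `group`, `p_ctrl`, `p_kd`).
#' @export
simulate_allele_counts <- function(ann, xci, config = simulation_config(),
                                   seed = 1) {
  with_seed(derive_seed(seed, "alleles"), {
    g <- ann$genes[ann$genes$chrom == "chrX", ]
    status <- unname(ifelse(is.na(xci[g$gene_id]), "unknown", xci[g$gene_id]))
    p_base <- ifelse(status == "escape", config$p_escape,
                     ifelse(status == "variable",
                            (config$p_escape + config$p_inactive) / 2,
                            config$p_inactive))
    jitter <- stats::rnorm(nrow(g), 0, config$p_jitter_sd)
    p_ctrl <- ifelse(p_base > 0, pmin(pmax(p_base + jitter, 0.001), 0.5), 0)
    n <- nrow(g)
    group <- rep("stable", n)
    shuffled <- sample.int(n)
    n_re <- round(config$frac_reactivated * n)
    n_mono <- round(config$frac_monoallelized * n)
    group[shuffled[seq_len(n_re)]] <- "reactivated"
    group[shuffled[n_re + seq_len(n_mono)]] <- "monoallelized"
    p_kd_raw <- p_ctrl + ifelse(group == "reactivated", config$dp_kd,
                                ifelse(group == "monoallelized",
                                       -config$dp_kd, 0))
    clamped <- p_kd_raw < 0 | p_kd_raw > 0.5
    if (any(clamped))
      warnf("minor-allele fraction clamped to [0, 0.5] for %d gene(s) after knockdown shift",
            sum(clamped))
    p_kd <- pmin(pmax(p_kd_raw, 0), 0.5)
    samples <- c("CTRL", paste0("KD", seq_len(config$n_kd_clones)))
    recs <- list()
    for (i in seq_len(n)) {
      pos <- sort(round(stats::runif(config$snps_per_gene, g$start[i] + 1,
                                     g$end[i])))
      for (s in samples) {
        p <- if (s == "CTRL") p_ctrl[i] else p_kd[i]
        n_reads <- stats::rpois(config$snps_per_gene, config$reads_per_snp)
        minor <- stats::rbinom(config$snps_per_gene, n_reads, p)
        flip <- stats::runif(config$snps_per_gene) < 0.5
        recs[[length(recs) + 1]] <- data.frame(
          gene_id = g$gene_id[i], chrom = "chrX", pos = pos, sample_id = s,
          ref_count = ifelse(flip, minor, n_reads - minor),
          alt_count = ifelse(flip, n_reads - minor, minor),
          stringsAsFactors = FALSE)
      }
    }
    list(allele_counts = allele_counts(do.call(rbind, recs)),
         truth = data.frame(gene_id = g$gene_id, status = status,
                            group = group, p_ctrl = p_ctrl, p_kd = p_kd,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a complete dataset
#'
#' Runs all generator stages (annotation + repeats, XCI status, counts,
#' allelic counts) under deterministically derived per-stage sub-seeds, so
#' any stage can also be regenerated independently with the same seed.
#'
#' @param config [simulation_config()].
#' @param seed integer seed.
#' @param alleles simulate allelic counts too? (slowest stage; default TRUE)
#' @return list of class `xresponse_sim` with elements `annotation`,
#'   `repeats`, `mixing`, `xci`, `counts`, `truth_de`, and (optionally)
#'   `allele_counts`, `truth_alleles`, plus `config` and `seed`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1,
                             alleles = TRUE) {
  sa <- simulate_annotation(config, seed)
  xci <- simulate_xci_status(sa$annotation, config, seed)
  sc <- simulate_counts(sa$annotation, config, seed)
  out <- list(annotation = sa$annotation, repeats = sa$repeats,
              mixing = sa$mixing, xci = xci, counts = sc$counts,
              truth_de = sc$truth, config = config, seed = seed)
  if (alleles) {
    al <- simulate_allele_counts(sa$annotation, xci, config, seed)
    out$allele_counts <- al$allele_counts
    out$truth_alleles <- al$truth
  }
  structure(out, class = "xresponse_sim")
}

#' @export
print.xresponse_sim <- function(x, ...) {
  cat(sprintf("xresponse_sim (seed %s, scenario '%s'): %d genes, %d repeats\n",
              x$seed, x$config$scenario, nrow(x$annotation$genes),
              nrow(x$repeats)))
  invisible(x)
}

#' Write a simulated dataset as the standard-format files the pipeline reads
#'
#' @param sim `xresponse_sim`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gene_annotation(sim$annotation, p("annotation.gtf"))
  write_tsv(data.frame(chrom = sim$repeats$chrom, start = sim$repeats$start,
                       end = sim$repeats$end, name = sim$repeats$repeat_class),
            p("repeats.bed"))
  # repeats.bed is BED4: strip the header line
  bed <- readLines(p("repeats.bed")); writeLines(bed[-1], p("repeats.bed"))
  write_count_matrix(sim$counts, p("counts.tsv"), p("samples.tsv"))
  write_xci_status(sim$xci, p("xci_status.tsv"))
  write_tsv(sim$truth_de, p("truth_degs.tsv"))
  paths <- c(annotation = p("annotation.gtf"), repeats = p("repeats.bed"),
             counts = p("counts.tsv"), samples = p("samples.tsv"),
             xci = p("xci_status.tsv"), truth_de = p("truth_degs.tsv"))
  if (!is.null(sim$allele_counts)) {
    write_allele_counts(sim$allele_counts, p("allele_counts.tsv"))
    write_tsv(sim$truth_alleles, p("truth_alleles.tsv"))
    paths <- c(paths, alleles = p("allele_counts.tsv"),
               truth_alleles = p("truth_alleles.tsv"))
  }
  jsonlite::write_json(unclass(sim$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, config = p("config.json"))
  invisible(paths)
}
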