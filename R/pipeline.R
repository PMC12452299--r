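## pipeline: end-to-end orchestration of a per-dataset run and of comparative
## multi-dataset analyses, with a serialized run manifest so outputs are
## reproducible from fixed inputs and seed.

#' Run the full analysis for one dataset
#'
#' Orchestrates the per-dataset stages: DE classification (from an ingested
#' DE table, or the built-in minimal NB Wald test when raw counts are given),
#' per-chromosome DEG percentages/rankings, X-vs-autosome Z tests, the KS
#' distribution panel, X-chromosome density correlations (when repeats are
#' supplied) and allelic-ratio analysis (when allelic counts are supplied).
#'
#' @param de `de_table`, or `NULL` to derive one from `counts`.
#' @param ann [genome_annotation()].
#' @param counts optional [count_matrix()] (used when `de` is `NULL`).
#' @param repeats optional `repeat_track` enabling the density stage.
#' @param allele_counts optional [allele_counts()] enabling the allelic stage.
#' @param xci optional named XCI status vector.
#' @param control_chrom control autosome name or `"auto"`.
#' @param ar_control,ar_kd control / knockdown sample ids for the allelic
#'   stage (defaults: `"CTRL"` and every other sample id present).
#' @param window,step density window grid (bp).
#' @param x_chrom X chromosome name.
#' @param label dataset label recorded in the manifest.
#' @return list of class `xresponse_run` with elements `de`,
#'   `chrom_summary`, `z_tests`, `ks`, `control_chrom`, and optionally
#'   `density`, `deg_positions`, `ar`, `xci_test`, plus `manifest`.
#' @export
run_dataset <- function(de = NULL, ann, counts = NULL, repeats = NULL,
                        allele_counts = NULL, xci = NULL,
                        control_chrom = "auto", ar_control = "CTRL",
                        ar_kd = NULL, window = 1e6, step = 2.5e5,
                        x_chrom = "chrX", label = "dataset") {
  if (is.null(de)) {
    if (is.null(counts)) stopf("run_dataset needs a DE table or a count matrix")
    de <- de_test(counts)
  }
  if (identical(control_chrom, "auto"))
    control_chrom <- pick_control_chromosome(ann, target = x_chrom)
  summary <- chrom_deg_percentages(de, ann)
  out <- list(label = label, de = de, chrom_summary = summary,
              z_tests = x_vs_autosome_tests(summary, x_chrom = x_chrom),
              ks = ks_panel(de, ann, control_chrom = control_chrom,
                            x_chrom = x_chrom),
              control_chrom = control_chrom)
  if (!is.null(repeats)) {
    out$density <- density_correlations(de, ann, repeats, chrom = x_chrom,
                                        window = window, step = step)
    out$deg_positions <- deg_position_table(de, ann, chrom = x_chrom, xci = xci)
  }
  if (!is.null(allele_counts)) {
    if (is.null(ar_kd))
      ar_kd <- setdiff(unique(allele_counts$sample_id), ar_control)
    out$ar <- ar_table(allele_counts, xci = xci, control = ar_control,
                       kd_samples = ar_kd)
    out$xci_test <- xci_contingency(out$ar)
    esc <- out$ar$xci_status == "escape"
    ina <- out$ar$xci_status == "inactive"
    dar1 <- out$ar[[paste0("dar_", ar_kd[1])]]
    if (sum(esc & !is.na(dar1)) >= 2 && sum(ina & !is.na(dar1)) >= 2)
      out$dar_test <- delta_ar_test(dar1[esc], dar1[ina])
  }
  out$manifest <- list(label = label, control_chrom = control_chrom,
                       window = window, step = step, x_chrom = x_chrom,
                       n_genes = nrow(ann$genes), n_de = nrow(de),
                       version = as.character(utils::packageVersion("xresponse")),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  structure(out, class = "xresponse_run")
}

#' @export
print.xresponse_run <- function(x, ...) {
  s <- x$chrom_summary
  xrow <- s[s$chrom == (x$manifest$x_chrom %||% "chrX"), ]
  cat(sprintf("xresponse_run '%s': %d DEGs (%d up, %d down) across %d chromosomes\n",
              x$label, sum(s$n_deg), sum(s$n_up), sum(s$n_down), nrow(s)))
  if (nrow(xrow) == 1)
    cat(sprintf("  X: %.2f%% up (rank %d/%d), %.2f%% down (rank %d/%d); control chromosome %s\n",
                xrow$pct_up, xrow$rank_up, nrow(s), xrow$pct_down,
                xrow$rank_down, nrow(s), x$control_chrom))
  ks <- x$ks$X_vs_autosomes
  cat(sprintf("  KS X vs autosomes: D = %.4f, p = %.3g [%s]\n",
              ks$D, ks$p, ks$direction))
  invisible(x)
}

#' Write all outputs of a run as tab-separated files plus a JSON manifest
#'
#' @param run `xresponse_run`.
#' @param dir output directory.
#' @return named vector of written paths.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_de_table(run$de, p("de_table.tsv"))
  write_tsv(as.data.frame(run$chrom_summary), p("chrom_summary.tsv"))
  write_tsv(run$z_tests, p("z_tests.tsv"))
  write_tsv(ks_panel_table(run$ks), p("ks_tests.tsv"))
  paths <- c(de = p("de_table.tsv"), chrom_summary = p("chrom_summary.tsv"),
             z_tests = p("z_tests.tsv"), ks = p("ks_tests.tsv"))
  if (!is.null(run$density)) {
    write_tsv(run$density$correlations, p("density_correlations.tsv"))
    write_tsv(run$deg_positions, p("deg_positions.tsv"))
    for (nm in names(run$density$tracks))
      write_tsv(as.data.frame(run$density$tracks[[nm]]),
                p(sprintf("track_%s.tsv", nm)))
    paths <- c(paths, density = p("density_correlations.tsv"))
  }
  if (!is.null(run$ar)) {
    write_tsv(as.data.frame(run$ar), p("ar_table.tsv"))
    ct <- run$xci_test
    write_tsv(data.frame(escape_up = ct$table[1, 1], escape_down = ct$table[1, 2],
                         inactive_up = ct$table[2, 1], inactive_down = ct$table[2, 2],
                         odds_ratio = ct$odds_ratio, fisher_p = ct$p),
              p("xci_contingency.tsv"))
    paths <- c(paths, ar = p("ar_table.tsv"))
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, manifest = p("manifest.json")))
}

#' Comparative analysis across datasets
#'
#' Computes multi-dataset DEG intersections (exclusive UpSet-style counts and
#' the full-intersection gene lists, per direction) and the pairwise
#' cross-dataset Pearson correlation matrix of X-linked DEG density tracks
#' (runs must share one window grid).
#'
#' @param runs named list of `xresponse_run` objects (>= 2).
#' @param track which density track to correlate (default `"deg_all"`).
#' @return list of class `xresponse_comparison`: `overlap_up`,
#'   `overlap_down`, `shared_up`, `shared_down`, `density_cor` (matrix or
#'   `NULL` when no run has a density stage).
#' @export
run_comparative <- function(runs, track = "deg_all") {
  if (length(runs) < 2) stopf("comparative analysis needs >= 2 datasets")
  if (is.null(names(runs))) names(runs) <- paste0("dataset", seq_along(runs))
  col <- deg_set_collection(lapply(runs, `[[`, "de"))
  out <- list(overlap_up = deg_intersections(col, "up"),
              overlap_down = deg_intersections(col, "down"),
              shared_up = shared_degs(col, direction = "up"),
              shared_down = shared_degs(col, direction = "down"))
  with_density <- names(runs)[!vapply(runs, function(r) is.null(r$density), TRUE)]
  if (length(with_density) >= 2) {
    m <- diag(1, length(with_density))
    dimnames(m) <- list(with_density, with_density)
    pm <- m; pm[] <- NA_real_
    for (i in seq_along(with_density)) for (j in seq_along(with_density)) {
      if (j <= i) next
      res <- cross_dataset_correlation(
        runs[[with_density[i]]]$density$tracks[[track]],
        runs[[with_density[j]]]$density$tracks[[track]])
      m[i, j] <- m[j, i] <- res$r
      pm[i, j] <- pm[j, i] <- res$p
    }
    out$density_cor <- m
    out$density_cor_p <- pm
  }
  structure(out, class = "xresponse_comparison")
}

#' @export
print.xresponse_comparison <- function(x, ...) {
  cat(sprintf("xresponse_comparison: %d shared up DEG(s), %d shared down DEG(s)\n",
              length(x$shared_up), length(x$shared_down)))
  if (length(x$shared_down) > 0)
    cat("  shared down:", paste(utils::head(x$shared_down, 10), collapse = ", "), "\n")
  if (!is.null(x$density_cor)) {
    cat("  X-linked DEG density correlations:\n")
    print(round(x$density_cor, 4))
  }
  invisible(x)
}
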