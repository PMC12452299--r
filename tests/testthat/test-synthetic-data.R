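# Generator: determinism, invariants, ground-truth recovery.

test_that("identical seeds give identical output; different seeds differ", {
  cfg <- small_config()
  s1 <- simulate_annotation(cfg, seed = 5)
  s2 <- simulate_annotation(cfg, seed = 5)
  expect_identical(s1$annotation$genes, s2$annotation$genes)
  expect_identical(as.data.frame(s1$repeats), as.data.frame(s2$repeats))
  s3 <- simulate_annotation(cfg, seed = 6)
  expect_false(identical(s1$annotation$genes, s3$annotation$genes))
})

test_that("stage sub-seeds are independent: counts reproduce without the annotation stage", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg, seed = 9)$annotation
  c1 <- simulate_counts(ann, cfg, seed = 9)
  c2 <- simulate_counts(ann, cfg, seed = 9)
  expect_identical(c1$counts$counts, c2$counts$counts)
})

test_that("generated objects satisfy the data-model invariants", {
  sim <- suppressWarnings(simulate_dataset(small_config(), seed = 2, alleles = TRUE))
  g <- sim$annotation$genes
  expect_true(all(g$start >= 0 & g$start < g$end))
  expect_true(all(g$end <= sim$annotation$chrom_lengths[g$chrom]))
  expect_false(anyDuplicated(g$gene_id) > 0)
  expect_true(all(sim$counts$counts >= 0))
  expect_setequal(unique(sim$counts$samples$condition), c("control", "deficient"))
  expect_true(all(sim$repeats$repeat_class %in% c("SINE", "LINE", "other")))
  expect_true(all(sim$allele_counts$ref_count >= 0 &
                  sim$allele_counts$alt_count >= 0))
})

test_that("the truth table marks round(f_x * n_X) affected X genes in the stem scenario", {
  cfg <- small_config(f_x = 0.2)
  sa <- simulate_annotation(cfg, seed = 4)
  sc <- simulate_counts(sa$annotation, cfg, seed = 4)
  n_x <- sum(sa$annotation$genes$chrom == "chrX")
  expect_equal(sum(sc$truth$affected), round(0.2 * n_x))
  expect_true(all(sc$truth$chrom[sc$truth$affected] == "chrX"))

  null <- simulate_counts(sa$annotation, small_config(scenario = "null"), seed = 4)
  expect_equal(sum(null$truth$affected), 0)
  diff <- simulate_counts(sa$annotation,
                          small_config(f_x = 0.2, scenario = "differentiated"),
                          seed = 4)
  expect_equal(sum(diff$truth$affected), round(0.2 * n_x))
  expect_true(any(diff$truth$chrom[diff$truth$affected] != "chrX"))
})

test_that("estimated fold changes of affected genes recover the configured effect", {
  cfg <- simulation_config()   # default depth >= 1e6 reads per sample, 3 vs 3
  sa <- simulate_annotation(cfg, seed = 8)
  sc <- simulate_counts(sa$annotation, cfg, seed = 8)
  expect_gt(sum(sc$counts$counts[, 1]), 1e6)
  de <- de_test(sc$counts)
  est <- de$log2fc[match(sc$truth$gene_id[sc$truth$affected], de$gene_id)]
  expect_equal(mean(est), cfg$delta, tolerance = 0.15)
})

test_that("repeat density coupling is signed as configured at small scale", {
  cfg <- small_config()
  sa <- simulate_annotation(cfg, seed = 12)
  win <- make_windows(sa$annotation$chrom_lengths[["chrX"]])
  g <- sa$annotation$genes[sa$annotation$genes$chrom == "chrX", ]
  r <- sa$repeats[sa$repeats$chrom == "chrX", ]
  tg <- density_track(g, win, "count")
  r_sine <- pearson(tg, density_track(r[r$repeat_class == "SINE", ], win, "count"))$r
  r_line <- pearson(tg, density_track(r[r$repeat_class == "LINE", ], win, "count"))$r
  expect_gt(r_sine, 0.2)
  expect_lt(r_line, -0.1)
})

test_that("a zero minor-allele fraction yields AR = 0 always", {
  cfg <- small_config(p_inactive = 0, frac_escape = 0, frac_variable = 0,
                      dp_kd = 0, p_jitter_sd = 0)
  sa <- simulate_annotation(cfg, seed = 14)
  xci <- simulate_xci_status(sa$annotation, cfg, seed = 14)
  al <- simulate_allele_counts(sa$annotation, xci, cfg, seed = 14)
  ar <- allelic_ratio(al$allele_counts$ref_count, al$allele_counts$alt_count)
  expect_true(all(ar[!is.na(ar)] == 0))
})

test_that("knockdown shifts outside [0, 0.5] are clamped with a warning", {
  cfg <- small_config(p_inactive = 0.05, dp_kd = 0.3, frac_monoallelized = 0.5)
  sa <- simulate_annotation(cfg, seed = 15)
  xci <- simulate_xci_status(sa$annotation, cfg, seed = 15)
  expect_warning(al <- simulate_allele_counts(sa$annotation, xci, cfg, seed = 15),
                 "clamped")
  expect_true(all(al$truth$p_kd >= 0 & al$truth$p_kd <= 0.5))
})

test_that("written simulations read back into equivalent objects", {
  sim <- suppressWarnings(simulate_dataset(small_config(), seed = 16, alleles = TRUE))
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  ann <- read_gene_annotation(paths[["annotation"]], "gtf")
  g0 <- sim$annotation$genes[order(sim$annotation$genes$gene_id), ]
  g1 <- ann$genes[order(ann$genes$gene_id), ]
  rownames(g0) <- rownames(g1) <- NULL
  expect_equal(g1, g0, ignore_attr = TRUE)
  cm <- read_count_matrix(paths[["counts"]], paths[["samples"]])
  expect_equal(cm$counts, sim$counts$counts)
  rt <- read_repeat_annotation(paths[["repeats"]], "bed")
  expect_equal(nrow(rt), nrow(sim$repeats))
  expect_equal(table(rt$repeat_class), table(sim$repeats$repeat_class))
  xci <- read_xci_status(paths[["xci"]])
  expect_equal(xci[names(sim$xci)], sim$xci)
  ac <- read_allele_counts(paths[["alleles"]])
  expect_equal(nrow(ac), nrow(sim$allele_counts))
})
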