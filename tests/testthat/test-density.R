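# Sliding-window density tracks and the correlation layer.

test_that("midpoint floors the average of start and end", {
  expect_equal(midpoint(100, 200), 150)
  expect_equal(midpoint(100, 201), 150)
  expect_equal(midpoint(0, 2), 1)
  expect_error(midpoint(5, 5), "start < end")
})

test_that("window grids contain only full windows, except short chromosomes", {
  w <- make_windows(2e6)
  expect_equal(nrow(w), 5)
  expect_equal(w$start, seq(0, 1e6, by = 2.5e5))
  expect_equal(nrow(make_windows(1e6)), 1)
  short <- make_windows(6e5)
  expect_equal(nrow(short), 1)
  expect_equal(c(short$start, short$end), c(0, 6e5))
  expect_true(attr(short, "truncated"))
  expect_error(make_windows(1e6, window = -1), "positive")
  expect_error(make_windows(1e6, window = 1e5, step = 2e5), "exceed")

  # window count formula on random geometries
  set.seed(31)
  for (i in 1:20) {
    L <- sample(2e6:5e7, 1); win <- sample(5e5:2e6, 1)
    st <- sample(1e5:win, 1)
    expect_equal(nrow(make_windows(L, win, st)),
                 if (L < win) 1 else floor((L - win) / st) + 1)
  }
})

test_that("count mode assigns midpoints to every overlapping window", {
  w <- make_windows(2e6)
  tr <- density_track(5e5, w, "count")
  expect_equal(tr$value, c(1, 1, 1, 0, 0))
  expect_equal(density_track(numeric(), w, "count")$value, rep(0, 5))
})

test_that("coverage mode reports overlapped fraction of the window", {
  w <- make_windows(2e6)
  full <- data.frame(start = 0, end = 2e6)
  expect_equal(density_track(full, w, "coverage")$value, rep(1, 5))
  half <- data.frame(start = 0, end = 5e5)
  expect_equal(density_track(half, w, "coverage")$value[1:3],
               c(0.5, 0.25, 0))
})

test_that("with non-overlapping windows counts sum to the features covered", {
  set.seed(37)
  L <- 1e7
  feats <- data.frame(start = sort(sample(0:(L - 1000), 200)), end = NA)
  feats$end <- feats$start + 500
  w <- make_windows(L, window = 1e6, step = 1e6)
  tr <- density_track(feats, w, "count")
  mids <- midpoint(feats$start, feats$end)
  expect_equal(sum(tr$value), sum(mids < max(w$end)))
})

test_that("pearson handles exact and degenerate cases", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(2, 5)), "constant")
  expect_error(pearson(x, 1:4), "equal length")
})

test_that("partial correlation reproduces the closed-form worked example", {
  v <- exact_correlation_vectors(0.9, 0.8, 0.8)
  res <- partial_correlation(v$x, v$y, v$z)
  expect_equal(res$r, 0.26 / 0.36, tolerance = 1e-10)
  expect_equal(res$r, 0.7222, tolerance = 1e-4)

  # uncorrelated control leaves the correlation untouched
  v2 <- exact_correlation_vectors(0.6, 0, 0)
  expect_equal(partial_correlation(v2$x, v2$y, v2$z)$r, 0.6, tolerance = 1e-10)
})

test_that("partial correlation equals the residual-regression oracle", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    res <- partial_correlation(x, y, z)
    rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
    expect_equal(res$r, cor(rx, ry), tolerance = 1e-10)
  }
  expect_error(partial_correlation(1:5, c(2, 1, 4, 3, 5), 2 * (1:5)),
               "collinear")
})

test_that("pearson and partial correlations are invariant under affine rescaling", {
  set.seed(43)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50); z <- rnorm(50)
  expect_equal(pearson(3 * x + 1, y)$r, pearson(x, y)$r, tolerance = 1e-12)
  expect_equal(partial_correlation(2 * x - 5, 0.1 * y + 2, z)$r,
               partial_correlation(x, y, z)$r, tolerance = 1e-12)
})

test_that("DEG position table reports midpoints, direction and the XIST flag", {
  ann <- genome_annotation(data.frame(
    gene_id = c("g1", "XIST", "g3", "auto1"),
    chrom = c("chrX", "chrX", "chrX", "chr1"),
    start = c(100, 1000, 5000, 0), end = c(200, 2000, 6000, 900),
    strand = "+"))
  de <- de_table(data.frame(
    gene_id = c("g1", "XIST", "g3", "auto1"),
    log2fc = c(1.2, -3, 0.1, 2),
    pvalue = c(0.001, 0.001, 0.5, 0.001),
    padj = c(0.01, 0.001, 0.9, 0.01)))
  pos <- deg_position_table(de, ann, chrom = "chrX", xci = c(g1 = "escape"))
  expect_equal(nrow(pos), 2)  # g3 is not a DEG; auto1 is not on chrX
  expect_equal(pos$position[pos$gene_id == "g1"], 150)
  expect_equal(pos$direction, c("up", "down"))
  expect_true(pos$escape[pos$gene_id == "g1"])
  expect_true(pos$is_xist[pos$gene_id == "XIST"])

  empty <- deg_position_table(tiny_de(), tiny_annotation(), chrom = "chrX")
  expect_equal(nrow(empty), 0)
})

test_that("cross-dataset correlation demands a shared grid", {
  w <- make_windows(5e6)
  t1 <- density_track(c(1e6, 2e6, 3e6), w, "count")
  expect_equal(cross_dataset_correlation(t1, t1)$r, 1)
  t2 <- density_track(c(1e6), make_windows(5e6, step = 5e5), "count")
  expect_error(cross_dataset_correlation(t1, t2), "grid")
})

test_that("density_correlations builds all tracks and the partial column", {
  sim <- simulate_dataset(small_config(), seed = 3, alleles = FALSE)
  de <- de_test(sim$counts)
  da <- density_correlations(de, sim$annotation, sim$repeats)
  expect_named(da$tracks, c("genes", "deg_all", "deg_up", "deg_down",
                            "sine", "line"))
  expect_true(any(da$correlations$kind == "partial"))
  expect_true(all(abs(da$correlations$r) <= 1))
})
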