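# Normalization, expression summaries and the minimal NB Wald test.

test_that("size factors follow the median-of-ratios formula", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(size_factors(cbind(a = c(5, 9), b = c(5, 9)))), c(1, 1))

  # all-zero gene is excluded from the reference and changes nothing
  m2 <- rbind(m, g4 = c(0, 0))
  expect_equal(size_factors(m2), size_factors(m))

  expect_error(size_factors(cbind(a = c(0, 3), b = c(2, 0))), "reference gene")
})

test_that("size factors are scale-equivariant and match the DESeq2 estimator", {
  set.seed(42)
  m <- matrix(rnbinom(600, mu = 100, size = 10), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  sf <- size_factors(m)
  m3 <- m; m3[, 2] <- m3[, 2] * 3
  # equivariance holds for factor ratios: scaling one sample's counts by c
  # scales its factor relative to every other sample by c
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3[2] / sf3[1]), unname(3 * sf[2] / sf[1]),
               tolerance = 1e-12)

  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("TPM matches its closed form and is depth-invariant", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tp <- tpm(m, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tp[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(colSums(tp), c(s1 = 1e6))

  single <- matrix(7, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(unname(tpm(single, 500)[1, 1]), 1e6)

  set.seed(1)
  m2 <- matrix(rpois(20, 40) + 1, 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  len <- stats::setNames(sample(500:5000, 5), rownames(m2))
  expect_equal(tpm(2 * m2, len), tpm(m2, len))
  expect_equal(unname(colSums(tpm(m2, len))), rep(1e6, 4))
  expect_error(tpm(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s")),
                   c(a = 100, b = 100)), "all-zero")
})

test_that("FPKM follows 1e9 * c / (L * N)", {
  m <- matrix(c(100, 300), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  fk <- fpkm(m, c(g1 = 2000, g2 = 1000), lib_sizes = 1e6)
  expect_equal(unname(fk[, 1]), c(1e9 * 100 / (2000 * 1e6),
                                  1e9 * 300 / (1000 * 1e6)))
})

test_that("percent reduction is 100 * (1 - deficient/control), unclamped", {
  expect_equal(percent_reduction(100, 8), 92)
  expect_equal(percent_reduction(100, 100), 0)
  expect_equal(percent_reduction(100, 40), 60)   # inside the 50-70% band
  expect_equal(percent_reduction(100, 150), -50) # upregulation allowed
  expect_error(percent_reduction(0, 10), "control")
})

test_that("DEG classification uses strict cutoffs and treats missing padj as none", {
  de <- de_table(data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(0.60, 0.58, -1.2, -0.59, 0.9),
    pvalue = c(0.001, 0.001, 0.01, 0.001, 0.2),
    padj = c(0.01, 0.001, NA, 0.04, 0.5)))
  expect_equal(de$deg_class, c("up", "none", "none", "down", "none"))
})

test_that("DEG classification is monotone in padj and |log2fc|", {
  set.seed(3)
  for (i in 1:50) {
    lfc <- runif(1, -3, 3); padj <- runif(1)
    base <- classify_degs(data.frame(gene_id = "g", log2fc = lfc,
                                     pvalue = padj, padj = padj))$deg_class
    better <- classify_degs(data.frame(gene_id = "g", log2fc = lfc * 1.5,
                                       pvalue = padj, padj = padj / 2))$deg_class
    if (base != "none") expect_equal(better, base)
  }
})

test_that("fold change from FPKM pairs averages ratios and handles zero WT", {
  expect_equal(fc_from_fpkm(c(1, 2), c(2, 4)), 2)
  expect_equal(fc_from_fpkm(c(2, 1), c(4, 1)), 1.5)
  expect_equal(fc_from_fpkm(c(1, 1), c(1, 1)), 1)
  expect_warning(fc <- fc_from_fpkm(c(0, 1), c(5, 3)), "skipped")
  expect_equal(fc, 3)
  expect_warning(fc0 <- fc_from_fpkm(c(0, 0), c(5, 3)), "skipped")
  expect_true(is.na(fc0))
})

test_that("expressed-gene filter is inclusive at the threshold", {
  m <- matrix(c(1.0, 0.99, 5), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  expect_equal(filter_expressed(m, 1), c("a", "c"))
  expect_equal(filter_expressed(m[0, , drop = FALSE]), character())
})

test_that("BH adjustment equals the textbook definition on random p-vectors", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("the NB Wald test detects a strong single-gene effect", {
  set.seed(21)
  n <- 500
  mu <- rlnorm(n, log(200), 1)
  counts <- sapply(1:6, function(j) rnbinom(n, mu = mu, size = 1 / 0.03))
  # gene 1: true log2 fold change 2 at mean 500 in the deficient triplet
  counts[1, ] <- rnbinom(6, mu = 500 * c(1, 1, 1, 4, 4, 4), size = 1 / 0.03)
  dimnames(counts) <- list(paste0("g", 1:n), paste0("s", 1:6))
  cm <- count_matrix(counts, rep(c("control", "deficient"), each = 3))
  de <- de_test(cm)
  expect_equal(de$deg_class[1], "up")
  expect_equal(de$log2fc[1], 2, tolerance = 0.5)
})

test_that("the NB Wald test is calibrated under the null", {
  set.seed(31)
  fr <- vapply(1:5, function(s) {
    n <- 2000
    mu <- rlnorm(n, log(150), 1)
    disp <- rlnorm(n, log(0.03), 0.5)
    counts <- sapply(1:6, function(j) rnbinom(n, mu = mu, size = 1 / disp))
    dimnames(counts) <- list(paste0("g", 1:n), paste0("s", 1:6))
    cm <- count_matrix(counts, rep(c("control", "deficient"), each = 3))
    de <- de_test(cm)
    mean(de$pvalue < 0.05, na.rm = TRUE)
  }, 1.0)
  expect_gt(mean(fr), 0.03)
  expect_lt(mean(fr), 0.07)
})

test_that("all-zero genes get missing p and no DEG call", {
  m <- rbind(g1 = c(10, 12, 9, 30, 33, 28), g0 = rep(0, 6),
             g2 = c(20, 18, 22, 21, 19, 20))
  colnames(m) <- paste0("s", 1:6)
  cm <- count_matrix(m, rep(c("control", "deficient"), each = 3))
  de <- de_test(cm)
  expect_true(is.na(de$pvalue[de$gene_id == "g0"]))
  expect_true(is.na(de$padj[de$gene_id == "g0"]))
  expect_equal(de$deg_class[de$gene_id == "g0"], "none")
})

test_that("de_test requires two samples per condition", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  cm <- count_matrix(m, c("control", "deficient"))
  expect_error(de_test(cm), "2 samples per condition")
})
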