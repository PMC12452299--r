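# I/O layer: coordinate conventions, validation, round trips.

test_that("GTF coordinates convert to 0-based half-open and round-trip", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\tgene\t501\t800\t.\t-\t.\tgene_id "g2";',
    'chrX\tsrc\tgene\t11\t60\t.\t+\t.\tgene_id "g3";'), gtf)
  ann <- read_gene_annotation(gtf, "gtf")
  expect_equal(nrow(ann$genes), 3)
  g1 <- ann$genes[ann$genes$gene_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(100, 200))

  # write -> read restores the original 1-based coordinates field-for-field
  out <- tempfile(fileext = ".gtf")
  write_gene_annotation(ann, out)
  ann2 <- read_gene_annotation(out, "gtf")
  expect_equal(ann2$genes[order(ann2$genes$gene_id), ],
               ann$genes[order(ann$genes$gene_id), ],
               ignore_attr = TRUE)
  raw <- grep("\tgene\t", readLines(out), value = TRUE)
  expect_true(any(grepl("\t101\t200\t", raw)))
})

test_that("annotation validation enforces interval and uniqueness invariants", {
  bad <- data.frame(gene_id = "g1", chrom = "chr1", start = 200, end = 100,
                    strand = "+")
  expect_error(genome_annotation(bad), "start < end")
  dup <- data.frame(gene_id = c("g", "g"), chrom = "chr1",
                    start = c(0, 10), end = c(5, 20), strand = "+")
  expect_error(genome_annotation(dup), "duplicated")
  over <- data.frame(gene_id = "g1", chrom = "chr1", start = 0, end = 500,
                     strand = "+")
  expect_error(genome_annotation(over, chrom_lengths = c(chr1 = 100)),
               "beyond chromosome end")
})

test_that("chromosome naming is normalized to the chr dialect", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = c("X", "chrX"),
                  start = c(0, 100), end = c(50, 150), strand = "+")
  ann <- genome_annotation(g)
  expect_equal(unique(ann$genes$chrom), "chrX")
})

test_that("RepeatMasker .out classes map by prefix and headers are skipped", {
  out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end  (left)    repeat    class/family  begin end (left) ID",
    "",
    "  463  11.4  0.0  0.0  chrX  101  400  (1000)  +  AluY   SINE/Alu   1  300  (0)  1",
    "  999   8.0  0.1  0.2  chrX  1001 4000 (500)   -  L1MA   LINE/L1    1  3000 (0)  2",
    " 120  20.0  0.0  0.0  chrX  5001 5500 (100)   +  Tigger DNA/hAT    1  500  (0)  3"), out)
  rt <- read_repeat_annotation(out, "repeatmasker_out")
  expect_equal(nrow(rt), 3)
  expect_equal(rt$repeat_class, c("SINE", "LINE", "other"))
  expect_equal(rt$start[1], 100)  # 1-based inclusive -> 0-based
  expect_equal(rt$end[1], 400)
})

test_that("empty BED yields an empty repeat track; BED4 parses classes", {
  bed <- tempfile(fileext = ".bed")
  writeLines(character(), bed)
  expect_equal(nrow(read_repeat_annotation(bed, "bed")), 0)
  writeLines(c("chrX\t0\t300\tSINE/Alu", "chrX\t1000\t4000\tLINE"), bed)
  rt <- read_repeat_annotation(bed, "bed")
  expect_equal(rt$repeat_class, c("SINE", "LINE"))
})

test_that("DE table reader preserves NA padj, rejects duplicates and missing columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbaseMean\tlog2FoldChange\tpvalue\tpadj",
               "g1\t100\t0.6\t0.001\t0.01",
               "g2\t50\t-1.2\t0.2\tNA",
               "g3\t10\t0.1\t0.9\t0.95",
               "g4\t5\t2.0\t0.0001\t0.002",
               "g5\t80\t-0.7\t0.01\t0.04"), f)
  de <- read_de_table(f, "deseq2_results")
  expect_equal(nrow(de), 5)
  expect_true(is.na(de$padj[de$gene_id == "g2"]))
  expect_equal(de$deg_class[de$gene_id == "g2"], "none")

  writeLines(c("gene_id\tlog2FoldChange\tpvalue\tpadj",
               "g1\t1\t0.1\t0.1", "g1\t2\t0.1\t0.1"), f)
  expect_error(read_de_table(f, "deseq2_results"), "duplicated.*g1")

  writeLines(c("gene_id\tlog2FoldChange\tpvalue", "g1\t1\t0.1"), f)
  expect_error(read_de_table(f, "deseq2_results"), "padj")
})

test_that("fpkm_pair dialect computes fold change by averaging replicate ratios", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\twt_fpkm_1\twt_fpkm_2\tko_fpkm_1\tko_fpkm_2",
               "g1\t2\t1\t4\t1"), f)
  de <- read_de_table(f, "fpkm_pair")
  expect_equal(de$log2fc, log2(1.5))
})

test_that("allele counts and XCI status parse and validate", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tpos\tsample_id\trefCount\taltCount",
               "GTPBP6\tchrX\t1000\tCTRL\t30\t10"), f)
  ac <- read_allele_counts(f)
  expect_equal(nrow(ac), 1)
  expect_equal(ac$ref_count, 30)

  writeLines(c("gene_id\tchrom\tpos\tsample_id\trefCount\taltCount",
               "GTPBP6\tchrX\t1000\tCTRL\t-1\t10"), f)
  expect_error(read_allele_counts(f), "negative")

  x <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tstatus", "g1\tEscape", "g2\tinactive", "g3\tweird"), x)
  expect_warning(xci <- read_xci_status(x), "unknown")
  expect_equal(unname(xci[c("g1", "g2", "g3")]),
               c("escape", "inactive", "unknown"))
})

test_that("count matrix round-trips through its TSV writers", {
  m <- matrix(rpois(12, 50), 4, 3,
              dimnames = list(paste0("g", 1:4), c("c1", "c2", "k1")))
  cm <- count_matrix(m, c("control", "control", "deficient"))
  cp <- tempfile(); mp <- tempfile()
  write_count_matrix(cm, cp, mp)
  cm2 <- read_count_matrix(cp, mp)
  expect_equal(cm2$counts, cm$counts)
  expect_equal(cm2$samples, cm$samples)
})
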