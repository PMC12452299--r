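## annotations-io: read and normalize external formats into the internal data
## model.  One coordinate convention everywhere: 0-based half-open intervals.
## Conversion from 1-based inclusive (GTF) happens at the I/O boundary only.

#' Construct a genome annotation
#'
#' The internal gene model used throughout the package: one row per gene with
#' chromosome, 0-based half-open interval, strand and a length used for
#' TPM/FPKM normalization, plus per-chromosome lengths.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `length` (defaults to `end - start`).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp. If
#'   `NULL`, each chromosome's length is set to the maximum gene end on it.
#' @return object of class `genome_annotation`: list with elements `genes`
#'   (validated data.frame) and `chrom_lengths`.
#' @examples
#' genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
#'                     start = c(0, 500), end = c(400, 900), strand = "+")
#' ann <- genome_annotation(genes)
#' ann$chrom_lengths
#' @export
genome_annotation <- function(genes, chrom_lengths = NULL) {
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0)
    stopf("gene table is missing column(s): %s", paste(missing, collapse = ", "))
  genes$chrom <- norm_chrom(genes$chrom)
  genes$strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  if (is.null(genes$length)) genes$length <- genes$end - genes$start
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stopf("duplicated gene id(s): %s", paste(utils::head(dup, 10), collapse = ", "))
  }
  bad <- which(!(genes$start >= 0 & genes$start < genes$end))
  if (length(bad) > 0)
    stopf("invalid interval (need 0 <= start < end) for gene(s): %s",
          paste(utils::head(genes$gene_id[bad], 10), collapse = ", "))
  if (any(genes$length <= 0)) stopf("gene length must be > 0")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  } else {
    names(chrom_lengths) <- norm_chrom(names(chrom_lengths))
    absent <- setdiff(unique(genes$chrom), names(chrom_lengths))
    if (length(absent) > 0)
      stopf("chrom_lengths missing chromosome(s): %s", paste(absent, collapse = ", "))
    over <- genes$end > chrom_lengths[genes$chrom]
    if (any(over))
      stopf("gene(s) extend beyond chromosome end: %s",
            paste(utils::head(genes$gene_id[over], 10), collapse = ", "))
  }
  structure(list(genes = genes[, c(required, "length")],
                 chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(x$chrom_lengths)))
  tab <- table(x$genes$chrom)
  tab <- tab[sort_chroms(names(tab))]
  print(utils::head(as.data.frame(tab, responseName = "n_genes"), 30))
  invisible(x)
}

#' Read a gene annotation from GTF or BED
#'
#' GTF coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention; BED is already half-open and passes through. For GTF,
#' only `gene`-typed records are used when a `type` field is present.
#'
#' @param path file path.
#' @param format `"gtf"` or `"bed"`.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return [genome_annotation()] object.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed"),
                                 chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) stopf("failed to parse %s as %s: %s",
                                           path, format, conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (format == "gtf" && "type" %in% names(md)) {
    keep <- as.character(md$type) == "gene"
    if (any(keep)) { gr <- gr[keep]; md <- S4Vectors::mcols(gr) }
  }
  ids <- if ("gene_id" %in% names(md)) as.character(md$gene_id)
         else if ("name" %in% names(md)) as.character(md$name)
         else stopf("no gene identifier (gene_id attribute or BED name column) in %s", path)
  genes <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # rtracklayer yields 1-based inclusive starts for both formats
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if ("gene_length" %in% names(md)) genes$length <- as.numeric(md$gene_length)
  if (is.null(chrom_lengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(sl) > 0 && !all(is.na(sl))) chrom_lengths <- sl[!is.na(sl)]
  }
  genome_annotation(genes, chrom_lengths = chrom_lengths)
}

#' Write a gene annotation as GTF
#'
#' Emits one `gene` record per gene, converting back to the 1-based inclusive
#' GTF convention (so read/write round-trips are exact), with `gene_id` and
#' `gene_length` attributes.
#'
#' @param ann [genome_annotation()] object.
#' @param path output path.
#' @export
write_gene_annotation <- function(ann, path) {
  g <- ann$genes
  attrs <- sprintf('gene_id "%s"; gene_length %d;', g$gene_id, as.integer(g$length))
  lines <- sprintf("%s\txresponse\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   g$chrom, g$start + 1L, g$end,
                   ifelse(g$strand %in% c("+", "-"), g$strand, "."), attrs)
  hdr <- sprintf("##chrom_length %s %d", names(ann$chrom_lengths),
                 as.integer(ann$chrom_lengths))
  writeLines(c(hdr, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read a repeat annotation into SINE/LINE/other classes
#'
#' RepeatMasker `.out` files carry a class/family column such as `SINE/Alu` or
#' `LINE/L1`; the class is taken from the prefix before `/` and anything that
#' is not SINE or LINE is mapped to `"other"`. BED input takes the class from
#' the name (4th) column.
#'
#' @param path file path.
#' @param format `"repeatmasker_out"` or `"bed"`.
#' @return data.frame of class `repeat_track` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `repeat_class`.
#' @export
read_repeat_annotation <- function(path, format = c("repeatmasker_out", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("repeat file not found: %s", path)
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
    if (length(lines) == 0)
      return(repeat_track(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), repeat_class = character())))
    f <- strsplit(lines, "\t", fixed = TRUE)
    n <- vapply(f, length, 1L)
    if (any(n < 4)) stopf("BED repeat line %d has fewer than 4 columns",
                          which(n < 4)[1])
    df <- data.frame(chrom = vapply(f, `[[`, "", 1),
                     start = as.numeric(vapply(f, `[[`, "", 2)),
                     end = as.numeric(vapply(f, `[[`, "", 3)),
                     repeat_class = vapply(f, `[[`, "", 4),
                     stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    # header: two column-name lines plus a blank line; also tolerate headerless
    body <- lines[!grepl("^\\s*$", lines) &
                  !grepl("^\\s*(SW|score)\\b", lines, ignore.case = TRUE)]
    if (length(body) == 0)
      return(repeat_track(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), repeat_class = character())))
    f <- strsplit(trimws(body), "\\s+")
    n <- vapply(f, length, 1L)
    if (any(n < 11)) stopf("RepeatMasker .out body line %d has %d fields (need >= 11)",
                           which(n < 11)[1], min(n))
    df <- data.frame(chrom = vapply(f, `[[`, "", 5),
                     start = as.numeric(vapply(f, `[[`, "", 6)) - 1, # 1-based inclusive
                     end = as.numeric(vapply(f, `[[`, "", 7)),
                     repeat_class = vapply(f, `[[`, "", 11),
                     stringsAsFactors = FALSE)
  }
  repeat_track(df)
}

#' Construct/validate a repeat track
#'
#' @param df data.frame with `chrom`, `start`, `end`, `repeat_class`.
#' @return validated `repeat_track` data.frame with `repeat_class` collapsed
#'   to the closed vocabulary `SINE`/`LINE`/`other`.
#' @export
repeat_track <- function(df) {
  required <- c("chrom", "start", "end", "repeat_class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("repeat table missing column(s): %s", paste(missing, collapse = ", "))
  df$chrom <- norm_chrom(df$chrom)
  if (nrow(df) > 0 && any(!(df$start >= 0 & df$start < df$end)))
    stopf("repeat element with invalid interval (need 0 <= start < end)")
  cls <- toupper(sub("/.*$", "", df$repeat_class))
  df$repeat_class <- ifelse(cls == "SINE", "SINE",
                            ifelse(cls == "LINE", "LINE", "other"))
  class(df) <- c("repeat_track", "data.frame")
  df
}

#' Read a differential-expression table
#'
#' Two dialects: `deseq2_results` (the tab-separated results table written by
#' standard count-based DE tools: gene id, log2FoldChange, pvalue, padj) and
#' `fpkm_pair` (gene id plus paired WT/KO replicate FPKM columns named
#' `wt_fpkm_*` / `ko_fpkm_*`, from which a fold change is computed by
#' averaging per-replicate KO/WT ratios).
#'
#' Missing `padj` values (`NA` in the file) are preserved as missing, never
#' coerced to zero; duplicated gene ids are an error.
#'
#' @param path file path.
#' @param dialect `"deseq2_results"` or `"fpkm_pair"`.
#' @return `de_table` data.frame (see [de_table()]).
#' @export
read_de_table <- function(path, dialect = c("deseq2_results", "fpkm_pair")) {
  dialect <- match.arg(dialect)
  if (dialect == "deseq2_results") {
    df <- read_tsv_checked(path, c("log2FoldChange", "pvalue", "padj"), "DE")
    id_col <- intersect(c("gene_id", "gene", "id"), names(df))
    if (length(id_col) == 0)
      stopf("DE table %s has no gene id column (gene_id/gene/id)", path)
    out <- data.frame(gene_id = as.character(df[[id_col[1]]]),
                      base_mean = if ("baseMean" %in% names(df))
                        as.numeric(df$baseMean) else NA_real_,
                      log2fc = as.numeric(df$log2FoldChange),
                      pvalue = as.numeric(df$pvalue),
                      padj = as.numeric(df$padj),
                      stringsAsFactors = FALSE)
    if ("deg_class" %in% names(df)) out$deg_class <- df$deg_class
    de_table(out)
  } else {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    id_col <- intersect(c("gene_id", "gene", "id"), names(df))
    if (length(id_col) == 0) stopf("FPKM table %s has no gene id column", path)
    wt <- grep("^wt_fpkm", names(df), value = TRUE)
    ko <- grep("^ko_fpkm", names(df), value = TRUE)
    if (length(wt) == 0 || length(ko) == 0)
      stopf("FPKM-pair table %s needs wt_fpkm_* and ko_fpkm_* columns", path)
    if (length(wt) != length(ko))
      stopf("unpaired replicate columns: %d WT vs %d KO", length(wt), length(ko))
    fc <- vapply(seq_len(nrow(df)), function(i)
      fc_from_fpkm(as.numeric(df[i, wt]), as.numeric(df[i, ko])), 1.0)
    de_table(data.frame(gene_id = as.character(df[[id_col[1]]]),
                        base_mean = rowMeans(df[, wt, drop = FALSE]),
                        log2fc = log2(fc), pvalue = NA_real_, padj = NA_real_,
                        stringsAsFactors = FALSE))
  }
}

#' Construct/validate a DE table
#'
#' @param df data.frame with `gene_id`, `log2fc`, `pvalue`, `padj`, optional
#'   `base_mean` and `deg_class`.
#' @return `de_table` data.frame; `deg_class` filled by [classify_degs()] when
#'   absent.
#' @export
de_table <- function(df) {
  required <- c("gene_id", "log2fc", "pvalue", "padj")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("DE table missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id)) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    stopf("duplicated gene id(s) in DE table: %s",
          paste(utils::head(dup, 10), collapse = ", "))
  }
  ok <- function(p) all(is.na(p) | (p >= 0 & p <= 1))
  if (!ok(df$pvalue) || !ok(df$padj)) stopf("p-values must lie in [0, 1]")
  if (is.null(df$base_mean)) df$base_mean <- NA_real_
  cls <- c("de_table", "data.frame")
  class(df) <- cls
  if (is.null(df$deg_class)) df <- classify_degs(df)
  df
}

#' Write a DE table in the deseq2_results dialect
#' @param de `de_table`.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(gene_id = de$gene_id, baseMean = de$base_mean,
                    log2FoldChange = de$log2fc, pvalue = de$pvalue,
                    padj = de$padj, deg_class = de$deg_class)
  write_tsv(out, path)
}

#' Read per-SNP allelic read counts
#'
#' Expects a tab-separated table with columns `gene_id`, `chrom`, `pos`,
#' `sample_id`, `ref_count`, `alt_count` (the `refCount`/`altCount` spellings
#' are also accepted). Negative counts are a validation error.
#'
#' @param path file path.
#' @return `allele_counts` data.frame.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[names(df) == "refCount"] <- "ref_count"
  names(df)[names(df) == "altCount"] <- "alt_count"
  required <- c("gene_id", "chrom", "pos", "sample_id", "ref_count", "alt_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("allele-count table %s missing column(s): %s", path,
          paste(missing, collapse = ", "))
  allele_counts(df[, required])
}

#' Construct/validate an allele-count table
#' @param df data.frame with the columns documented in [read_allele_counts()].
#' @return validated `allele_counts` data.frame.
#' @export
allele_counts <- function(df) {
  df$chrom <- norm_chrom(df$chrom)
  if (any(df$ref_count < 0 | df$alt_count < 0))
    stopf("negative allelic read counts")
  class(df) <- c("allele_counts", "data.frame")
  df
}

#' Write an allele-count table
#' @param ac `allele_counts` data.frame.
#' @param path output path.
#' @export
write_allele_counts <- function(ac, path) write_tsv(as.data.frame(ac), path)

#' Read an XCI status table
#'
#' Tab-separated `gene_id` / `status` table; statuses are matched
#' case-insensitively against the closed vocabulary `escape`, `inactive`,
#' `variable`, `unknown`. Unrecognized labels map to `"unknown"` with a
#' warning.
#'
#' @param path file path.
#' @return named character vector gene id -> status.
#' @export
read_xci_status <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "status"), "XCI status")
  status <- tolower(trimws(df$status))
  known <- c("escape", "inactive", "variable", "unknown")
  bad <- !(status %in% known)
  if (any(bad)) {
    warnf("%d unrecognized XCI label(s) (e.g. %s) mapped to 'unknown'",
          sum(bad), paste(utils::head(unique(df$status[bad]), 3), collapse = ", "))
    status[bad] <- "unknown"
  }
  stats::setNames(status, df$gene_id)
}

#' Write an XCI status table
#' @param xci named character vector gene id -> status.
#' @param path output path.
#' @export
write_xci_status <- function(xci, path)
  write_tsv(data.frame(gene_id = names(xci), status = unname(xci)), path)

#' Construct a count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param condition character vector (one per sample) with values `"control"`
#'   or `"deficient"`.
#' @param replicate optional integer replicate index per sample.
#' @return object of class `count_matrix`: list with `counts` and `samples`.
#' @export
count_matrix <- function(counts, condition, replicate = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix needs gene row names and sample column names")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (length(condition) != ncol(counts))
    stopf("condition must have one entry per sample")
  if (!all(condition %in% c("control", "deficient")))
    stopf("condition values must be 'control' or 'deficient'")
  if (!all(c("control", "deficient") %in% condition))
    stopf("need at least one sample in each condition")
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  structure(list(counts = counts,
                 samples = data.frame(sample_id = colnames(counts),
                                      condition = condition,
                                      replicate = as.integer(replicate),
                                      stringsAsFactors = FALSE)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d control, %d deficient)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$condition == "control"),
              sum(x$samples$condition == "deficient")))
  invisible(x)
}

#' Read a count matrix plus sample metadata
#'
#' @param counts_path tab-separated genes x samples table; first column
#'   `gene_id`.
#' @param meta_path tab-separated table with columns `sample_id`,
#'   `condition`, `replicate`.
#' @return [count_matrix()] object.
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stopf("first column of %s must be gene_id", counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  meta <- read_tsv_checked(meta_path, c("sample_id", "condition", "replicate"),
                           "sample metadata")
  if (!setequal(meta$sample_id, colnames(m)))
    stopf("sample ids in %s and %s disagree", counts_path, meta_path)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  count_matrix(m, meta$condition, meta$replicate)
}

#' Write a count matrix and its sample metadata
#' @param cm [count_matrix()] object.
#' @param counts_path,meta_path output paths.
#' @export
write_count_matrix <- function(cm, counts_path, meta_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(cm$samples, meta_path)
  invisible(counts_path)
}
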