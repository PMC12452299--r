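## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Normalize chromosome names to the "chr" dialect
#'
#' Datasets mix `"X"` and `"chrX"` naming; all internal tables use the
#' `"chr"`-prefixed form so joins never silently drop genes.
#'
#' @param x character vector of chromosome names.
#' @return character vector with a `"chr"` prefix on every name.
#' @examples
#' norm_chrom(c("X", "chrX", "1", "MT"))
#' @export
norm_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

## Natural chromosome ordering: chr1 < chr2 < ... < chr22 < chrX < chrY < chrM,
## anything unrecognized after that, alphabetically.  Used for deterministic
## tie-breaking in rankings and control-chromosome selection.
chrom_order_key <- function(chrom) {
  body <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(body))
  special <- match(body, c("X", "Y", "M", "MT"))
  key <- ifelse(!is.na(num), num,
                ifelse(!is.na(special), 100L + special, 200L))
  order(key, body)
}

sort_chroms <- function(chrom) chrom[chrom_order_key(chrom)]

is_autosome <- function(chrom) {
  body <- sub("^chr", "", chrom)
  !is.na(suppressWarnings(as.integer(body)))
}

## Run an expression under a fixed RNG seed, restoring the caller's RNG state.
## Keeps the generator fully deterministic per stage without clobbering the
## session stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Deterministic sub-seed per pipeline stage, kept below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + offs * 104729) %% 2147483629)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("%s table %s is missing required column(s): %s",
          what, path, paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
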