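## overlap: multi-dataset DEG intersections (UpSet-style exclusive membership
## counts) and plain shared-DEG extraction.

#' Build a DEG set collection from DE tables
#'
#' @param de_list named list of `de_table` objects (labels are dataset names).
#' @return object of class `deg_set_collection`: named list with `up` and
#'   `down` gene-id sets per dataset.
#' @export
deg_set_collection <- function(de_list) {
  if (is.null(names(de_list)) || any(!nzchar(names(de_list))))
    stopf("de_list must be a named list of DE tables")
  sets <- lapply(de_list, function(de) {
    list(up = sort(unique(de$gene_id[de$deg_class == "up"])),
         down = sort(unique(de$gene_id[de$deg_class == "down"])))
  })
  structure(sets, class = "deg_set_collection")
}

collection_sets <- function(collection, direction) {
  if (!(direction %in% c("up", "down")))
    stopf("direction must be 'up' or 'down'")
  lapply(collection, `[[`, direction)
}

#' Exclusive DEG intersection counts (UpSet semantics)
#'
#' Every gene in the union is assigned to exactly one membership combination
#' (the exact set of datasets containing it), so the counts over all
#' combinations sum to the union size. Also returns the full-intersection
#' gene list (genes present in every dataset), sorted.
#'
#' @param collection [deg_set_collection()] (or a plain named list of
#'   gene-id sets, in which case `direction` is ignored).
#' @param direction `"up"` or `"down"`.
#' @return list with `counts` (data.frame `combo`, `degree`, `count`, one row
#'   per non-empty combination, largest degree first) and
#'   `full_intersection` (character vector).
#' @examples
#' col <- list(A = list(up = c("g1", "g2"), down = character()),
#'             B = list(up = c("g2", "g3"), down = character()))
#' class(col) <- "deg_set_collection"
#' deg_intersections(col, "up")$counts
#' @export
deg_intersections <- function(collection, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sets <- if (inherits(collection, "deg_set_collection"))
    collection_sets(collection, direction) else collection
  if (length(sets) < 2) stopf("need at least two datasets")
  labels <- names(sets)
  genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, labels))
  combo <- apply(member, 1, function(m) paste(labels[m], collapse = "&"))
  if (length(genes) == 0) {
    counts <- data.frame(combo = character(), degree = integer(),
                         count = integer())
  } else {
    tab <- table(combo)
    counts <- data.frame(combo = names(tab), count = as.integer(tab),
                         stringsAsFactors = FALSE)
    counts$degree <- lengths(strsplit(counts$combo, "&", fixed = TRUE))
    counts <- counts[order(-counts$degree, -counts$count, counts$combo),
                     c("combo", "degree", "count")]
    rownames(counts) <- NULL
  }
  full <- if (length(genes) > 0) genes[rowSums(member) == length(sets)]
          else character()
  list(counts = counts, full_intersection = sort(full))
}

#' Plain intersection of DEGs across named datasets
#'
#' Non-exclusive intersection: genes present in every dataset of the subset,
#' regardless of membership elsewhere.
#'
#' @param collection [deg_set_collection()].
#' @param subset character vector of dataset labels (default: all).
#' @param direction `"up"` or `"down"`.
#' @return sorted character vector of shared gene ids.
#' @export
shared_degs <- function(collection, subset = NULL, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sets <- collection_sets(collection, direction)
  if (is.null(subset)) subset <- names(sets)
  unknown <- setdiff(subset, names(sets))
  if (length(unknown) > 0)
    stopf("unknown dataset label(s): %s", paste(unknown, collapse = ", "))
  sort(Reduce(intersect, sets[subset]))
}
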