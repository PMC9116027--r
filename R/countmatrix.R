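#' Gene-by-location count matrix with depth offsets
#'
#' The container consumed by every analysis stage: a non-negative integer
#' matrix with genes as rows and spatial locations (spots, beads, cells)
#' as columns, plus per-location total counts \eqn{N_i} used as offsets in
#' all count models. Offsets are always recomputed from the matrix itself so
#' that filtering and subsetting stay internally consistent.
#'
#' @param counts matrix or [Matrix::sparseMatrix()] of non-negative integers,
#'   genes in rows.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   rownames or `gene1..geneG`.
#' @param location_ids character vector of unique location identifiers;
#'   defaults to colnames or `loc1..locn`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `gene_ids`, `location_ids` and `offsets` (column sums).
#' @export
count_matrix <- function(counts, gene_ids = NULL, location_ids = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  assert_that(length(dim(counts)) == 2L, "`counts` must be a matrix")
  x <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  assert_that(all(is.finite(x@x)), "counts contain non-finite entries")
  assert_that(all(x@x >= 0), "counts contain negative entries")
  assert_that(all(x@x == floor(x@x)), "counts contain non-integer entries")
  gene_ids <- as.character(gene_ids %||% rownames(counts) %||% paste0("gene", seq_len(nrow(x))))
  location_ids <- as.character(location_ids %||% colnames(counts) %||% paste0("loc", seq_len(ncol(x))))
  assert_that(length(gene_ids) == nrow(x), "gene_ids length does not match row count")
  assert_that(length(location_ids) == ncol(x), "location_ids length does not match column count")
  assert_that(!anyDuplicated(gene_ids), "duplicate gene ids")
  assert_that(!anyDuplicated(location_ids), "duplicate location ids")
  dimnames(x) <- list(gene_ids, location_ids)
  structure(
    list(
      counts = x,
      gene_ids = gene_ids,
      location_ids = location_ids,
      offsets = Matrix::colSums(x)
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  nz <- length(x$counts@x)
  cat(sprintf(
    "count_matrix: %d genes x %d locations (%.1f%% nonzero), median location total %g\n",
    nrow(x$counts), ncol(x$counts),
    100 * nz / prod(dim(x$counts)), stats::median(x$offsets)
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or location
#'
#' Offsets are recomputed from the retained columns.
#' @param m a [count_matrix()].
#' @param genes,locations indices, logical masks or id vectors; `NULL` keeps all.
#' @return a `count_matrix`.
#' @export
subset_counts <- function(m, genes = NULL, locations = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else resolve_index(genes, m$gene_ids, "gene")
  li <- if (is.null(locations)) seq_along(m$location_ids) else resolve_index(locations, m$location_ids, "location")
  count_matrix(m$counts[gi, li, drop = FALSE],
               gene_ids = m$gene_ids[gi], location_ids = m$location_ids[li])
}

#' @noRd
resolve_index <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    assert_that(!anyNA(pos), sprintf("unknown %s ids", what))
    return(pos)
  }
  if (is.logical(idx)) {
    assert_that(length(idx) == length(ids), sprintf("logical %s mask has wrong length", what))
    return(which(idx))
  }
  as.integer(idx)
}

#' Remove all-zero genes (and empty locations)
#'
#' Standard pre-analysis filtering: genes with zero counts at every location
#' carry no likelihood information and are dropped; locations with a zero
#' total would give a zero offset and are dropped too (with a message).
#' Gene order is preserved and offsets recomputed.
#'
#' @param m a [count_matrix()].
#' @param verbose emit messages about dropped locations.
#' @return filtered `count_matrix`; errors if no gene survives.
#' @export
filter_genes <- function(m, verbose = FALSE) {
  stopifnot(inherits(m, "count_matrix"))
  keep_loc <- m$offsets > 0
  if (!all(keep_loc)) {
    log_msg(verbose, "dropping %d location(s) with zero total count", sum(!keep_loc))
    m <- subset_counts(m, locations = keep_loc)
  }
  keep_gene <- Matrix::rowSums(m$counts) > 0
  assert_that(any(keep_gene), "no gene has a nonzero count after filtering")
  if (all(keep_gene)) return(m)
  subset_counts(m, genes = keep_gene)
}
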