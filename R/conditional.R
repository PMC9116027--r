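# Cell-type-conditional analysis: the gene panel re-run with per-location
# cell-type compositions as covariates in the count-component mean.
# Compositions are an input (estimated upstream by any deconvolution
# method, or supplied as ground truth by the simulator); this package never
# estimates them.

#' Encode a composition matrix as a covariate design
#'
#' Composition rows sum to 1, so the full matrix is collinear with the
#' model intercept: the last cell-type column is dropped as the reference.
#' Constant columns (no variation across locations) are dropped with a
#' warning. Remaining columns are centered. The choice of reference column
#' does not affect the fitted likelihood (same column space).
#'
#' @param compositions location x cell-type matrix of non-negative reals;
#'   each row must sum to 1 within `1e-6`.
#' @return centered design matrix with 0 or more columns; 0 columns means
#'   the compositions carry no usable signal (caller should fall back to
#'   the unconditional analysis).
#' @export
encode_covariates <- function(compositions) {
  w <- as.matrix(compositions)
  assert_that(all(is.finite(w)) && all(w >= 0),
              "compositions must be non-negative and finite")
  assert_that(all(abs(rowSums(w) - 1) <= 1e-6),
              "composition rows must sum to 1")
  if (ncol(w) <= 1L) {
    out <- matrix(numeric(0), nrow = nrow(w), ncol = 0L)
    return(out)
  }
  X <- w[, -ncol(w), drop = FALSE]
  const <- apply(X, 2L, function(col) max(col) - min(col) < 1e-12)
  if (any(const)) {
    warning(sprintf("dropping %d constant composition column(s)", sum(const)))
    X <- X[, !const, drop = FALSE]
  }
  scale(X, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

#' Gene panel conditional on cell-type compositions
#'
#' Identical pipeline to [run_gene_panel()] with the encoded composition
#' design entering every model's count-component mean (the zero-inflation
#' weight stays intercept-only); the per-model parameter count, and hence
#' AIC, grows by the number of covariate columns. If the encoded design has
#' zero columns the unconditional panel is returned with a warning.
#'
#' @param m a filtered [count_matrix()].
#' @param compositions location x cell-type composition matrix, rows
#'   aligned with the locations of `m` (matched by rownames when present).
#' @param ... passed to [run_gene_panel()].
#' @return panel table as from [run_gene_panel()].
#' @export
conditional_panel <- function(m, compositions, ...) {
  stopifnot(inherits(m, "count_matrix"))
  w <- as.matrix(compositions)
  assert_that(nrow(w) == ncol(m$counts),
              "compositions must have one row per location")
  if (!is.null(rownames(w))) {
    assert_that(setequal(rownames(w), m$location_ids),
                "composition rownames do not match location ids")
    w <- w[m$location_ids, , drop = FALSE]
  }
  X <- encode_covariates(w)
  if (ncol(X) == 0L) {
    warning("compositions carry no variation; running unconditional panel")
    return(run_gene_panel(m, ...))
  }
  run_gene_panel(m, covariates = X, ...)
}
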