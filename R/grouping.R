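# Location clustering (library-size normalization -> highly variable genes
# -> PCA -> shared-nearest-neighbor Louvain) and cluster-specific
# re-analysis with before/after model-preference ratios.
#
# The clustering recipe follows the standard single-cell workflow but fixes
# every default explicitly (scale factor 1e4, vst HVG with loess span 0.3
# and clipping at sqrt(n), 15 PCs, k = 20 neighbors, Jaccard SNN pruned
# below 1/15, Louvain at resolution 0.5, required seed) so results are
# reproducible without any external toolkit.

#' Library-size log-normalization
#'
#' \eqn{x_{gi} = \ln(1 + 10^4 \, y_{gi} / N_i)}: counts scaled by location
#' totals, multiplied by a fixed scale factor, then log-transformed with a
#' pseudo-count of 1.
#'
#' @param m a [count_matrix()] (all offsets must be positive).
#' @param scale_factor multiplier applied after depth division (default 1e4).
#' @return a sparse gene-by-location real matrix.
#' @export
normalize_log <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  assert_that(all(m$offsets > 0), "offsets must be positive; filter first")
  x <- m$counts %*% Matrix::Diagonal(ncol(m$counts), scale_factor / m$offsets)
  dimnames(x) <- dimnames(m$counts)
  log1p(x)
}

#' Highly variable gene selection (vst)
#'
#' Variance-stabilizing ranking: the expected standard deviation of each
#' gene's raw counts is taken from a loess fit (span 0.3) of
#' \eqn{\log_{10}} variance on \eqn{\log_{10}} mean; counts are
#' standardized against it, clipped at \eqn{\sqrt{n}}, and genes are ranked
#' by the variance of the clipped standardized values. Deterministic.
#'
#' @param m a filtered [count_matrix()].
#' @param n_top number of genes to return (default 2000); all genes if
#'   fewer are present.
#' @param loess_span span of the mean-variance trend fit.
#' @return character vector of gene ids, ranked most to least variable.
#' @export
select_hvg <- function(m, n_top = 2000L, loess_span = 0.3) {
  stopifnot(inherits(m, "count_matrix"))
  x <- m$counts
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  v <- (Matrix::rowSums(x^2) - n * mu^2) / (n - 1)
  v <- pmax(v, 0)
  std_var <- numeric(nrow(x))
  ok <- v > 0 & mu > 0
  if (sum(ok) >= 4) {
    fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = loess_span,
                        degree = 2)
    exp_sd <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(n)
    dense <- as.matrix(x[ok, , drop = FALSE])
    z <- (dense - mu[ok]) / exp_sd
    z[z > clip] <- clip
    std_var[ok] <- apply(z, 1L, stats::var)
  } else {
    std_var[ok] <- v[ok]   # too few genes for a trend; rank by raw variance
  }
  ord <- order(std_var, decreasing = TRUE)
  head(m$gene_ids[ord], min(n_top, nrow(x)))
}

#' PCA embedding of locations
#'
#' Centers and unit-scales each gene of the supplied normalized matrix
#' (zero-variance genes dropped), then extracts the top principal
#' components of the locations. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param x normalized gene-by-location matrix (e.g. [normalize_log()]
#'   restricted to HVGs).
#' @param n_pcs number of components (default 15); reduced with a warning
#'   when it exceeds the matrix rank bound.
#' @return location x n_pcs score matrix with attribute `"sdev"` (component
#'   standard deviations) and `"rotation"` (gene loadings).
#' @export
embed_pca <- function(x, n_pcs = 15L) {
  x <- as.matrix(x)
  sds <- apply(x, 1L, stats::sd)
  keep <- sds > 0
  assert_that(any(keep), "all genes have zero variance")
  xs <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) / sds[keep]
  max_pcs <- min(dim(xs)) - 1L
  if (n_pcs > max_pcs) {
    warning(sprintf("n_pcs reduced from %d to %d (rank bound)", n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  pr <- stats::prcomp(t(xs), center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  rot <- pr$rotation[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  attr(scores, "sdev") <- pr$sdev[seq_len(n_pcs)]
  attr(scores, "rotation") <- rot
  scores
}

#' Cluster locations by shared-nearest-neighbor Louvain
#'
#' Builds a k-nearest-neighbor graph on the PCA scores (Euclidean metric,
#' each location's neighbor set includes itself), converts it to a
#' shared-nearest-neighbor graph with Jaccard edge weights
#' \eqn{|A \cap B| / |A \cup B|}, prunes edges below 1/15, and runs Louvain
#' modularity optimization at the given resolution. Cluster labels are
#' integers from 0, ordered by decreasing cluster size.
#'
#' @param scores location x d score matrix from [embed_pca()].
#' @param resolution Louvain resolution parameter (default 0.5).
#' @param k_neighbors neighborhood size (default 20).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @param seed integer seed for the Louvain heuristic.
#' @return a `cluster_assignment`: list with `labels` (named 0-based integer
#'   vector, one per location) and `params`.
#' @export
cluster_locations <- function(scores, resolution = 0.5, k_neighbors = 20L,
                              prune = 1 / 15, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  assert_that(n >= k_neighbors + 1L,
              "need at least k_neighbors + 1 locations")
  d <- as.matrix(stats::dist(scores))
  # neighbor sets include self, matching common SNN practice
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k_neighbors)]))
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k_neighbors),
    j = as.vector(t(nn)), x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k_neighbors - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(memb)])
  names(labels) <- rownames(scores)
  structure(list(
    labels = labels,
    params = list(resolution = resolution, k_neighbors = k_neighbors,
                  prune = prune, seed = seed, n_clusters = length(sizes))
  ), class = "cluster_assignment")
}

#' Whole clustering pipeline on a count matrix
#'
#' Convenience wrapper: [normalize_log()] -> [select_hvg()] ->
#' [embed_pca()] -> [cluster_locations()].
#'
#' @param m a filtered [count_matrix()].
#' @param n_hvg,n_pcs,resolution,k_neighbors,seed pipeline parameters.
#' @return a `cluster_assignment` (see [cluster_locations()]); the HVG ids
#'   used are attached in `params$hvg`.
#' @export
cluster_pipeline <- function(m, n_hvg = 2000L, n_pcs = 15L, resolution = 0.5,
                             k_neighbors = 20L, seed = 1L) {
  hvg <- select_hvg(m, n_top = n_hvg)
  x <- normalize_log(m)[hvg, , drop = FALSE]
  scores <- embed_pca(x, n_pcs = n_pcs)
  ca <- cluster_locations(scores, resolution = resolution,
                          k_neighbors = k_neighbors, seed = seed)
  ca$params$n_hvg <- length(hvg)
  ca$params$n_pcs <- ncol(scores)
  ca$params$scale_factor <- 1e4
  ca
}

#' Per-cluster gene panels
#'
#' For each cluster: subset its locations, drop genes that are all-zero
#' within the cluster, recompute offsets, and run the full four-model panel
#' with the Bonferroni denominator set to the genes retained in that
#' cluster. Clusters smaller than `min_size` locations are skipped (LRTs on
#' a handful of locations are meaningless); skipped labels are recorded in
#' the `"skipped"` attribute.
#'
#' @param m a filtered [count_matrix()].
#' @param labels a `cluster_assignment` or an integer/character label per
#'   location.
#' @param min_size minimum locations for a cluster to be analyzed
#'   (default 20).
#' @param ... passed to [run_gene_panel()].
#' @return named list of per-cluster panel tables (names = cluster labels).
#' @export
cluster_specific_panel <- function(m, labels, min_size = 20L, ...) {
  stopifnot(inherits(m, "count_matrix"))
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  assert_that(length(labels) == ncol(m$counts),
              "one label per location required")
  out <- list()
  skipped <- character(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < min_size) {
      skipped <- c(skipped, as.character(cl))
      next
    }
    sub <- filter_genes(subset_counts(m, locations = idx))
    out[[as.character(cl)]] <- run_gene_panel(sub, ...)
  }
  if (length(skipped))
    message(sprintf("skipped %d cluster(s) below min_size: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  attr(out, "skipped") <- skipped
  out
}

#' @noRd
panel_category_props <- function(panel) {
  ok <- !is.na(panel$preferred_family)
  props <- c(
    vapply(FAMILIES, function(f)
      mean(panel$preferred_family[ok] == f), numeric(1)),
    vapply(names(LRT_CONTRASTS), function(ct)
      mean(panel[[paste0("sig_", ct)]][ok]), numeric(1))
  )
  names(props) <- c(paste0("pref_", FAMILIES),
                    paste0("sig_", names(LRT_CONTRASTS)))
  props
}

#' Before/after clustering preference and significance ratios
#'
#' For each cluster and each of eight categories — the four AIC model
#' preferences and the four LRT significance sets — the ratio of the
#' within-cluster proportion (after clustering) to the whole-tissue
#' proportion (before). A ratio is undefined when the before-proportion is
#' zero; such clusters are omitted from that category's median (the
#' omission is counted).
#'
#' @param whole whole-tissue panel table from [run_gene_panel()].
#' @param per_cluster list of per-cluster panels from
#'   [cluster_specific_panel()].
#' @return list with `ratios` (long data.frame: category, cluster,
#'   prop_before, prop_after, ratio) and `medians` (data.frame: category,
#'   median_ratio, n_used, n_omitted).
#' @export
before_after_ratios <- function(whole, per_cluster) {
  before <- panel_category_props(whole)
  rows <- lapply(names(per_cluster), function(cl) {
    after <- panel_category_props(per_cluster[[cl]])
    data.frame(category = names(before), cluster = cl,
               prop_before = unname(before), prop_after = unname(after),
               ratio = ifelse(before > 0, unname(after / before), NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  ratios <- do.call(rbind, rows)
  meds <- do.call(rbind, lapply(split(ratios, ratios$category), function(df) {
    ok <- !is.na(df$ratio)
    data.frame(category = df$category[1L],
               median_ratio = if (any(ok)) stats::median(df$ratio[ok]) else NA_real_,
               n_used = sum(ok), n_omitted = sum(!ok),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(meds) <- NULL
  list(ratios = ratios, medians = meds)
}
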