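# Readers and writers. Count matrices are gene-major on disk (genes =
# rows). Sparse counts travel as MatrixMarket MTX with companion gene /
# location id files; dense counts as delimited text with a header row of
# location ids and a first column of gene ids. Offsets are never read from
# disk: they are always recomputed from the matrix.

#' Read a count matrix
#'
#' `format = "mtx"`: `path` is the MatrixMarket coordinate file; gene and
#' location ids come from `genes_path` / `locations_path` (defaults:
#' sibling `genes.tsv` / `locations.tsv`, first column used). Dense
#' `csv`/`tsv`: header row = location ids, first column = gene ids
#' (gene-major orientation is the on-disk contract). A `.gz` suffix is
#' handled transparently. Non-integer, negative entries and duplicate gene
#' ids are rejected.
#'
#' @param path input file.
#' @param format `"mtx"`, `"csv"`, `"tsv"`; default guesses from the
#'   extension.
#' @param genes_path,locations_path id files for MTX input.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        genes_path = NULL, locations_path = NULL) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- switch(tolower(tools::file_ext(base)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension: ", path))
  }
  if (format == "mtx") {
    x <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file: ",
                                           conditionMessage(e), call. = FALSE))
    dir <- dirname(path)
    genes_path <- genes_path %||% file.path(dir, "genes.tsv")
    locations_path <- locations_path %||% file.path(dir, "locations.tsv")
    assert_that(file.exists(genes_path),
                sprintf("gene id file not found: %s", genes_path))
    assert_that(file.exists(locations_path),
                sprintf("location id file not found: %s", locations_path))
    gid <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
    lid <- utils::read.table(locations_path, sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
    assert_that(length(gid) == nrow(x),
                sprintf("dimension mismatch: MTX has %d rows but %d gene ids",
                        nrow(x), length(gid)))
    assert_that(length(lid) == ncol(x),
                sprintf("dimension mismatch: MTX has %d columns but %d location ids",
                        ncol(x), length(lid)))
    return(count_matrix(x, gene_ids = gid, location_ids = lid))
  }
  sep <- if (format == "csv") "," else "\t"
  if (grepl("\\.gz$", path)) {
    # fread needs R.utils for gz; base readers gzip transparently
    dt <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, check.names = FALSE)
  }
  assert_that(ncol(dt) >= 2, "malformed header: need id column plus data")
  ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  assert_that(is.numeric(mat), "non-numeric entries in count matrix")
  m <- count_matrix(mat, gene_ids = ids, location_ids = colnames(dt)[-1])
  m
}

#' Write a count matrix
#'
#' `format = "mtx"` writes `counts.mtx` + `genes.tsv` + `locations.tsv`
#' into directory `path`; dense formats write a single delimited file
#' (header = location ids, first column `gene_id`).
#'
#' @param m a [count_matrix()].
#' @param path output directory (mtx) or file (csv/tsv).
#' @param format `"mtx"`, `"csv"` or `"tsv"`.
#' @return the main file path, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx", "csv", "tsv")) {
  stopifnot(inherits(m, "count_matrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    main <- file.path(path, "counts.mtx")
    Matrix::writeMM(m$counts, main)
    writeLines(m$gene_ids, file.path(path, "genes.tsv"))
    writeLines(m$location_ids, file.path(path, "locations.tsv"))
    return(invisible(main))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene_id = m$gene_ids, as.matrix(m$counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", m$location_ids)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Read a location x cell-type composition matrix
#'
#' Delimited file with header = cell-type names and first column =
#' location ids; rows must sum to 1 within `1e-6`.
#'
#' @param path CSV/TSV file (gzip accepted).
#' @return numeric matrix with location rownames.
#' @export
read_compositions <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = TRUE)
  w <- as.matrix(dt[, -1, drop = FALSE])
  rownames(w) <- as.character(dt[[1]])
  assert_that(all(abs(rowSums(w) - 1) <= 1e-6),
              "composition rows must sum to 1")
  w
}

#' Read / write location cluster labels
#'
#' Two-column TSV `location_id <tab> cluster`; no header.
#' @param path TSV file.
#' @param location_ids if given, labels are reordered to match and must
#'   cover all ids.
#' @return integer label vector named by location id.
#' @export
read_labels <- function(path, location_ids = NULL) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  dt <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("location_id", "cluster"),
                          colClasses = c("character", "integer"))
  labels <- stats::setNames(dt$cluster, dt$location_id)
  if (!is.null(location_ids)) {
    assert_that(all(location_ids %in% names(labels)),
                "label file does not cover all locations")
    labels <- labels[location_ids]
  }
  labels
}

#' @rdname read_labels
#' @param labels named integer vector.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(location_id = names(labels), cluster = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @noRd
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @noRd
write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis end to end
#'
#' filter -> per-gene summaries -> cross-gene trends -> whole-tissue gene
#' panel -> (optional) clustering, cluster-specific panels and
#' before/after ratios -> (optional) cell-type-conditional panel. All
#' artifacts are written under `out_dir` as TSV/JSON; a `run_log.json`
#' records parameters, versions and per-stage timings, and a `status.json`
#' marks success or the failing stage (partial outputs are preserved).
#'
#' @param m a [count_matrix()] (or a path readable by [read_counts()]).
#' @param out_dir output directory, created if needed.
#' @param cluster run the clustering stage (default TRUE when locations
#'   allow it).
#' @param labels optional externally supplied cluster labels (named vector
#'   or TSV path) to bypass clustering.
#' @param compositions optional composition matrix (or CSV/TSV path) for
#'   the conditional stage.
#' @param use_offset include depth offsets in all model means
#'   (default TRUE).
#' @param alpha,bonferroni,boundary_mixture testing parameters, see
#'   [run_gene_panel()].
#' @param min_cluster_size see [cluster_specific_panel()].
#' @param seed integer seed (clustering heuristic).
#' @param verbose print stage progress.
#' @return (invisibly) list with `summaries`, `trends`, `panel`,
#'   `clusters`, `cluster_panels`, `ratios`, `conditional`.
#' @export
run_all <- function(m, out_dir, cluster = TRUE, labels = NULL,
                    compositions = NULL, use_offset = TRUE, alpha = 0.05,
                    bonferroni = TRUE, boundary_mixture = FALSE,
                    min_cluster_size = 20L, seed = 1L, verbose = TRUE) {
  if (is.character(m)) m <- read_counts(m)
  stopifnot(inherits(m, "count_matrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  current_stage <- "setup"
  stage <- function(name, expr) {
    current_stage <<- name
    log_msg(verbose, "[%s] ...", name)
    tic <- Sys.time()
    val <- force(expr)
    timings[[name]] <<- round(as.numeric(Sys.time() - tic, units = "secs"), 3)
    val
  }
  res <- list()
  status <- list(ok = FALSE, failed_stage = NA_character_)
  on.exit({
    write_json(list(
      package_version = as.character(utils::packageVersion("spotcount")),
      r_version = R.version.string, seed = seed, use_offset = use_offset,
      alpha = alpha, bonferroni = bonferroni, timings = timings,
      total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    ), file.path(out_dir, "run_log.json"))
    write_json(status, file.path(out_dir, "status.json"))
  }, add = TRUE)

  tryCatch({
    m <- stage("filter", filter_genes(m, verbose = verbose))
    res$summaries <- stage("summaries", summarize_genes(m))
    write_tsv(res$summaries, file.path(out_dir, "gene_summaries.tsv"))
    write_json(dataset_summary(res$summaries),
               file.path(out_dir, "dataset_summary.json"))

    res$trends <- stage("trends", {
      s <- res$summaries
      list(
        zero_poisson = fit_zero_trend(s$mean, s$zero_prop, "poisson"),
        zero_nb = fit_zero_trend(s$mean, s$zero_prop, "nb"),
        var_poisson = fit_variance_trend(s$mean, s$variance, "poisson"),
        var_nb = fit_variance_trend(s$mean, s$variance, "nb")
      )
    })
    write_json(lapply(res$trends, function(tf)
      list(model = tf$model, response = tf$response,
           phi_hat = tf$phi_hat, mse = tf$mse, converged = tf$converged,
           n_iter = tf$n_iter, n_excluded = tf$n_excluded)),
      file.path(out_dir, "trends.json"))
    write_tsv(data.frame(
      gene_id = res$summaries$gene_id,
      pred_zero_poisson = res$trends$zero_poisson$predictions,
      pred_zero_nb = res$trends$zero_nb$predictions,
      pred_var_poisson = res$trends$var_poisson$predictions,
      pred_var_nb = res$trends$var_nb$predictions
    ), file.path(out_dir, "trend_predictions.tsv"))

    res$panel <- stage("gene_panel",
      run_gene_panel(m, alpha = alpha, bonferroni = bonferroni,
                     boundary_mixture = boundary_mixture,
                     use_offset = use_offset, verbose = verbose))
    write_tsv(res$panel, file.path(out_dir, "gene_panel.tsv"))

    if (!is.null(labels) || isTRUE(cluster)) {
      if (!is.null(labels)) {
        if (is.character(labels) && length(labels) == 1L && file.exists(labels))
          labels <- read_labels(labels, m$location_ids)
        assert_that(length(labels) == ncol(m$counts),
                    "external labels must cover every retained location")
        if (is.null(names(labels))) names(labels) <- m$location_ids
        res$clusters <- structure(
          list(labels = labels, params = list(source = "external")),
          class = "cluster_assignment")
      } else if (ncol(m$counts) >= 21L) {
        res$clusters <- stage("clustering", cluster_pipeline(m, seed = seed))
      }
      if (!is.null(res$clusters)) {
        write_labels(res$clusters$labels, file.path(out_dir, "cluster_labels.tsv"))
        write_json(res$clusters$params[setdiff(names(res$clusters$params), "hvg")],
                   file.path(out_dir, "cluster_params.json"))
        res$cluster_panels <- stage("cluster_panels",
          cluster_specific_panel(m, res$clusters, min_size = min_cluster_size,
                                 alpha = alpha, bonferroni = bonferroni,
                                 boundary_mixture = boundary_mixture,
                                 use_offset = use_offset))
        for (cl in names(res$cluster_panels))
          write_tsv(res$cluster_panels[[cl]],
                    file.path(out_dir, sprintf("gene_panel_cluster%s.tsv", cl)))
        if (length(res$cluster_panels)) {
          res$ratios <- before_after_ratios(res$panel, res$cluster_panels)
          write_tsv(res$ratios$ratios, file.path(out_dir, "ratios.tsv"))
          write_json(stats::setNames(as.list(res$ratios$medians$median_ratio),
                                     res$ratios$medians$category),
                     file.path(out_dir, "ratio_medians.json"))
        }
      }
    }

    if (!is.null(compositions)) {
      if (is.character(compositions)) compositions <- read_compositions(compositions)
      res$conditional <- stage("conditional",
        conditional_panel(m, compositions, alpha = alpha,
                          bonferroni = bonferroni,
                          boundary_mixture = boundary_mixture,
                          use_offset = use_offset))
      write_tsv(res$conditional, file.path(out_dir, "gene_panel_conditional.tsv"))
    }
    status$ok <- TRUE
  }, error = function(e) {
    status$failed_stage <<- current_stage
    status$error <<- conditionMessage(e)
    stop(e)
  })
  invisible(res)
}
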