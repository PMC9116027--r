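# Per-gene summaries, the four likelihood ratio tests, Bonferroni
# significance, AIC model selection, and dataset-level reporting.

# the four nested contrasts, null -> alternative
LRT_CONTRASTS <- list(
  p_vs_zip   = c("poisson", "zip"),
  p_vs_nb    = c("poisson", "nb"),
  nb_vs_zinb = c("nb", "zinb"),
  zip_vs_zinb = c("zip", "zinb")
)

#' Per-gene summary statistics
#'
#' Mean, sample variance (n-1 denominator), zero proportion, and the
#' variance/mean ratio for every gene of a (filtered) count matrix.
#'
#' @param m a [count_matrix()].
#' @return data.frame with columns `gene_id`, `mean`, `variance`,
#'   `zero_prop`, `var_mean_ratio`.
#' @export
summarize_genes <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  x <- m$counts
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  # var = (sum(y^2) - n*mu^2) / (n-1), sparse-friendly
  ssq <- Matrix::rowSums(x^2)
  v <- if (n > 1) (ssq - n * mu^2) / (n - 1) else rep(NA_real_, nrow(x))
  v <- pmax(v, 0)
  nz <- Matrix::rowSums(x != 0)
  data.frame(
    gene_id = m$gene_ids,
    mean = mu,
    variance = v,
    zero_prop = (n - nz) / n,
    var_mean_ratio = v / mu,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Likelihood ratio test between two nested count-model fits
#'
#' Statistic \eqn{\max(0, 2(\ell_{alt} - \ell_{null}))} referred to an
#' upper-tail \eqn{\chi^2} with df = difference in parameter count (1 for
#' all four supported contrasts). Negative statistics — possible when the
#' null was refit by the moment fallback — are clamped to zero. The
#' overdispersion contrasts (P vs NB, ZIP vs ZINB) test a parameter on the
#' boundary of its space; the plain \eqn{\chi^2_1} reference is the default
#' (conservative), with the \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}
#' mixture available via `boundary_mixture = TRUE`.
#'
#' @param fit_null,fit_alt `model_fit` objects; the pair must be one of the
#'   four nested contrasts P-vs-ZIP, P-vs-NB, NB-vs-ZINB, ZIP-vs-ZINB.
#' @param boundary_mixture use the half-mixture null for the dispersion
#'   contrasts.
#' @return list with `stat`, `df`, `p_value`.
#' @export
lrt <- function(fit_null, fit_alt, boundary_mixture = FALSE) {
  stopifnot(inherits(fit_null, "model_fit"), inherits(fit_alt, "model_fit"))
  pair <- vapply(LRT_CONTRASTS, function(ct)
    identical(ct, c(fit_null$family, fit_alt$family)), logical(1))
  assert_that(any(pair), sprintf("not a supported nested contrast: %s vs %s",
                                 fit_null$family, fit_alt$family))
  df <- fit_alt$k - fit_null$k
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  boundary <- names(LRT_CONTRASTS)[pair] %in% c("p_vs_nb", "zip_vs_zinb")
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (boundary_mixture && boundary) p <- if (stat == 0) 1 else 0.5 * p
  list(stat = stat, df = df, p_value = p)
}

#' @noRd
pick_preferred <- function(aics) {
  # ties -> fewer parameters -> fixed order poisson, nb, zip, zinb
  ks <- vapply(FAMILIES, n_params_for, integer(1), p = 0L)
  ord <- order(aics, ks, seq_along(FAMILIES))
  FAMILIES[ord[1L]]
}

#' Fit all four models and run the four LRTs for every gene
#'
#' The per-gene engine: for each gene of a filtered matrix, fits Poisson,
#' NB (with moment fallback), ZIP and ZINB with depth offsets (and optional
#' covariates in the count-component mean), computes the four nested LRTs,
#' flags Bonferroni significance at `alpha / G` where G is the number of
#' genes in this analysis unit, and records the AIC-preferred family
#' (ties broken toward fewer parameters, then the fixed order P, NB, ZIP,
#' ZINB). Genes are processed independently; a failure in one gene is
#' recorded in its `error` column and never aborts the panel.
#'
#' @param m a filtered [count_matrix()].
#' @param covariates optional location-level design matrix (see
#'   [encode_covariates()]).
#' @param alpha family-wise significance level (default 0.05).
#' @param bonferroni divide `alpha` by the number of genes (default TRUE).
#' @param boundary_mixture see [lrt()].
#' @param use_offset if FALSE, drop the depth offset from every model's mean
#'   (all offsets set to 1); used to quantify the benefit of offsets.
#' @param verbose print progress every 200 genes.
#' @return data.frame with one row per gene: summary statistics, per-family
#'   loglik/AIC/convergence, NB fitting method, dispersion and
#'   zero-inflation estimates, LRT statistics and p-values
#'   (`stat_*`/`p_*`), significance flags (`sig_*`), `preferred_family`,
#'   and `error` (NA unless that gene failed). The Bonferroni threshold is
#'   attached as attribute `threshold`.
#' @export
run_gene_panel <- function(m, covariates = NULL, alpha = 0.05,
                           bonferroni = TRUE, boundary_mixture = FALSE,
                           use_offset = TRUE, verbose = FALSE) {
  stopifnot(inherits(m, "count_matrix"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    assert_that(nrow(covariates) == ncol(m$counts),
                "covariates rows must match locations")
  }
  G <- nrow(m$counts)
  offs <- if (use_offset) m$offsets else rep(1, ncol(m$counts))
  threshold <- if (bonferroni) alpha / G else alpha
  dense <- as.matrix(m$counts)
  rows <- vector("list", G)
  for (g in seq_len(G)) {
    rows[[g]] <- panel_one_gene(dense[g, ], offs, covariates, boundary_mixture)
    if (verbose && g %% 200 == 0) message(sprintf("  fitted %d / %d genes", g, G))
  }
  out <- data.table::rbindlist(rows)
  out <- cbind(data.frame(gene_id = m$gene_ids, stringsAsFactors = FALSE),
               as.data.frame(out))
  for (ct in names(LRT_CONTRASTS)) {
    out[[paste0("sig_", ct)]] <- !is.na(out[[paste0("p_", ct)]]) &
      out[[paste0("p_", ct)]] < threshold
  }
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  out
}

#' @noRd
panel_one_gene <- function(y, offs, covariates, boundary_mixture) {
  template <- list(
    mean = mean(y), variance = stats::var(y), zero_prop = mean(y == 0)
  )
  res <- tryCatch({
    fits <- list(
      poisson = fit_gene("poisson", y, offs, covariates),
      nb = fit_nb_with_fallback(y, offs, covariates),
      zip = fit_gene("zip", y, offs, covariates),
      zinb = fit_gene("zinb", y, offs, covariates)
    )
    tests <- lapply(LRT_CONTRASTS, function(ct)
      lrt(fits[[ct[1]]], fits[[ct[2]]], boundary_mixture))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    c(
      template,
      list(
        loglik_poisson = fits$poisson$loglik, aic_poisson = aics[["poisson"]],
        loglik_nb = fits$nb$loglik, aic_nb = aics[["nb"]],
        loglik_zip = fits$zip$loglik, aic_zip = aics[["zip"]],
        loglik_zinb = fits$zinb$loglik, aic_zinb = aics[["zinb"]],
        nb_phi = fits$nb$phi, nb_method = fits$nb$method,
        nb_converged = fits$nb$converged,
        zip_pi = fits$zip$pi,
        zinb_phi = fits$zinb$phi, zinb_pi = fits$zinb$pi,
        stat_p_vs_zip = tests$p_vs_zip$stat, p_p_vs_zip = tests$p_vs_zip$p_value,
        stat_p_vs_nb = tests$p_vs_nb$stat, p_p_vs_nb = tests$p_vs_nb$p_value,
        stat_nb_vs_zinb = tests$nb_vs_zinb$stat, p_nb_vs_zinb = tests$nb_vs_zinb$p_value,
        stat_zip_vs_zinb = tests$zip_vs_zinb$stat, p_zip_vs_zinb = tests$zip_vs_zinb$p_value,
        preferred_family = pick_preferred(aics),
        error = NA_character_
      )
    )
  }, error = function(e) {
    c(template, list(
      loglik_poisson = NA_real_, aic_poisson = NA_real_,
      loglik_nb = NA_real_, aic_nb = NA_real_,
      loglik_zip = NA_real_, aic_zip = NA_real_,
      loglik_zinb = NA_real_, aic_zinb = NA_real_,
      nb_phi = NA_real_, nb_method = NA_character_, nb_converged = NA,
      zip_pi = NA_real_, zinb_phi = NA_real_, zinb_pi = NA_real_,
      stat_p_vs_zip = NA_real_, p_p_vs_zip = NA_real_,
      stat_p_vs_nb = NA_real_, p_p_vs_nb = NA_real_,
      stat_nb_vs_zinb = NA_real_, p_nb_vs_zinb = NA_real_,
      stat_zip_vs_zinb = NA_real_, p_zip_vs_zinb = NA_real_,
      preferred_family = NA_character_,
      error = conditionMessage(e)
    ))
  })
  res
}

#' Overlap between two gene sets
#'
#' Reports \eqn{|A \cap B| / |A|} and \eqn{|A \cap B| / |B|}; a proportion
#' with an empty denominator set is undefined and returned as `NA` (not 0).
#'
#' @param set_a,set_b character vectors of gene ids from the same universe.
#' @return list with `prop_a_in_b`, `prop_b_in_a`.
#' @export
overlap_proportions <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  inter <- length(intersect(set_a, set_b))
  list(
    prop_a_in_b = if (length(set_a) == 0) NA_real_ else inter / length(set_a),
    prop_b_in_a = if (length(set_b) == 0) NA_real_ else inter / length(set_b)
  )
}

#' Dataset-level summary of overdispersion and sparsity
#'
#' From a per-gene summary table: the proportion of genes whose sample
#' variance strictly exceeds the sample mean, the median variance/mean
#' ratio, and the overall zero proportion of the matrix (equal to the
#' unweighted mean of per-gene zero proportions since every gene spans the
#' same locations).
#'
#' @param summaries output of [summarize_genes()].
#' @return list with `prop_var_gt_mean`, `median_ratio`, `overall_zero_prop`.
#' @export
dataset_summary <- function(summaries) {
  assert_that(is.data.frame(summaries) && nrow(summaries) > 0,
              "summaries must be a non-empty data.frame")
  list(
    prop_var_gt_mean = mean(summaries$variance > summaries$mean),
    median_ratio = stats::median(summaries$var_mean_ratio),
    overall_zero_prop = mean(summaries$zero_prop)
  )
}
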