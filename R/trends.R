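# Transcriptome-wide mean->variance and mean->zero-proportion trend fits
# under cross-gene Poisson and NB models, scored by MSE.
#
# The Poisson trend has no free parameter: predicted variance equals the
# mean and predicted zero proportion is exp(-mu). The NB trend has a single
# shared dispersion phi, fitted by Gauss-Newton nonlinear least squares on
# the log scale of phi with step-halving (halving prevents divergence
# without moving the fixed points). Residuals are taken on the raw response
# scale; MSE is *reported* on the zero-proportion scale for the zero trend
# and on the natural-log variance scale for the variance trend, matching the
# axes on which these relationships are conventionally displayed.

#' @noRd
gauss_newton_phi <- function(means, resp, predict_fn, dpred_dlogphi_fn,
                             phi0 = 1, tol = 1e-8, max_iter = 50L) {
  lphi <- log(phi0)
  sse <- function(lp) sum((resp - predict_fn(means, exp(lp)))^2)
  cur <- sse(lphi)
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    phi <- exp(lphi)
    r <- resp - predict_fn(means, phi)
    J <- dpred_dlogphi_fn(means, phi)
    jtj <- sum(J^2)
    if (jtj < 1e-300) { converged <- TRUE; break }
    step <- sum(J * r) / jtj
    # step halving on the sum of squares
    new_l <- lphi + step
    new_sse <- sse(new_l)
    halvings <- 0L
    while (!is.finite(new_sse) || (new_sse > cur && halvings < 30L)) {
      step <- step / 2
      new_l <- lphi + step
      new_sse <- sse(new_l)
      halvings <- halvings + 1L
    }
    if (!is.finite(new_sse) || new_sse > cur) break
    lphi <- new_l
    cur <- new_sse
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  list(phi = exp(lphi), converged = converged, n_iter = n_iter)
}

#' @noRd
new_trend_fit <- function(model, response, phi_hat, predictions, mse,
                          converged, n_iter, n_excluded = 0L) {
  structure(list(model = model, response = response, phi_hat = phi_hat,
                 predictions = predictions, mse = mse, converged = converged,
                 n_iter = n_iter, n_excluded = n_excluded),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit [%s -> %s]: %smse=%.4g (%d iter, converged=%s)\n",
              x$model, x$response,
              if (is.null(x$phi_hat)) "" else sprintf("phi=%.4g, ", x$phi_hat),
              x$mse, x$n_iter, x$converged))
  invisible(x)
}

#' Cross-gene zero-proportion trend
#'
#' Fits the relationship between per-gene zero proportion p and per-gene
#' mean \eqn{\mu} across all genes: \eqn{p = e^{-\mu}} under the cross-gene
#' Poisson model (no fitting) or the NB zero mass
#' \eqn{p = (1 + \mu/\phi)^{-\phi}} under the cross-gene NB model, with a
#' single \eqn{\phi} estimated by Gauss-Newton least squares (start
#' \eqn{\phi_0 = 1}, converged when the step falls below `1e-8` or after 50
#' iterations). MSE is on the zero-proportion scale.
#'
#' @param means per-gene means (> 0).
#' @param zero_props per-gene zero proportions in \[0, 1\].
#' @param model `"poisson"` or `"nb"`.
#' @return a `trend_fit` with `phi_hat` (NULL for poisson), per-gene
#'   `predictions`, `mse`, `converged`, `n_iter`.
#' @export
fit_zero_trend <- function(means, zero_props, model = c("nb", "poisson")) {
  model <- match.arg(model)
  assert_that(all(means > 0), "means must be positive")
  assert_that(all(zero_props >= 0 & zero_props <= 1), "zero_props must be in [0, 1]")
  if (model == "poisson") {
    pred <- exp(-means)
    return(new_trend_fit("poisson", "zero_prop", NULL, pred,
                         mean((zero_props - pred)^2), TRUE, 0L))
  }
  assert_that(length(means) >= 2, "nb trend needs at least 2 genes")
  predict_fn <- function(mu, phi) (1 + mu / phi)^(-phi)
  dpred <- function(mu, phi) {
    # d/dlog(phi) of (1+mu/phi)^(-phi)
    predict_fn(mu, phi) * (mu / (phi + mu) - log1p(mu / phi)) * phi
  }
  gn <- gauss_newton_phi(means, zero_props, predict_fn, dpred)
  pred <- predict_fn(means, gn$phi)
  new_trend_fit("nb", "zero_prop", gn$phi, pred,
                mean((zero_props - pred)^2), gn$converged, gn$n_iter)
}

#' Cross-gene variance trend
#'
#' Fits the mean-variance relationship across genes:
#' \eqn{\sigma^2 = \mu} (Poisson, no fitting) or
#' \eqn{\sigma^2 = \mu + \mu^2/\phi} (NB) with a shared \eqn{\phi} by
#' Gauss-Newton on the raw variance scale. MSE is reported on the
#' natural-log variance scale; genes with zero sample variance are excluded
#' from the MSE (their count is returned in `n_excluded`).
#'
#' @param means per-gene means (> 0).
#' @param variances per-gene sample variances (>= 0).
#' @param model `"poisson"` or `"nb"`.
#' @return a `trend_fit`.
#' @export
fit_variance_trend <- function(means, variances, model = c("nb", "poisson")) {
  model <- match.arg(model)
  assert_that(all(means > 0), "means must be positive")
  assert_that(all(variances >= 0), "variances must be non-negative")
  log_mse <- function(pred) {
    ok <- variances > 0
    list(mse = mean((log(variances[ok]) - log(pred[ok]))^2),
         n_excluded = sum(!ok))
  }
  if (model == "poisson") {
    pred <- means
    sc <- log_mse(pred)
    return(new_trend_fit("poisson", "log_variance", NULL, pred,
                         sc$mse, TRUE, 0L, sc$n_excluded))
  }
  assert_that(length(means) >= 2, "nb trend needs at least 2 genes")
  predict_fn <- function(mu, phi) mu + mu^2 / phi
  dpred <- function(mu, phi) -mu^2 / phi  # chain through log(phi)
  gn <- gauss_newton_phi(means, variances, predict_fn, dpred)
  pred <- predict_fn(means, gn$phi)
  sc <- log_mse(pred)
  new_trend_fit("nb", "log_variance", gn$phi, pred, sc$mse,
                gn$converged, gn$n_iter, sc$n_excluded)
}
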