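# Likelihoods, MLE fits, GEE fallback, moment formulas.

test_that("log_likelihood matches hand computations and degenerate limits", {
  # poisson, mu = 1 at both locations, y = [1,1]: sum(y log mu - mu - log y!) = -2
  expect_equal(log_likelihood("poisson", list(beta0 = 0), c(1, 1), c(1, 1)), -2)
  # zip with pi = 0 degenerates to poisson on any input
  y <- c(0, 3, 1, 0, 2)
  offs <- c(1, 2, 1, 3, 1)
  expect_equal(
    log_likelihood("zip", list(beta0 = -0.4, pi = 0), y, offs),
    log_likelihood("poisson", list(beta0 = -0.4), y, offs)
  )
  # zinb at huge dispersion approaches zip with the same (beta0, pi)
  expect_lt(abs(
    log_likelihood("zinb", list(beta0 = 0.1, phi = 1e6, pi = 0.2), c(0, 1, 2), rep(1, 3)) -
      log_likelihood("zip", list(beta0 = 0.1, pi = 0.2), c(0, 1, 2), rep(1, 3))
  ), 1e-3)
  # input validation
  expect_error(log_likelihood("poisson", list(beta0 = 0), c(-1, 1), c(1, 1)),
               "non-negative integers")
  expect_error(log_likelihood("poisson", list(beta0 = 0), c(1.5, 1), c(1, 1)),
               "non-negative integers")
  expect_error(log_likelihood("poisson", list(beta0 = 0), c(1, 1), c(0, 1)),
               "positive")
})

test_that("Poisson MLE is the closed form sum(y)/sum(N)", {
  f <- fit_gene("poisson", c(1, 1), c(1, 1))
  expect_equal(f$beta0, 0)
  expect_equal(f$loglik, -2)
  expect_equal(f$aic, 6)
  f2 <- fit_gene("poisson", c(2, 4), c(1, 1))
  expect_equal(exp(f2$beta0), 3)
  expect_equal(f2$loglik, 6 * log(3) - 6 - log(48))
  expect_equal(f2$aic, 2 - 2 * (6 * log(3) - 6 - log(48)))
  # aic invariant holds on every family fit
  set.seed(4)
  y <- rpois(100, 2)
  for (fam in c("poisson", "nb", "zip", "zinb")) {
    ft <- fit_gene(fam, y, rep(1, 100))
    expect_equal(ft$aic, 2 * ft$k - 2 * ft$loglik)
  }
  expect_error(fit_gene("poisson", c(0, 0), c(1, 1)), "all-zero")
})

test_that("NB MLE agrees with MASS::glm.nb and recovers dispersion", {
  set.seed(42)
  n <- 800
  N <- round(runif(n, 50, 150))
  y <- rnbinom(n, size = 2, mu = 5 / 100 * N)
  f <- fit_gene("nb", y, N)
  o <- MASS::glm.nb(y ~ 1 + offset(log(N)))
  expect_equal(f$loglik, as.numeric(stats::logLik(o)), tolerance = 1e-6)
  expect_equal(f$phi, o$theta, tolerance = 1e-4)
  expect_true(f$converged)
  # recovery at n = 2000 within 15%
  set.seed(9)
  y2 <- rnbinom(2000, size = 2, mu = 5)
  f2 <- fit_gene("nb", y2, rep(1, 2000))
  expect_lt(abs(f2$phi - 2) / 2, 0.15)
})

test_that("ZI fits recover zero-inflation weight and initialize sanely", {
  set.seed(7)
  n <- 1500
  y <- as.integer(rpois(n, 4) * (runif(n) >= 0.4))
  f <- fit_gene("zip", y, rep(1, n))
  expect_true(f$converged)
  expect_lt(abs(f$pi - 0.4), 0.05)
  expect_lt(abs(exp(f$beta0) - 4), 0.3)
  set.seed(8)
  y2 <- as.integer(rnbinom(n, size = 1, mu = 5) * (runif(n) >= 0.3))
  f2 <- fit_gene("zinb", y2, rep(1, n))
  expect_lt(abs(f2$pi - 0.3), 0.07)
  expect_lt(abs(f2$phi - 1) / 1, 0.35)
})

test_that("likelihood nesting holds across families up to tolerance", {
  set.seed(11)
  worlds <- list(
    rpois(300, 2),
    rnbinom(300, size = 0.8, mu = 3),
    as.integer(rpois(300, 5) * (runif(300) >= 0.5)),
    as.integer(rnbinom(300, size = 1, mu = 4) * (runif(300) >= 0.3))
  )
  for (y in worlds) {
    offs <- rep(1, length(y))
    ll <- vapply(c("poisson", "nb", "zip", "zinb"),
                 function(fm) fit_gene(fm, y, offs)$loglik, numeric(1))
    expect_gte(ll[["nb"]], ll[["poisson"]] - 1e-4)
    expect_gte(ll[["zip"]], ll[["poisson"]] - 1e-4)
    expect_gte(ll[["zinb"]], ll[["nb"]] - 1e-4)
    expect_gte(ll[["zinb"]], ll[["zip"]] - 1e-4)
  }
})

test_that("offset equivariance: doubling offsets and halving the rate is a no-op", {
  set.seed(13)
  y <- rpois(200, 3)
  N <- runif(200, 50, 150)
  for (fam in c("poisson", "nb")) {
    params <- list(beta0 = -3.5, phi = 2)
    l1 <- log_likelihood(fam, params, y, N)
    params2 <- list(beta0 = -3.5 - log(2), phi = 2)
    l2 <- log_likelihood(fam, params2, y, 2 * N)
    expect_equal(l1, l2, tolerance = 1e-10)
  }
})

test_that("GEE plug-in solves the moment identity and caps at the boundary", {
  # hand solve: mu = 1, residual variance 2/(2-1) = 2, 2 = 1 + 1/phi -> phi = 1
  g <- fit_nb_gee(c(0, 2), c(1, 1))
  expect_equal(exp(g$beta0), 1)
  expect_equal(g$phi, 1)
  expect_identical(g$method, "gee_plugin")
  expect_equal(g$aic, 2 * g$k - 2 * g$loglik)
  # constant counts: residual variance 0 <= mean -> capped and flagged
  g2 <- fit_nb_gee(c(1, 1), c(1, 1))
  expect_true(g2$phi_capped)
  expect_equal(g2$phi, 1e8)
  expect_false(g2$converged)
  # recovery: phi within 20% on NB data at n = 5000
  set.seed(21)
  y <- rnbinom(5000, size = 1, mu = 2)
  g3 <- fit_nb_gee(y, rep(1, 5000))
  expect_lt(abs(g3$phi - 1), 0.2)
  # intercept-only mean equals the Poisson MLE exactly
  set.seed(22)
  y4 <- rpois(300, 2)
  N4 <- runif(300, 10, 100)
  expect_equal(fit_nb_gee(y4, N4)$beta0, fit_gene("poisson", y4, N4)$beta0)
})

test_that("NB fallback picks the smaller-AIC candidate and keeps MLE when healthy", {
  # underdispersed constant counts: MLE diverges, fallback engaged
  y <- rep(3L, 50)
  mle <- fit_gene("nb", y, rep(1, 50))
  expect_false(mle$converged)
  fb <- fit_nb_with_fallback(y, rep(1, 50))
  expect_lte(fb$aic, mle$aic)
  # healthy NB data: MLE path chosen
  set.seed(31)
  y2 <- rnbinom(1000, size = 0.5, mu = 5)
  f2 <- fit_nb_with_fallback(y2, rep(1, 1000))
  expect_identical(f2$method, "mle")
  expect_true(f2$converged)
})

test_that("model_moments implements the four closed forms", {
  nb <- family_moments("nb", mu = 2, phi = 1)
  expect_equal(nb$variance, 6)
  expect_equal(nb$zero_prop, 1 / 3)
  po <- family_moments("poisson", mu = 1)
  expect_equal(po$zero_prop, exp(-1))
  zp <- family_moments("zip", mu = 1, pi = 0.5)
  expect_equal(zp$mean, 0.5)
  expect_equal(zp$zero_prop, 0.5 + 0.5 * exp(-1))
  zn <- family_moments("zinb", mu = 2, phi = 1, pi = 0.25)
  expect_equal(zn$mean, 1.5)
  expect_equal(zn$variance, 0.75 * 6 + 0.25 * 0.75 * 4)
  expect_equal(zn$zero_prop, 0.25 + 0.75 / 3)
  # via a fitted object and an offset
  f <- fit_gene("poisson", c(2, 4), c(1, 1))
  mm <- model_moments(f, offset = 1)
  expect_equal(mm$mean, 3)
  expect_equal(mm$variance, 3)
  # NB/ZIP/ZINB variance >= mean at positive mean
  for (args in list(list("nb", 2, 5, NULL), list("zip", 2, NULL, 0.3),
                    list("zinb", 2, 5, 0.3))) {
    mo <- family_moments(args[[1]], mu = args[[2]], phi = args[[3]], pi = args[[4]])
    expect_gte(mo$variance, mo$mean)
  }
})
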