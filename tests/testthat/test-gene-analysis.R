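# Filtering, summaries, LRT machinery, the panel, overlaps, dataset summary.

test_that("filter_genes drops exactly the all-zero genes, preserving order", {
  Y <- rbind(g1 = c(1, 0, 2), g2 = c(0, 0, 0), g3 = c(0, 1, 0),
             g4 = c(0, 0, 0), g5 = c(3, 3, 3))
  m <- count_matrix(Y)
  f <- filter_genes(m)
  expect_identical(f$gene_ids, c("g1", "g3", "g5"))
  expect_identical(f$offsets, Matrix::colSums(f$counts))
  # identity on a matrix with no all-zero gene
  m2 <- count_matrix(rbind(a = c(1, 2), b = c(3, 4)))
  expect_identical(as.matrix(filter_genes(m2)$counts), as.matrix(m2$counts))
  # zero-total locations dropped
  Y3 <- rbind(a = c(1, 0), b = c(2, 0))
  f3 <- filter_genes(count_matrix(Y3))
  expect_equal(ncol(f3$counts), 1)
  expect_error(filter_genes(count_matrix(matrix(0, 2, 2))), "no gene")
})

test_that("summarize_genes computes n-1 variance and exact zero proportions", {
  m <- count_matrix(rbind(g1 = c(0, 0, 2), g2 = c(3, 3, 3)))
  s <- summarize_genes(m)
  expect_equal(s$mean, c(2 / 3, 3))
  expect_equal(s$variance, c(4 / 3, 0))
  expect_equal(s$zero_prop, c(2 / 3, 0))
  s2 <- summarize_genes(count_matrix(rbind(g = c(0, 1))))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$variance, 0.5)
  expect_equal(s2$var_mean_ratio, 1)
})

test_that("lrt clamps, references chi-square 1, rejects non-nested pairs", {
  set.seed(2)
  y <- rpois(200, 2)
  offs <- rep(1, 200)
  fp <- fit_gene("poisson", y, offs)
  fn <- fit_gene("nb", y, offs)
  fz <- fit_gene("zip", y, offs)
  r <- lrt(fp, fn)
  expect_gte(r$stat, 0)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, stats::pchisq(r$stat, 1, lower.tail = FALSE))
  # chi2_1 95th percentile maps to p ~ 0.05
  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  # equal logliks -> stat 0, p 1 (clamp covers optimizer noise)
  fp2 <- fp; fp2$loglik <- fn$loglik + 0.5  # simulated fallback artifact
  r2 <- lrt(fp2, fn)
  expect_equal(r2$stat, 0)
  expect_equal(r2$p_value, 1)
  expect_error(lrt(fz, fn), "nested")
  # boundary mixture halves the p-value for the dispersion contrasts
  r3 <- lrt(fp, fn, boundary_mixture = TRUE)
  if (r3$stat > 0) expect_equal(r3$p_value, r$p_value / 2)
})

test_that("run_gene_panel: schema, determinism, Bonferroni, tie-breaks", {
  sim <- poisson_world(G = 12, n = 150, seed = 41)
  m <- filter_genes(sim$matrix)
  p1 <- run_gene_panel(m)
  p2 <- run_gene_panel(m)
  expect_identical(p1, p2)  # deterministic, seed-free
  expect_equal(nrow(p1), nrow(m$counts))
  expect_equal(attr(p1, "threshold"), 0.05 / nrow(m$counts))
  needed <- c("gene_id", "aic_poisson", "aic_nb", "aic_zip", "aic_zinb",
              "p_p_vs_zip", "p_p_vs_nb", "p_nb_vs_zinb", "p_zip_vs_zinb",
              "sig_p_vs_zip", "preferred_family", "nb_method", "error")
  expect_true(all(needed %in% names(p1)))
  expect_true(all(is.na(p1$error)))
  # preferred family attains the minimal AIC
  aics <- as.matrix(p1[, c("aic_poisson", "aic_nb", "aic_zip", "aic_zinb")])
  min_aic <- apply(aics, 1, min)
  got <- aics[cbind(seq_len(nrow(p1)),
                    match(p1$preferred_family, c("poisson", "nb", "zip", "zinb")))]
  expect_equal(got, min_aic, ignore_attr = TRUE)
  # p-values live in [0,1], stats are non-negative
  for (ct in c("p_vs_zip", "p_vs_nb", "nb_vs_zinb", "zip_vs_zinb")) {
    expect_true(all(p1[[paste0("p_", ct)]] >= 0 & p1[[paste0("p_", ct)]] <= 1))
    expect_true(all(p1[[paste0("stat_", ct)]] >= 0))
  }
})

test_that("panel power: NB and ZIP worlds are detected, Poisson world is not", {
  # scaled-down version of the power/selection criteria (G = 40, n = 300)
  G <- 40; n <- 300
  nb_sim <- simulate_dataset(sim_config(
    n_genes = G, n_locations = n, family_weights = c(nb = 1),
    mean_range = c(5e-3, 5e-3), phi_range = c(0.5, 0.5),
    depth_model = c(log(1000), 0.3), seed = 51
  ))
  pnb <- run_gene_panel(filter_genes(nb_sim$matrix))
  expect_gte(mean(pnb$sig_p_vs_nb), 0.95)
  expect_gte(mean(pnb$preferred_family %in% c("nb", "zinb")), 0.9)
  zip_sim <- simulate_dataset(sim_config(
    n_genes = G, n_locations = n, family_weights = c(zip = 1),
    mean_range = c(5e-3, 5e-3), pi_range = c(0.5, 0.5),
    depth_model = c(log(1000), 0.3), seed = 52
  ))
  pzip <- run_gene_panel(filter_genes(zip_sim$matrix))
  expect_gte(mean(pzip$sig_p_vs_zip), 0.95)
  po_sim <- poisson_world(G = G, n = n, seed = 53)
  ppo <- run_gene_panel(filter_genes(po_sim$matrix))
  expect_equal(sum(ppo$sig_p_vs_nb), 0)
  expect_equal(sum(ppo$sig_p_vs_zip), 0)
  expect_gte(mean(ppo$preferred_family == "poisson"), 0.7)
})

test_that("monotone power in 1/phi for the P-vs-NB test", {
  G <- 30; n <- 250
  rates <- numeric(0)
  for (inv_phi in c(0, 0.2, 1, 5)) {
    sim <- if (inv_phi == 0) {
      poisson_world(G = G, n = n, seed = 61, mean_range = c(2e-3, 2e-3))
    } else {
      simulate_dataset(sim_config(
        n_genes = G, n_locations = n, family_weights = c(nb = 1),
        mean_range = c(2e-3, 2e-3), phi_range = rep(1 / inv_phi, 2),
        depth_model = c(log(1000), 0.5), seed = 61
      ))
    }
    p <- run_gene_panel(filter_genes(sim$matrix))
    rates <- c(rates, mean(p$p_p_vs_nb < 0.05))
  }
  expect_true(all(diff(rates) >= 0))
})

test_that("overlap proportions and dataset summary follow their rules", {
  ov <- overlap_proportions(c("g1", "g2"), c("g2", "g3"))
  expect_equal(ov$prop_a_in_b, 0.5)
  expect_equal(ov$prop_b_in_a, 0.5)
  expect_equal(overlap_proportions(c("a"), c("a", "b"))$prop_a_in_b, 1)
  expect_true(is.na(overlap_proportions(character(0), c("a"))$prop_a_in_b))
  s <- data.frame(gene_id = c("a", "b", "c"), mean = c(1, 1, 1),
                  variance = c(1, 2, 3), zero_prop = c(0, 0.5, 0.2),
                  var_mean_ratio = c(1, 2, 3))
  d <- dataset_summary(s)
  expect_equal(d$prop_var_gt_mean, 2 / 3)   # strict inequality
  expect_equal(d$median_ratio, 2)
  expect_equal(d$overall_zero_prop, mean(c(0, 0.5, 0.2)))
  # all-Poisson simulation (equal depths, so no marginal depth-induced
  # overdispersion): median ratio near 1
  sim <- poisson_world(G = 60, n = 2000, seed = 71, sdlog = 0)
  ds <- dataset_summary(summarize_genes(filter_genes(sim$matrix)))
  expect_gt(ds$median_ratio, 0.95)
  expect_lt(ds$median_ratio, 1.05)
})
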