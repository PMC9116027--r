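# Normalization, HVG ranking, PCA, SNN-Louvain clustering, cluster panels,
# before/after ratios.

test_that("normalize_log matches the closed form and is monotone", {
  m <- count_matrix(rbind(g1 = c(0, 1, 100), g2 = c(100, 99, 0)))
  x <- normalize_log(m)
  N <- m$offsets
  expect_equal(x[1, 1], 0)
  expect_equal(x[1, 2], unname(log1p(1e4 * 1 / N[2])))
  expect_equal(x[2, 1], unname(log1p(1e4 * 100 / N[1])))
  # y = N_i gives ln(1 + 1e4)
  m2 <- count_matrix(rbind(g = 5), location_ids = "l1")
  expect_equal(normalize_log(m2)[1, 1], log1p(1e4))
  # y=1, N=100
  m3 <- count_matrix(rbind(a = 1, b = 99))
  expect_equal(normalize_log(m3)[1, 1], log(101))
  # monotone in y at fixed N, invariant to gene order
  expect_true(all(diff(x[1, order(m$counts[1, ] / N)]) >= 0))
  xr <- normalize_log(subset_counts(m, genes = c(2, 1)))
  expect_equal(as.matrix(xr)[2:1, ], as.matrix(x), ignore_attr = TRUE)
})

test_that("select_hvg returns everything when short and finds spiked genes", {
  sim <- poisson_world(G = 50, n = 300, seed = 91)
  m <- filter_genes(sim$matrix)
  expect_length(select_hvg(m, n_top = 2000), nrow(m$counts))
  expect_identical(select_hvg(m), select_hvg(m))  # deterministic
  # spike one gene with ~50x inflated variance at matched mean, against a
  # background of Poisson genes with varied means (the loess trend needs
  # spread in the mean)
  set.seed(92)
  lam <- exp(runif(100, log(1), log(20)))
  Y <- matrix(rpois(100 * 300, rep(lam, 300)), 100)
  Y[37, ] <- as.integer(rnbinom(300, size = 0.1, mu = 5))
  hv <- select_hvg(count_matrix(Y), n_top = 10)
  expect_identical(hv[1], "gene37")
})

test_that("embed_pca: orthonormal loadings, ordered variance, rank-1 capture", {
  set.seed(93)
  base <- matrix(rnorm(30 * 200), 30)
  scores <- embed_pca(base, n_pcs = 5)
  rot <- attr(scores, "rotation")
  expect_equal(crossprod(rot), diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  sd <- attr(scores, "sdev")
  expect_true(all(diff(sd) <= 1e-12))
  # rank-1 structure: PC1 dominates
  u <- runif(20, 1, 2) * sample(c(-1, 1), 20, replace = TRUE); v <- rnorm(300)
  x1 <- outer(u, v) + matrix(rnorm(20 * 300, sd = 1e-3), 20)
  s1 <- embed_pca(x1, n_pcs = 3)
  sd1 <- attr(s1, "sdev")
  expect_gt(sd1[1]^2 / sum(sd1^2), 0.999)
  expect_warning(embed_pca(matrix(rnorm(40), 4), n_pcs = 10), "reduced")
})

test_that("cluster_locations separates blobs and is seed-stable", {
  set.seed(94)
  n_per <- 200
  blob <- function(center) sweep(matrix(rnorm(n_per * 15), n_per), 2, center, `+`)
  scores <- rbind(blob(rep(0, 15)), blob(c(10, rep(0, 14))))
  truth <- rep(0:1, each = n_per)
  ca <- cluster_locations(scores, seed = 7)
  expect_length(ca$labels, 2 * n_per)
  expect_identical(sort(unique(ca$labels)), 0:1)
  expect_equal(adjusted_rand(ca$labels, truth), 1)
  expect_identical(cluster_locations(scores, seed = 7)$labels, ca$labels)
  # single isotropic blob: modal outcome over seeds is one cluster
  single <- blob(rep(0, 15))
  k_out <- vapply(1:10, function(s)
    length(unique(cluster_locations(single, seed = s)$labels)), integer(1))
  expect_identical(as.integer(names(sort(table(k_out), decreasing = TRUE))[1]), 1L)
  expect_error(cluster_locations(matrix(rnorm(30), 10), k_neighbors = 20),
               "at least")
})

test_that("full clustering pipeline recovers simulated clusters", {
  set.seed(95)
  G <- 80
  base <- exp(runif(G, log(2e-4), log(2e-3)))
  mult <- t(replicate(G, sample(c(0.2, 1, 5))))
  rates <- t(mult * base)          # K=3 rows after transpose
  sim <- simulate_cluster_mixture(3, rates, cluster_sizes = c(80, 80, 80),
                                  seed = 96)
  m <- filter_genes(sim$matrix)
  ca <- cluster_pipeline(m, k_neighbors = 15, seed = 97)
  expect_gte(adjusted_rand(ca$labels, sim$labels), 0.9)
})

test_that("cluster panels: K=1 equals the whole-tissue panel; small clusters skip", {
  sim <- poisson_world(G = 15, n = 120, seed = 98)
  m <- filter_genes(sim$matrix)
  whole <- run_gene_panel(m)
  per <- cluster_specific_panel(m, rep(0L, 120))
  expect_length(per, 1)
  expect_equal(per[["0"]], whole, ignore_attr = TRUE)
  # a 10-location cluster is below the default minimum and is skipped
  labels <- c(rep(0L, 110), rep(1L, 10))
  expect_message(per2 <- cluster_specific_panel(m, labels), "skipped")
  expect_identical(names(per2), "0")
  expect_identical(attr(per2, "skipped"), "1")
  # genes all-zero within a cluster are absent from that cluster's table
  Y <- rbind(g1 = c(2, 3, rep(1, 58)), g2 = c(rep(0, 30), rep(2, 30)))
  mm <- count_matrix(Y)
  p3 <- cluster_specific_panel(mm, rep(0:1, each = 30), min_size = 10)
  expect_false("g2" %in% p3[["0"]]$gene_id)
  expect_true(all(c("g1", "g2") %in% p3[["1"]]$gene_id))
})

test_that("before_after_ratios applies the undefined-ratio rule", {
  sim <- poisson_world(G = 20, n = 100, seed = 99)
  m <- filter_genes(sim$matrix)
  whole <- run_gene_panel(m)
  # identical before/after: every defined ratio is 1
  rr <- before_after_ratios(whole, list(`0` = whole))
  defined <- !is.na(rr$ratios$ratio)
  expect_true(all(rr$ratios$ratio[defined] == 1))
  # a category with prop_before = 0 is omitted from the median
  zero_before <- rr$ratios$prop_before == 0
  expect_true(all(is.na(rr$ratios$ratio[zero_before])))
  med <- rr$medians
  expect_true(all(med$n_omitted[med$category %in%
    rr$ratios$category[zero_before]] >= 1))
})
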