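# Shared fixtures, all generated in code under fixed seeds.

# small Poisson-only matrix with heterogeneous depths
poisson_world <- function(G = 50, n = 200, seed = 1,
                          mean_range = c(2e-4, 5e-3), sdlog = 0.5) {
  simulate_dataset(sim_config(
    n_genes = G, n_locations = n, family_weights = c(poisson = 1),
    mean_range = mean_range, depth_model = c(log(1000), sdlog), seed = seed
  ))
}

# |a - b| within k Monte-Carlo standard errors, with SEs estimated from the
# draws themselves
expect_within_mc <- function(emp, analytic, se, k = 4, label = "") {
  expect_lt(abs(emp - analytic), k * se + 1e-12, label = label)
}

# moment comparison of one simulated gene vector against analytic moments
check_moments <- function(y, mom, k = 4) {
  n <- length(y)
  se_mean <- stats::sd(y) / sqrt(n)
  m4 <- mean((y - mean(y))^4)
  se_var <- sqrt(max(m4 - stats::var(y)^2, 0) / n)
  p0 <- mean(y == 0)
  se_p0 <- sqrt(p0 * (1 - p0) / n)
  expect_within_mc(mean(y), mom$mean, se_mean, k, "mean")
  expect_within_mc(stats::var(y), mom$variance, se_var, k, "variance")
  expect_within_mc(p0, mom$zero_prop, se_p0, k, "zero_prop")
}

adjusted_rand <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}
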