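# Seeded generators for count matrices with known ground truth. These are
# first-class, tested code: every downstream stage (per-gene fitting, LRTs,
# trends, clustering, conditional analysis) is validated against data whose
# generating family and parameters are known exactly.

#' Configuration for the basic per-gene simulator
#'
#' Describes a "stated world": a mixture of genes drawn from the four count
#' families with log-link means and per-location depth offsets. Per-gene
#' baseline rates and dispersions are drawn log-uniformly over their ranges
#' (gene means in real tissues span orders of magnitude); zero-inflation
#' weights uniformly. Location totals \eqn{N_i} are log-normal, emulating the
#' strong depth heterogeneity of sequencing-based spatial platforms.
#'
#' @param n_genes,n_locations dimensions of the simulated matrix.
#' @param family_weights named probabilities over
#'   `c("poisson","nb","zip","zinb")`; must sum to 1.
#' @param mean_range positive interval for the per-gene baseline rate
#'   \eqn{\lambda_g} (counts per unit offset). The default, together with the
#'   default depth model, yields typical per-location gene means of about
#'   0.05–5 counts.
#' @param phi_range positive interval for NB/ZINB dispersion \eqn{\phi}
#'   (smaller = more overdispersed).
#' @param pi_range interval in \[0, 1) for the zero-inflation weight
#'   \eqn{\pi}.
#' @param depth_model `c(meanlog, sdlog)` of the log-normal for location
#'   totals \eqn{N_i}.
#' @param seed integer; fully determines the output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 100L,
                       n_locations = 500L,
                       family_weights = c(poisson = 0.25, nb = 0.25,
                                          zip = 0.25, zinb = 0.25),
                       mean_range = c(5e-5, 5e-3),
                       phi_range = c(0.1, 10),
                       pi_range = c(0.1, 0.5),
                       depth_model = c(meanlog = log(1000), sdlog = 0.5),
                       seed = 1L) {
  assert_that(n_genes >= 1 && n_locations >= 1, "dimensions must be positive")
  assert_that(all(names(family_weights) %in% FAMILIES) &&
                !anyDuplicated(names(family_weights)),
              "family_weights must be named by poisson/nb/zip/zinb")
  w <- stats::setNames(numeric(4), FAMILIES)
  w[names(family_weights)] <- family_weights
  assert_that(all(w >= 0) && abs(sum(w) - 1) < 1e-8, "family_weights must sum to 1")
  check_range <- function(r, name, lo_ok) {
    assert_that(is.numeric(r) && length(r) == 2L && r[1] <= r[2] && r[1] >= lo_ok,
                sprintf("invalid %s", name))
  }
  check_range(mean_range, "mean_range", .Machine$double.xmin)
  check_range(phi_range, "phi_range", .Machine$double.xmin)
  assert_that(length(pi_range) == 2L && pi_range[1] >= 0 && pi_range[2] < 1 &&
                pi_range[1] <= pi_range[2], "pi_range must lie in [0, 1)")
  assert_that(length(depth_model) == 2L && depth_model[2] >= 0,
              "depth_model must be c(meanlog, sdlog)")
  structure(list(
    n_genes = as.integer(n_genes), n_locations = as.integer(n_locations),
    family_weights = w, mean_range = mean_range, phi_range = phi_range,
    pi_range = pi_range, depth_model = unname(depth_model),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @noRd
runif_log <- function(n, range) {
  if (range[1] == range[2]) return(rep(range[1], n))
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' @noRd
draw_depths <- function(n, depth_model) {
  stats::rlnorm(n, meanlog = depth_model[1], sdlog = depth_model[2])
}

#' Simulate a gene-by-location count matrix from the four count families
#'
#' For each gene a family is drawn from `family_weights` and counts at
#' location i are drawn with count-component mean \eqn{\lambda_g N_i};
#' zero-inflated families additionally zero each entry independently with
#' probability \eqn{\pi_g} (Bernoulli thinning of the count component).
#' Identical seeds give bit-identical matrices.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a [count_matrix()]) and `truth`, a data.frame
#'   with one row per gene: `gene_id`, `family`, `lambda`, `phi` (NA unless
#'   NB/ZINB), `pi` (NA unless ZIP/ZINB); plus attribute-free copies of the
#'   drawn `depths` and the `seed`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes; n <- config$n_locations
    N <- draw_depths(n, config$depth_model)
    fam <- sample(FAMILIES, G, replace = TRUE, prob = config$family_weights)
    lambda <- runif_log(G, config$mean_range)
    phi <- ifelse(fam %in% c("nb", "zinb"),
                  runif_log(G, config$phi_range), NA_real_)
    pi <- ifelse(fam %in% c("zip", "zinb"),
                 stats::runif(G, config$pi_range[1], config$pi_range[2]), NA_real_)
    counts <- matrix(0L, G, n)
    for (g in seq_len(G)) {
      counts[g, ] <- draw_family_counts(fam[g], lambda[g] * N,
                                        phi = phi[g], pi = pi[g])
    }
    truth <- data.frame(
      gene_id = paste0("gene", seq_len(G)), family = fam,
      lambda = lambda, phi = phi, pi = pi, stringsAsFactors = FALSE
    )
    list(
      matrix = count_matrix(counts,
                            gene_ids = truth$gene_id,
                            location_ids = paste0("loc", seq_len(n))),
      truth = truth, depths = N, seed = config$seed
    )
  })
}

#' @noRd
draw_family_counts <- function(family, mu, phi = NA, pi = NA) {
  n <- length(mu)
  y <- switch(family,
    poisson = , zip = stats::rpois(n, mu),
    nb = , zinb = stats::rnbinom(n, size = phi, mu = mu)
  )
  if (family %in% c("zip", "zinb") && pi > 0) {
    y <- y * (stats::runif(n) >= pi)
  }
  as.integer(y)
}

#' Simulate cluster-structured counts: Poisson within, overdispersed across
#'
#' Locations are partitioned into K clusters; within a cluster, gene g is
#' Poisson with mean \eqn{\theta_{kg} N_i}. Marginally across clusters the
#' counts follow a finite Poisson mixture and are overdispersed whenever the
#' per-cluster rates differ — the mechanism by which expression heterogeneity
#' across tissue locations masquerades as overdispersion or zero inflation
#' in whole-tissue analyses.
#'
#' @param K number of clusters (>= 1).
#' @param per_cluster_rates K x G positive matrix of per-cluster baseline
#'   rates per unit offset.
#' @param cluster_sizes integer vector of K positive cluster sizes.
#' @param depth_model `c(meanlog, sdlog)` for location totals.
#' @param seed integer seed.
#' @return list with `matrix`, `labels` (0-based cluster label per location),
#'   `truth` (list with `rates`, `labels`, `depths`, `seed`).
#' @export
simulate_cluster_mixture <- function(K, per_cluster_rates, cluster_sizes,
                                     depth_model = c(log(1000), 0.5),
                                     seed = 1L) {
  assert_that(K >= 1, "K must be >= 1")
  per_cluster_rates <- as.matrix(per_cluster_rates)
  assert_that(nrow(per_cluster_rates) == K, "per_cluster_rates must have K rows")
  assert_that(all(per_cluster_rates > 0), "rates must be positive")
  assert_that(length(cluster_sizes) == K && all(cluster_sizes >= 1),
              "cluster_sizes must be K positive integers")
  G <- ncol(per_cluster_rates)
  n <- sum(cluster_sizes)
  labels <- rep(seq_len(K) - 1L, times = cluster_sizes)
  with_seed(seed, {
    N <- draw_depths(n, depth_model)
    counts <- matrix(0L, G, n)
    for (g in seq_len(G)) {
      mu <- per_cluster_rates[labels + 1L, g] * N
      counts[g, ] <- as.integer(stats::rpois(n, mu))
    }
    m <- count_matrix(counts, gene_ids = paste0("gene", seq_len(G)),
                      location_ids = paste0("loc", seq_len(n)))
    list(matrix = m, labels = labels,
         truth = list(rates = per_cluster_rates, labels = labels,
                      depths = N, seed = seed))
  })
}

#' Simulate cell-type-mixture counts with Dirichlet compositions
#'
#' Each location i receives a composition \eqn{w_i \sim Dirichlet(\alpha)}
#' over K cell types; gene g at location i is Poisson with mean
#' \eqn{N_i \sum_k w_{ik} \theta_{gk}}. With distinct type rates and
#' variable compositions the marginal counts are overdispersed even though
#' every location is conditionally Poisson — the generative twin of the
#' cell-type-conditional analysis.
#'
#' @param K_types number of cell types (>= 1).
#' @param type_rates K x G positive matrix of per-type baseline rates per
#'   unit offset.
#' @param dirichlet_alpha K positive Dirichlet concentration parameters.
#' @param n_locations number of locations.
#' @param depth_model `c(meanlog, sdlog)` for location totals.
#' @param seed integer seed.
#' @return list with `matrix`, `compositions` (location x K matrix, rows the
#'   true \eqn{w_i}, summing to 1), `truth` (list with `type_rates`, `alpha`,
#'   `depths`, `seed`).
#' @export
simulate_celltype_mixture <- function(K_types, type_rates, dirichlet_alpha,
                                      n_locations,
                                      depth_model = c(log(1000), 0.5),
                                      seed = 1L) {
  assert_that(K_types >= 1, "K_types must be >= 1")
  type_rates <- as.matrix(type_rates)
  assert_that(nrow(type_rates) == K_types, "type_rates must have K_types rows")
  assert_that(all(type_rates > 0), "type_rates must be positive")
  assert_that(length(dirichlet_alpha) == K_types && all(dirichlet_alpha > 0),
              "dirichlet_alpha must be K_types positive reals")
  G <- ncol(type_rates)
  n <- as.integer(n_locations)
  with_seed(seed, {
    N <- draw_depths(n, depth_model)
    W <- matrix(stats::rgamma(n * K_types, shape = rep(dirichlet_alpha, each = n)),
                nrow = n)
    W <- W / rowSums(W)
    M <- (W %*% type_rates) * N        # n x G matrix of means
    counts <- matrix(as.integer(stats::rpois(n * G, t(M))), nrow = G)
    m <- count_matrix(counts, gene_ids = paste0("gene", seq_len(G)),
                      location_ids = paste0("loc", seq_len(n)))
    rownames(W) <- m$location_ids
    colnames(W) <- paste0("type", seq_len(K_types))
    list(matrix = m, compositions = W,
         truth = list(type_rates = type_rates, alpha = dirichlet_alpha,
                      depths = N, seed = seed))
  })
}
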