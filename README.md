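# spotcount

Which count distribution does a spatial transcriptomics dataset actually
need? `spotcount` answers that gene by gene, for anyone QC-ing or modeling
gene-by-location count matrices (Visium spots, Slide-seq beads, seqFISH /
MERFISH cells, Tomo-seq sections, ...): it fits Poisson, negative binomial
(NB), zero-inflated Poisson (ZIP) and zero-inflated negative binomial
(ZINB) models with sequencing-depth offsets, tests formally for zero
inflation and overdispersion, and then asks the more interesting question —
how much of the detected overdispersion is just expression heterogeneity
across tissue locations or cell-type composition in disguise.

## The model at the core

For gene *g* at location *i* with total count *N<sub>i</sub>*, the
count-component mean is

```
mu_gi = N_i * exp(beta0_g + x_i' beta_g)
```

NB dispersion φ gives variance `mu + mu^2/phi`; zero-inflated families mix
a point mass at zero with weight π. Four nested 1-df likelihood ratio
tests per gene (P-vs-ZIP, P-vs-NB, NB-vs-ZINB, ZIP-vs-ZINB) are referred
to χ²₁ with Bonferroni correction over the genes tested; AIC = 2k − 2ℓ
picks the preferred family. When NB maximum likelihood diverges (sample
variance below the mean), a GEE-style moment plug-in solving
`sigma^2 = mu + mu^2/phi` takes over, and the smaller-AIC candidate wins.
Cross-gene mean–variance and mean–zero-proportion trends are fitted by
Gauss–Newton least squares; location clustering (log-normalize → vst HVG →
PCA → SNN–Louvain) and cell-type-composition covariates drive the
cluster-specific and conditional re-analyses. A seeded synthetic-data
generator with known per-gene ground truth backs every stage. Details and
caveats (boundary-conservative LRTs, log-linear conditional means) are in
`vignettes/count-model-characterization.Rmd`.

## Worked example

A three-cluster tissue where 60% of genes differ across clusters and 40%
do not — Poisson at every location, overdispersed only in aggregate:

```r
library(spotcount)
set.seed(1)
G <- 40
base <- exp(runif(G, log(5e-4), log(3e-3)))
variable <- runif(G) < 0.6
mult <- t(vapply(seq_len(G), function(g)
  if (variable[g]) sample(c(0.2, 1, 5)) else c(1, 1, 1), numeric(3)))
sim <- simulate_cluster_mixture(3, t(mult * base),
                                cluster_sizes = c(60, 60, 60), seed = 1)
m <- filter_genes(sim$matrix)
whole <- run_gene_panel(m)
mean(whole$sig_p_vs_nb)          # 0.575  -- 57.5% "overdispersed" genes
table(whole$preferred_family)    # nb 15 | poisson 14 | zinb 9 | zip 2

per <- cluster_specific_panel(m, sim$labels)
sapply(per, function(p) mean(p$sig_p_vs_nb))   # 0 0 0  -- none within clusters
before_after_ratios(whole, per)$medians[1:2, ]
#       category median_ratio n_used n_omitted
#        pref_nb   0.06666667      3         0
#   pref_poisson   2.71428571      3         0
```

Read: the whole-tissue analysis calls 57.5% of genes significantly
overdispersed (Bonferroni, P-vs-NB) and prefers NB/ZINB for most of them,
yet *within every true cluster zero genes are overdispersed* — the
preference for Poisson rises 2.7-fold after clustering while NB preference
collapses. That is the heterogeneity mechanism this package is built to
expose, reproduced on data where the truth is known.

The same pipeline runs from the command line:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "spotcount", package = "spotcount"))')
Rscript $CLI simulate --out sim --seed 3 --genes 100 --locations 400
Rscript $CLI run-all --input sim/counts.mtx --out results --seed 3
```

Subcommands: `simulate`, `filter`, `summarize`, `trend`, `fit-genes`,
`cluster`, `cluster-panel`, `conditional`, `run-all`.

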