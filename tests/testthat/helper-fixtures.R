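# Shared fixtures and independent oracles used across the test files.

# Small cohort used by several module tests: two phenotype groups, a
# comorbidity-style phi target, and planted effects in the first block.
small_cohort <- function(seed = 11, n = 600, missing_rate = 0) {
  cfg <- sim_config(
    n_individuals = n, n_twin_pairs = floor(n * 0.4),
    phenotypes = c(dz_a = 0.2, dz_b = 0.1, med_a = 0.15),
    phi_targets = data.frame(phenotype_i = "dz_a", phenotype_j = "med_a",
                             phi = 0.4),
    n_trait_blocks = 3, traits_per_block = 4, n_singleton_traits = 2,
    planted_effects = data.frame(
      phenotype = c("dz_a", "dz_b"),
      trait = c("blk01_t1", "blk02_t1"),
      log_odds_per_sd = c(0.8, 0.6)),
    missing_rate = missing_rate,
    seed = seed)
  simulate_cohort(cfg)
}

# The reference end-to-end fixture: 1000 samples in 400 twin pairs, 20
# phenotypes (12 diseases + 8 medications) at prevalences 2-40%, 68 traits
# (12 correlated blocks of 5 plus 8 singletons), comorbidity /
# co-prescription phi targets, and planted effects shared between a disease
# and its paired treatment.
reference_sim_block <- function() {
  phen <- c(setNames(round(seq(0.02, 0.40, length.out = 12), 3),
                     sprintf("dz%02d", 1:12)),
            setNames(round(seq(0.05, 0.30, length.out = 8), 3),
                     sprintf("med%02d", 1:8)))
  list(
    n_individuals = 1000, n_twin_pairs = 400,
    phenotypes = as.list(phen),
    phi_targets = data.frame(
      phenotype_i = c("dz06", "dz08", "med01"),
      phenotype_j = c("med02", "dz10", "med03"),
      phi = c(0.5, 0.3, 0.35)),
    n_trait_blocks = 12, traits_per_block = 5, n_singleton_traits = 8,
    within_block_rho = 0.9,
    planted_effects = data.frame(
      phenotype = c("dz06", "dz06", "med02", "med02", "dz03", "med05"),
      trait = c("blk01_t1", "blk02_t1", "blk01_t1", "blk02_t1",
                "blk05_t2", "solo01"),
      log_odds_per_sd = c(0.7, -0.6, 0.7, -0.6, 0.5, 0.6)),
    missing_rate = 0.03)
}

reference_pipeline_config <- function(seed) {
  sim <- reference_sim_block()
  sim$seed <- seed + 1
  list(seed = seed,
       simulate = sim,
       n_boot = 500,
       disease_phenotypes = sprintf("dz%02d", 1:12),
       medication_phenotypes = sprintf("med%02d", 1:8))
}

# Independent brute-force oracle: is `markers` an independent dominating
# set of the logical adjacency matrix? Direct scan, no package code.
is_independent_dominating <- function(markers, adj) {
  nodes <- rownames(adj)
  mk <- match(markers, nodes)
  if (anyNA(mk)) return(FALSE)
  if (length(mk) > 1L) {
    sub <- adj[mk, mk, drop = FALSE]
    if (any(sub)) return(FALSE)
  }
  rest <- setdiff(seq_along(nodes), mk)
  for (d in rest) {
    if (!any(adj[d, mk])) return(FALSE)
  }
  TRUE
}

# Random symmetric adjacency matrix at a given edge density.
random_graph_adj <- function(n, density, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n, dimnames = list(paste0("t", 1:n),
                                             paste0("t", 1:n)))
  up <- which(upper.tri(adj))
  adj[up] <- runif(length(up)) < density
  adj | t(adj)
}

adj_to_graph <- function(adj) {
  # embed an arbitrary adjacency as a thresholded correlation matrix
  corr <- matrix(0, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  corr[adj] <- 0.9
  diag(corr) <- 1
  threshold_graph(corr, threshold = 0.8)
}

# Rand index between two hard partitions (independent of any package code).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
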