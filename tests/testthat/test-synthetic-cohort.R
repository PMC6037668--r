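test_that("same seed gives an identical fixture, different seed does not", {
  a <- small_cohort(seed = 21)
  b <- small_cohort(seed = 21)
  c <- small_cohort(seed = 22)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$traits, b$traits)
  expect_identical(a$covariates, b$covariates)
  expect_false(identical(a$traits, c$traits))
})

test_that("realized prevalences land near their targets at n = 10000", {
  cfg <- sim_config(n_individuals = 10000,
                    phenotypes = c(p1 = 0.20, p2 = 0.05),
                    n_trait_blocks = 1, traits_per_block = 2,
                    n_singleton_traits = 0, seed = 5)
  ph <- simulate_phenotypes(cfg)
  prev <- colMeans(ph[-1], na.rm = TRUE)
  expect_gte(prev[["p1"]], 0.18); expect_lte(prev[["p1"]], 0.22)
  expect_gte(prev[["p2"]], 0.04); expect_lte(prev[["p2"]], 0.06)
})

test_that("pairwise phi tracks its target and is near zero otherwise", {
  cfg <- sim_config(n_individuals = 10000,
                    phenotypes = c(a = 0.2, b = 0.2, c = 0.3),
                    phi_targets = data.frame(phenotype_i = "a",
                                             phenotype_j = "b", phi = 0.5),
                    n_trait_blocks = 1, traits_per_block = 2,
                    n_singleton_traits = 0, seed = 9)
  ph <- simulate_phenotypes(cfg)
  r_ab <- phi_coefficient(ph$a, ph$b)$phi
  r_ac <- phi_coefficient(ph$a, ph$c)$phi
  expect_lt(abs(r_ab - 0.5), 0.05)
  expect_lt(abs(r_ac), 0.05)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_individuals = 0, phenotypes = c(a = 0.2),
                          seed = 1), "positive")
  expect_error(sim_config(n_individuals = 100, phenotypes = c(a = 0.2),
                          traits_per_block = 0, seed = 1),
               "traits_per_block")
  expect_error(sim_config(n_individuals = 100, phenotypes = c(a = 1.2),
                          seed = 1), "strictly in")
  expect_error(sim_config(n_individuals = 100, phenotypes = c(a = 0.2),
                          n_twin_pairs = 80, seed = 1), "twin")
})

test_that("an infeasible phi target fails naming the offending pair", {
  cfg <- sim_config(n_individuals = 100,
                    phenotypes = c(rare = 0.05, common = 0.5),
                    phi_targets = data.frame(phenotype_i = "rare",
                                             phenotype_j = "common",
                                             phi = 0.9),
                    n_trait_blocks = 1, traits_per_block = 2,
                    n_singleton_traits = 0, seed = 1)
  expect_error(simulate_phenotypes(cfg), "rare / common")
})

test_that("within-block Spearman correlations exceed 0.8 at rho = 0.9", {
  cfg <- sim_config(n_individuals = 2000, phenotypes = c(a = 0.2),
                    n_trait_blocks = 2, traits_per_block = 5,
                    n_singleton_traits = 0, within_block_rho = 0.9,
                    batch_effect_sd = 0, depth_effect = 0,
                    age_effect = 0, bmi_effect = 0, seed = 3)
  te <- simulate_traits_and_effects(cfg, simulate_phenotypes(cfg))
  rho <- spearman_matrix(te$traits)
  within1 <- rho[1:5, 1:5][upper.tri(diag(5))]
  across <- rho[1:5, 6:10]
  expect_true(all(within1 > 0.8))
  expect_true(all(abs(across) < 0.2))
})

test_that("twin pairs share family ID and have correlated traits", {
  fx <- small_cohort(seed = 31, n = 1000)
  fam <- fx$covariates$family_id
  twin1 <- seq(1, 800, by = 2); twin2 <- twin1 + 1
  expect_identical(fam[twin1], fam[twin2])
  tr <- fx$traits[, "blk01_t1"]
  within <- cor(tr[twin1], tr[twin2])
  set.seed(1)
  shuffled <- sample(twin2)
  between <- cor(tr[twin1], tr[shuffled])
  expect_gt(within, between)
  expect_gt(within, 0.1)
})

test_that("planted log-odds are recovered by a logistic fit on the trait", {
  cfg <- sim_config(n_individuals = 8000, phenotypes = c(dz = 0.2),
                    n_trait_blocks = 1, traits_per_block = 1,
                    n_singleton_traits = 0,
                    planted_effects = data.frame(phenotype = "dz",
                                                 trait = "blk01_t1",
                                                 log_odds_per_sd = 0.5),
                    twin_trait_icc = 0, seed = 13)
  te <- simulate_traits_and_effects(cfg, simulate_phenotypes(cfg))
  x <- scale(attr(te$traits, "clean")[, 1])
  fit <- glm(te$phenotypes$dz ~ x, family = binomial())
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - 0.5), 3 * est["Std. Error"])
})

test_that("fixtures round-trip through write_fixture/read_fixture", {
  fx <- small_cohort(seed = 41, n = 200, missing_rate = 0.05)
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  back <- read_fixture(dir)
  expect_identical(back$phenotypes, {
    p <- fx$phenotypes; attributes(p)[c("latent_u", "family")] <- NULL; p
  })
  expect_equal(unname(back$traits), unname(fx$traits),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$covariates, fx$covariates)
  expect_identical(back$truth$trait, fx$truth$trait)
  expect_equal(back$truth$log_odds_per_sd, fx$truth$log_odds_per_sd)
  expect_error(write_fixture(fx, file.path(dir, "nope", "deeper")),
               "does not exist")
})

test_that("traits cannot be simulated from a foreign phenotype table", {
  fx <- small_cohort(seed = 51, n = 100)
  stripped <- fx$phenotypes
  attr(stripped, "latent_u") <- NULL
  expect_error(simulate_traits_and_effects(fx$config, stripped),
               "latent state")
})
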