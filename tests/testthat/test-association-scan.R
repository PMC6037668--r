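# Minimal covariate table with no real confounding (single-level factors
# are dropped, constant fixed effects fit nothing).
flat_covariates <- function(ids) {
  data.frame(sample_id = ids,
             family_id = ids,  # every sample its own family
             sex = "F", dna_extractor = "e1", collection_method = "c1",
             sequencing_run = "r1",
             sequencing_depth = 30000, age = 60, bmi = 26,
             stringsAsFactors = FALSE)
}

test_that("degenerate covariates leave the centered trait untouched", {
  ids <- sprintf("s%03d", 1:50)
  set.seed(2)
  tr <- matrix(rnorm(100), 50, 2, dimnames = list(ids, c("t1", "t2")))
  cov <- flat_covariates(ids)
  cov$family_id <- "F1"  # single level -> dropped
  expect_warning(r <- residualize(tr, cov, "full"), "dropped")
  expect_equal(unname(r[, 1]), unname(tr[, 1] - mean(tr[, 1])),
               tolerance = 1e-8)
  expect_lt(abs(mean(r[, 2])), 1e-8)
})

test_that("residualization removes fixed-covariate and batch structure", {
  fx <- small_cohort(seed = 71, n = 2000)
  ids <- fx$covariates$sample_id
  set.seed(7)
  tr <- cbind(age_driven = 2 * fx$covariates$age + rnorm(2000),
              noise = rnorm(2000))
  rownames(tr) <- ids
  r <- residualize(tr, fx$covariates, "full")
  expect_lt(abs(cor(r[, "age_driven"], fx$covariates$age)), 0.02)
  expect_lt(abs(mean(r[, "age_driven"])), 1e-8)
  # injected run shift is absorbed by the run random intercept
  shift <- ifelse(fx$covariates$sequencing_run == "run1", 1, 0)
  tr2 <- cbind(shifted = rnorm(2000) + shift)
  rownames(tr2) <- ids
  r2 <- residualize(tr2, fx$covariates, "neither")
  run_means <- tapply(r2[, 1], fx$covariates$sequencing_run, mean)
  expect_lt(max(run_means) - min(run_means), 0.1 * sd(r2[, 1]))
  expect_identical(attr(r2, "variant"), "neither")
})

test_that("the scan flags skipped and separated fits instead of dropping", {
  ids <- sprintf("s%02d", 1:40)
  set.seed(4)
  x <- rnorm(40)
  tr <- matrix(x, 40, 1, dimnames = list(ids, "t"))
  phen <- data.frame(sample_id = ids,
                     all_neg = 0L,
                     sep = as.integer(x > 0),
                     stringsAsFactors = FALSE)
  res <- logistic_scan(phen, tr)
  expect_identical(res$status[res$phenotype == "all_neg"], "skipped")
  expect_identical(res$status[res$phenotype == "sep"], "separated")
  expect_true(all(is.na(res$p)))
})

test_that("planted effects are detected with the right sign and size", {
  fx <- small_cohort(seed = 81, n = 1500)
  r <- residualize(fx$traits, fx$covariates, "full")
  res <- bh_adjust(logistic_scan(fx$phenotypes, r))
  hit <- res[res$phenotype == "dz_a" & res$trait == "blk01_t1", ]
  expect_identical(hit$status, "ok")
  expect_lt(hit$p, 1e-4)
  expect_gt(hit$beta, 0)
  expect_gte(hit$q, hit$p)
})

test_that("null p-values are uniform (KS) and q >= p after adjustment", {
  cfg <- sim_config(n_individuals = 800,
                    phenotypes = c(a = 0.2, b = 0.3),
                    n_trait_blocks = 2, traits_per_block = 3,
                    n_singleton_traits = 4, seed = 29)
  fx <- simulate_cohort(cfg)
  res <- bh_adjust(logistic_scan(fx$phenotypes, fx$traits))
  ok <- res$status == "ok"
  expect_gt(ks.test(res$p[ok], "punif")$p.value, 0.01)
  expect_true(all(res$q[ok] >= res$p[ok]))
})

test_that("BH adjustment matches the hand-derived step-up values", {
  mk <- function(p) data.frame(phenotype = "x", trait = paste0("t", seq_along(p)),
                               variant = "full", beta = 1, se = 1, p = p,
                               q = NA_real_, n_cases = 10L, n_controls = 10L,
                               status = "ok", stringsAsFactors = FALSE)
  expect_equal(bh_adjust(mk(c(0.01, 0.02, 0.03, 0.04)))$q, rep(0.04, 4))
  expect_equal(bh_adjust(mk(0.123))$q, 0.123)
  p <- sort(runif(20))
  expect_true(all(diff(bh_adjust(mk(p))$q) >= -1e-15))
  expect_identical(nrow(bh_adjust(mk(0.5)[0, ])), 0L)
  # non-ok rows keep q = NA and do not count toward m
  d <- mk(c(0.01, 0.02)); d$status[2] <- "separated"; d$p[2] <- NA
  out <- bh_adjust(d)
  expect_equal(out$q[1], 0.01)
  expect_true(is.na(out$q[2]))
})

test_that("per-phenotype FDR scope adjusts within each phenotype", {
  d <- data.frame(phenotype = rep(c("a", "b"), each = 2),
                  trait = rep(c("t1", "t2"), 2), variant = "full",
                  beta = 1, se = 1, p = c(0.01, 0.04, 0.5, 0.6),
                  q = NA_real_, n_cases = 5L, n_controls = 5L,
                  status = "ok", stringsAsFactors = FALSE)
  out <- bh_adjust(d, scope = "per_phenotype")
  expect_equal(out$q[1:2], p.adjust(c(0.01, 0.04), "BH"))
  expect_equal(out$q[3:4], p.adjust(c(0.5, 0.6), "BH"))
})

test_that("scan variants agree when age/BMI carry no confounding", {
  cfg <- sim_config(n_individuals = 1200,
                    phenotypes = c(a = 0.25, b = 0.15),
                    n_trait_blocks = 2, traits_per_block = 3,
                    n_singleton_traits = 2,
                    planted_effects = data.frame(
                      phenotype = "a", trait = "blk01_t1",
                      log_odds_per_sd = 0.7),
                    age_effect = 0, bmi_effect = 0, seed = 37)
  fx <- simulate_cohort(cfg)
  sc <- run_scan_variants(fx$phenotypes, fx$traits, fx$covariates)
  expect_setequal(unique(sc$results$variant),
                  c("full", "no_bmi", "no_age", "neither"))
  off <- sc$beta_correlations[upper.tri(sc$beta_correlations)]
  expect_true(all(off > 0.95))
  # determinism: identical inputs give identical results
  sc2 <- run_scan_variants(fx$phenotypes, fx$traits, fx$covariates)
  expect_identical(sc$results, sc2$results)
})
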