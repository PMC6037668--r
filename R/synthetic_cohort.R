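# Twin-structured synthetic cohort generator.
#
# Binary phenotypes come from a Gaussian copula: each phenotype has a latent
# standard-normal score (correlated across phenotypes to hit target phi
# values, and within twin pairs through a family component), mapped to a
# uniform U. A sample is a case when U < plogis(alpha + sum(beta * trait)),
# so a planted `log_odds_per_sd` is exactly the conditional logistic slope
# on the standardized trait, and with no planted effects the model reduces
# to thresholding the latent normal at the prevalence quantile.

#' Build a simulation configuration
#'
#' Defines a twin-pair cohort with binary phenotypes at target prevalences,
#' optional target phi correlations between phenotype pairs, blocks of
#' intercorrelated standardized traits (emulating log relative abundances of
#' related taxa), planted logistic effects linking traits to phenotypes, and
#' technical confounders (DNA extraction batch, collection method,
#' sequencing run, sequencing depth) injected into the observed traits.
#'
#' @param n_individuals Number of samples.
#' @param phenotypes Named numeric vector of target prevalences in (0, 1).
#' @param seed Integer seed; fully determines the fixture.
#' @param n_twin_pairs Number of complete twin pairs (first `2 *
#'   n_twin_pairs` samples); remaining samples are singletons.
#' @param phi_targets Optional data frame (`phenotype_i`, `phenotype_j`,
#'   `phi`) of target pairwise phi correlations; unlisted pairs are near 0.
#' @param n_trait_blocks,traits_per_block,within_block_rho Correlated trait
#'   blocks: number of blocks, block size, and the common within-block
#'   Pearson correlation in (0, 1).
#' @param n_singleton_traits Additional mutually independent traits.
#' @param planted_effects Optional data frame (`phenotype`, `trait`,
#'   `log_odds_per_sd`) of true logistic effects per 1 SD of the clean
#'   (confounder-free) trait.
#' @param twin_phenotype_icc,twin_trait_icc Latent within-twin-pair
#'   intraclass correlations for phenotype liabilities and traits.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,prop_female Covariate
#'   distributions (age and sex are shared within a twin pair).
#' @param n_extractors,n_collection_methods,n_runs Batch factor level
#'   counts.
#' @param depth_meanlog,depth_sdlog Log-normal sequencing depth parameters.
#' @param batch_effect_sd SD of per-trait batch-level offsets added to
#'   observed traits.
#' @param depth_effect,age_effect,bmi_effect SDs of per-trait loadings of
#'   standardized log depth / age / BMI injected into observed traits.
#' @param missing_rate Fraction of phenotype entries set to unknown.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_individuals,
                       phenotypes,
                       seed,
                       n_twin_pairs = floor(n_individuals / 2),
                       phi_targets = NULL,
                       n_trait_blocks = 12L,
                       traits_per_block = 5L,
                       n_singleton_traits = 8L,
                       within_block_rho = 0.9,
                       planted_effects = NULL,
                       twin_phenotype_icc = 0.25,
                       twin_trait_icc = 0.3,
                       age_mean = 60, age_sd = 12,
                       bmi_mean = 26, bmi_sd = 5,
                       prop_female = 0.9,
                       n_extractors = 3L, n_collection_methods = 2L,
                       n_runs = 8L,
                       depth_meanlog = log(3e4), depth_sdlog = 0.4,
                       batch_effect_sd = 0.3,
                       depth_effect = 0.2,
                       age_effect = 0.1,
                       bmi_effect = 0.1,
                       missing_rate = 0) {
  if (n_individuals < 1L) stop_miwas("n_individuals must be positive")
  if (is.null(names(phenotypes)) || !is.numeric(phenotypes)) {
    stop_miwas("phenotypes must be a named numeric vector of prevalences")
  }
  if (any(phenotypes <= 0 | phenotypes >= 1)) {
    stop_miwas("prevalences must lie strictly in (0, 1)")
  }
  if (n_individuals < 2L * n_twin_pairs) {
    stop_miwas("n_individuals must be at least 2 * n_twin_pairs")
  }
  if (traits_per_block < 1L) stop_miwas("traits_per_block must be >= 1")
  if (within_block_rho <= 0 || within_block_rho >= 1) {
    stop_miwas("within_block_rho must lie strictly in (0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_miwas("missing_rate must lie in [0, 1)")
  }
  if (missing(seed)) stop_miwas("seed is mandatory")
  trait_names <- c(
    unlist(lapply(seq_len(n_trait_blocks), function(b) {
      sprintf("blk%02d_t%d", b, seq_len(traits_per_block))
    })),
    if (n_singleton_traits > 0L) sprintf("solo%02d",
                                         seq_len(n_singleton_traits)))
  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects,
                                     stringsAsFactors = FALSE)
    stopifnot(all(c("phenotype", "trait", "log_odds_per_sd") %in%
                    names(planted_effects)))
    bad_p <- setdiff(planted_effects$phenotype, names(phenotypes))
    bad_t <- setdiff(planted_effects$trait, trait_names)
    if (length(bad_p)) stop_miwas("unknown phenotype(s) in planted_effects: ",
                                  paste(bad_p, collapse = ", "))
    if (length(bad_t)) stop_miwas("unknown trait(s) in planted_effects: ",
                                  paste(bad_t, collapse = ", "))
  }
  if (!is.null(phi_targets)) {
    phi_targets <- as.data.frame(phi_targets, stringsAsFactors = FALSE)
    stopifnot(all(c("phenotype_i", "phenotype_j", "phi") %in%
                    names(phi_targets)))
    bad <- setdiff(c(phi_targets$phenotype_i, phi_targets$phenotype_j),
                   names(phenotypes))
    if (length(bad)) stop_miwas("unknown phenotype(s) in phi_targets: ",
                                paste(bad, collapse = ", "))
    if (any(abs(phi_targets$phi) >= 1)) {
      stop_miwas("target phi must lie strictly in (-1, 1)")
    }
  }
  fields <- c(names(formals(sim_config)), "trait_names")
  structure(mget(fields, envir = environment()), class = "sim_config")
}

# P(Z1 < z1, Z2 < z2) for standard bivariate normal with correlation r,
# by 1-D quadrature over the conditional distribution.
pbinorm <- function(z1, z2, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(z1) * stats::pnorm(z2))
  s <- sqrt(1 - r^2)
  stats::integrate(function(t) {
    stats::dnorm(t) * stats::pnorm((z2 - r * t) / s)
  }, lower = -8.5, upper = z1, rel.tol = 1e-10)$value
}

# Latent (tetrachoric) correlation reproducing a target phi between two
# thresholded binary variables with the given prevalences.
solve_latent_rho <- function(p1, p2, phi, pair_label) {
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  p11 <- p1 * p2 + phi * denom
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    stop_miwas("infeasible phi target for pair ", pair_label,
               ": joint prevalence ", signif(p11, 4),
               " outside [", signif(lo, 4), ", ", signif(hi, 4), "]")
  }
  z1 <- stats::qnorm(p1); z2 <- stats::qnorm(p2)
  f <- function(r) pbinorm(z1, z2, r) - p11
  stats::uniroot(f, interval = c(-0.9995, 0.9995), tol = 1e-9)$root
}

latent_correlation <- function(config) {
  phen <- names(config$phenotypes)
  k <- length(phen)
  R <- diag(k); dimnames(R) <- list(phen, phen)
  if (!is.null(config$phi_targets) && nrow(config$phi_targets)) {
    for (i in seq_len(nrow(config$phi_targets))) {
      a <- config$phi_targets$phenotype_i[i]
      b <- config$phi_targets$phenotype_j[i]
      r <- solve_latent_rho(config$phenotypes[[a]], config$phenotypes[[b]],
                            config$phi_targets$phi[i],
                            paste(a, b, sep = " / "))
      R[a, b] <- R[b, a] <- r
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    pairs <- if (is.null(config$phi_targets)) "" else
      paste(config$phi_targets$phenotype_i, config$phi_targets$phenotype_j,
            sep = "/", collapse = ", ")
    stop_miwas("latent correlation matrix not positive definite after ",
               "mapping phi targets (pairs: ", pairs, ")")
  }
  R
}

family_index <- function(config) {
  n <- config$n_individuals
  np <- config$n_twin_pairs
  fam <- integer(n)
  if (np > 0L) fam[seq_len(2L * np)] <- rep(seq_len(np), each = 2L)
  nsingle <- n - 2L * np
  if (nsingle > 0L) fam[(2L * np + 1L):n] <- np + seq_len(nsingle)
  fam
}

# Draw n rows of MVN(0, R) given the upper Cholesky factor of R.
rmvn_chol <- function(n, cholR) {
  k <- ncol(cholR)
  matrix(stats::rnorm(n * k), n, k) %*% cholR
}

#' Simulate binary phenotype statuses
#'
#' Latent multivariate-Gaussian threshold model: phenotype liabilities are
#' correlated across phenotypes (via tetrachoric mapping of the target phi
#' values) and within twin pairs (family intraclass correlation), then
#' thresholded at the quantile matching each target prevalence. The latent
#' copula uniforms are kept in attribute `"latent_u"` so planted effects can
#' later re-express case status conditionally on traits.
#'
#' @param config A [sim_config].
#' @return Phenotype data frame (`sample_id` + one 1/0/NA column per
#'   phenotype) with attributes `"latent_u"` and `"family"`.
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  R <- latent_correlation(config)
  n <- config$n_individuals
  phen <- names(config$phenotypes)
  fam <- family_index(config)
  icc <- config$twin_phenotype_icc
  U <- with_seed(derive_seed(config$seed, 1L), {
    cholR <- chol(R)
    E <- rmvn_chol(n, cholR)
    FF <- rmvn_chol(max(fam), cholR)
    Z <- sqrt(1 - icc) * E + sqrt(icc) * FF[fam, , drop = FALSE]
    stats::pnorm(Z)
  })
  colnames(U) <- phen
  status <- vapply(phen, function(p) {
    as.integer(U[, p] < config$phenotypes[[p]])
  }, integer(n))
  if (config$missing_rate > 0) {
    mask <- with_seed(derive_seed(config$seed, 2L), {
      matrix(stats::runif(n * length(phen)) < config$missing_rate,
             n, length(phen))
    })
    status[mask] <- NA_integer_
  }
  out <- data.frame(sample_id = sprintf("S%05d", seq_len(n)), status,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "latent_u") <- U
  attr(out, "family") <- fam
  out
}

#' Simulate traits, covariates, and apply planted effects
#'
#' Clean traits are standard-normal with equicorrelated blocks
#' (`within_block_rho`) and a shared twin-pair component. Observed traits
#' add technical structure: per-trait batch-level offsets (extractor,
#' collection method, run), a loading on standardized log sequencing depth,
#' and small age/BMI loadings — so downstream residualization has real work
#' to do. For phenotypes carrying planted effects, case status is redrawn
#' from the latent copula uniform as `U < plogis(alpha + X beta)` with
#' `alpha` solved so the realized prevalence matches its target.
#'
#' @param config A [sim_config].
#' @param phenotypes The [simulate_phenotypes] output for the same config.
#' @return List with `traits` (observed matrix; clean signal in attribute
#'   `"clean"`), `covariates` (data frame), and `phenotypes` (updated for
#'   planted effects).
#' @export
simulate_traits_and_effects <- function(config, phenotypes) {
  stopifnot(inherits(config, "sim_config"))
  U <- attr(phenotypes, "latent_u")
  if (is.null(U)) {
    stop_miwas("phenotype table lacks latent state; generate it with ",
               "simulate_phenotypes() from the same config")
  }
  n <- config$n_individuals
  fam <- family_index(config)
  nb <- config$n_trait_blocks; tpb <- config$traits_per_block
  ns <- config$n_singleton_traits
  rho <- config$within_block_rho; icc <- config$twin_trait_icc

  block_draw <- function(nrows) {
    # equicorrelated blocks: shared factor + idiosyncratic noise
    cols <- list()
    if (nb > 0L) {
      for (b in seq_len(nb)) {
        shared <- stats::rnorm(nrows)
        eps <- matrix(stats::rnorm(nrows * tpb), nrows, tpb)
        cols[[b]] <- sqrt(rho) * shared + sqrt(1 - rho) * eps
      }
    }
    if (ns > 0L) cols[[nb + 1L]] <- matrix(stats::rnorm(nrows * ns),
                                           nrows, ns)
    do.call(cbind, cols)
  }

  res <- with_seed(derive_seed(config$seed, 3L), {
    Tind <- block_draw(n)
    Tfam <- block_draw(max(fam))
    clean <- sqrt(1 - icc) * Tind + sqrt(icc) * Tfam[fam, , drop = FALSE]
    colnames(clean) <- config$trait_names

    sexF <- stats::rbinom(max(fam), 1L, config$prop_female)
    age_f <- pmin(pmax(stats::rnorm(max(fam), config$age_mean,
                                    config$age_sd), 18), 100)
    covariates <- data.frame(
      sample_id = phenotypes$sample_id,
      family_id = sprintf("F%05d", fam),
      sex = ifelse(sexF[fam] == 1L, "F", "M"),
      age = round(age_f[fam], 1),
      bmi = round(pmax(stats::rnorm(n, config$bmi_mean, config$bmi_sd), 15),
                  1),
      dna_extractor = sprintf("ext%d",
                              sample.int(config$n_extractors, n, TRUE)),
      collection_method = sprintf("cm%d",
                                  sample.int(config$n_collection_methods,
                                             n, TRUE)),
      sequencing_run = sprintf("run%d", sample.int(config$n_runs, n, TRUE)),
      sequencing_depth = as.integer(round(stats::rlnorm(
        n, config$depth_meanlog, config$depth_sdlog))),
      stringsAsFactors = FALSE)

    p <- ncol(clean)
    observed <- clean
    for (fac in c("dna_extractor", "collection_method", "sequencing_run")) {
      lev <- unique(covariates[[fac]])
      off <- matrix(stats::rnorm(length(lev) * p, 0, config$batch_effect_sd),
                    length(lev), p, dimnames = list(lev, NULL))
      observed <- observed + off[covariates[[fac]], , drop = FALSE]
    }
    observed <- observed +
      outer(zscore(log(covariates$sequencing_depth)),
            stats::rnorm(p, 0, config$depth_effect)) +
      outer(zscore(covariates$age), stats::rnorm(p, 0, config$age_effect)) +
      outer(zscore(covariates$bmi), stats::rnorm(p, 0, config$bmi_effect))
    list(clean = clean, observed = observed, covariates = covariates)
  })

  out_phen <- phenotypes
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    for (ph in unique(pe$phenotype)) {
      rows <- pe[pe$phenotype == ph, , drop = FALSE]
      eta <- as.vector(res$clean[, rows$trait, drop = FALSE] %*%
                         rows$log_odds_per_sd)
      target <- config$phenotypes[[ph]]
      alpha <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) -
                                target, interval = c(-30, 30))$root
      new_status <- as.integer(U[, ph] < stats::plogis(alpha + eta))
      new_status[is.na(out_phen[[ph]])] <- NA_integer_  # keep missingness
      out_phen[[ph]] <- new_status
    }
    attr(out_phen, "latent_u") <- U
    attr(out_phen, "family") <- attr(phenotypes, "family")
  }

  traits <- res$observed
  rownames(traits) <- phenotypes$sample_id
  rownames(res$clean) <- phenotypes$sample_id
  attr(traits, "clean") <- res$clean
  attr(traits, "trait_info") <- data.frame(
    trait = colnames(traits),
    kind = rep("synthetic_marker", ncol(traits)),
    stringsAsFactors = FALSE)
  list(traits = traits, covariates = res$covariates,
       phenotypes = out_phen)
}

#' Simulate a complete cohort fixture
#'
#' Orchestrates [simulate_phenotypes] and [simulate_traits_and_effects] and
#' bundles the result with the planted-effect ground truth.
#'
#' @param config A [sim_config].
#' @return Object of class `cohort_fixture`: list with `phenotypes`,
#'   `traits`, `covariates`, `truth` (data frame of planted effects) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  phen <- simulate_phenotypes(config)
  te <- simulate_traits_and_effects(config, phen)
  truth <- config$planted_effects %||%
    data.frame(phenotype = character(0), trait = character(0),
               log_odds_per_sd = numeric(0), stringsAsFactors = FALSE)
  structure(list(phenotypes = te$phenotypes, traits = te$traits,
                 covariates = te$covariates, truth = truth,
                 config = config),
            class = "cohort_fixture")
}

#' @export
print.cohort_fixture <- function(x, ...) {
  cat("cohort_fixture:", nrow(x$phenotypes), "samples,",
      ncol(x$phenotypes) - 1L, "phenotypes,", ncol(x$traits), "traits,",
      nrow(x$truth), "planted effects (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a cohort fixture to TSV files
#'
#' Writes `phenotypes.tsv`, `traits.tsv`, `covariates.tsv` and `truth.tsv`
#' (planted effects: phenotype, trait, log_odds_per_sd) into an existing
#' directory; all tables carry a header row and a `sample_id` first column
#' and round-trip through [read_fixture].
#'
#' @param fixture A [simulate_cohort] result.
#' @param directory Existing writable directory.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fixture, directory) {
  stopifnot(inherits(fixture, "cohort_fixture"))
  if (!dir.exists(directory)) {
    stop_miwas("directory does not exist: ", directory)
  }
  paths <- file.path(directory, c("phenotypes.tsv", "traits.tsv",
                                  "covariates.tsv", "truth.tsv"))
  write_tsv(fixture$phenotypes, paths[1])
  tr <- data.frame(sample_id = rownames(fixture$traits), fixture$traits,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(tr, paths[2])
  write_tsv(fixture$covariates, paths[3])
  write_tsv(fixture$truth, paths[4])
  invisible(paths)
}

#' Read a cohort fixture written by [write_fixture]
#'
#' @param directory Directory holding the four fixture TSVs.
#' @return A `cohort_fixture` (without the generator's internal latent
#'   state).
#' @export
read_fixture <- function(directory) {
  phen <- read_phenotype_table(file.path(directory, "phenotypes.tsv"))
  traits <- read_trait_matrix(file.path(directory, "traits.tsv"))
  cov <- read_covariate_table(file.path(directory, "covariates.tsv"))
  truth <- read_tsv(file.path(directory, "truth.tsv"))
  structure(list(phenotypes = phen, traits = traits, covariates = cov,
                 truth = truth, config = NULL), class = "cohort_fixture")
}
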