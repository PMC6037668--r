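# Confounder residualization of marker traits (mixed models) followed by
# per-(phenotype, trait) logistic regression with BH false discovery rate
# control, in four covariate-sensitivity variants.

SCAN_VARIANTS <- c("full", "no_bmi", "no_age", "neither")

variant_fixed <- function(variant) {
  switch(variant,
         full = c("log_depth", "age", "bmi"),
         no_bmi = c("log_depth", "age"),
         no_age = c("log_depth", "bmi"),
         neither = "log_depth",
         stop_miwas("unknown scan variant: ", variant))
}

RANDOM_FACTORS <- c("dna_extractor", "collection_method", "sequencing_run",
                    "sex", "family_id")

#' Residualize traits against technical and biological confounders
#'
#' Per trait, fits a Gaussian mixed model with random intercepts for DNA
#' extractor, collection method, sequencing run, sex and family, and the
#' variant's fixed effects (log sequencing depth always; age and/or BMI
#' depending on the variant), then returns the residuals. Random-effect
#' factors with fewer than two levels are dropped with a warning; a trait
#' whose mixed fit fails falls back to a fixed-effects-only linear model
#' (grouping factors entered as fixed), recorded in the fit log.
#'
#' @param traits Numeric samples x traits matrix (sample row names).
#' @param covariates Covariate data frame (see [read_covariate_table]);
#'   sequencing depth enters on the log scale.
#' @param variant One of `"full"`, `"no_bmi"`, `"no_age"`, `"neither"`.
#' @return Residual matrix (same shape), with attributes `"variant"` and
#'   `"fit_log"` (data frame: trait, method).
#' @export
residualize <- function(traits, covariates, variant = "full") {
  m <- as.matrix(traits)
  variant <- match.arg(variant, SCAN_VARIANTS)
  stopifnot(is.data.frame(covariates), "sample_id" %in% names(covariates))
  if (!identical(rownames(m), as.character(covariates$sample_id))) {
    stop_miwas("traits and covariates must share one sample index")
  }
  cov <- covariates
  cov$log_depth <- log(cov$sequencing_depth)
  if (any(!is.finite(cov$log_depth))) {
    stop_miwas("sequencing_depth must be positive")
  }
  fixed <- variant_fixed(variant)
  missing_fixed <- setdiff(fixed, names(cov))
  if (length(missing_fixed)) {
    stop_miwas("missing covariate column(s): ",
               paste(missing_fixed, collapse = ", "))
  }
  rand <- intersect(RANDOM_FACTORS, names(cov))
  for (f in rand) cov[[f]] <- factor(cov[[f]])
  drop <- rand[vapply(rand, function(f) nlevels(cov[[f]]) < 2L, TRUE)]
  if (length(drop)) {
    warning("random-effect factor(s) with <2 levels dropped: ",
            paste(drop, collapse = ", "))
    rand <- setdiff(rand, drop)
  }
  use_mixed <- length(rand) > 0L
  re_terms <- if (use_mixed) paste0("(1|", rand, ")") else character(0)
  fml_mixed <- stats::as.formula(paste(".y ~", paste(c(fixed, re_terms),
                                                     collapse = " + ")))
  fml_fixed <- stats::reformulate(c(fixed, rand), response = ".y")

  out <- m
  methods <- character(ncol(m))
  base_fit <- NULL  # first successful mixed fit, reused via refit()
  for (j in seq_len(ncol(m))) {
    yy <- m[, j]
    obs <- !is.na(yy)
    if (!any(obs)) {
      methods[j] <- "skipped"
      out[, j] <- NA_real_
      next
    }
    covj <- cov[obs, , drop = FALSE]
    covj$.y <- yy[obs]
    complete <- all(obs)
    r <- NULL
    if (use_mixed) {
      fit <- tryCatch(suppressMessages(suppressWarnings(
        if (is.null(base_fit) || !complete) {
          lme4::lmer(fml_mixed, data = covj, REML = TRUE,
                     control = lme4::lmerControl(
                       calc.derivs = FALSE,
                       check.conv.singular = "ignore"))
        } else {
          lme4::refit(base_fit, newresp = covj$.y)
        })), error = function(e) NULL)
      if (!is.null(fit)) {
        if (is.null(base_fit) && complete) base_fit <- fit
        r <- stats::residuals(fit)
        methods[j] <- "mixed"
      }
    }
    if (is.null(r)) {
      r <- stats::residuals(stats::lm(fml_fixed, data = covj))
      methods[j] <- if (use_mixed) "fixed_fallback" else "fixed"
    }
    full <- rep(NA_real_, nrow(m))
    full[obs] <- r - mean(r)
    out[, j] <- full
  }
  attr(out, "variant") <- variant
  attr(out, "fit_log") <- data.frame(trait = colnames(m), method = methods,
                                     stringsAsFactors = FALSE)
  out
}

# Wald logistic fit of y ~ 1 + x via IRLS; returns beta, se, p, status.
logistic_wald <- function(x, y) {
  X <- cbind(1, x)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                status = "unconverged"))
  }
  beta <- fit$coefficients[2]
  mu <- fit$fitted.values
  w <- fit$weights
  status <- "ok"
  if (!fit$converged) status <- "unconverged"
  eps <- 1e-8
  if (any(mu < eps | mu > 1 - eps) && abs(beta) > 10) status <- "separated"
  xtwx <- crossprod(X * sqrt(w))
  cv <- tryCatch(solve(xtwx), error = function(e) NULL)
  if (is.null(cv)) {
    return(list(beta = beta, se = NA_real_, p = NA_real_,
                status = "separated"))
  }
  se <- sqrt(cv[2, 2])
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  if (status != "ok") p <- NA_real_
  list(beta = unname(beta), se = unname(se), p = unname(p), status = status)
}

#' Logistic association scan over all phenotype-by-trait pairs
#'
#' For each pair fits `status ~ intercept + trait` by logistic regression on
#' samples with both values observed, recording the Wald slope, standard
#' error and p-value. Pairs without both cases and controls are emitted with
#' status `"skipped"`; separation and non-convergence are flagged, never
#' silently dropped.
#'
#' @param phenotypes Phenotype data frame (`sample_id` + 1/0/NA columns).
#' @param residual_traits Numeric samples x traits matrix (typically
#'   [residualize] output).
#' @param variant Scan-variant label stored with the results.
#' @return Data frame of class `association_result`: phenotype, trait,
#'   variant, beta, se, p, q (`NA` until [bh_adjust]), n_cases, n_controls,
#'   status.
#' @export
logistic_scan <- function(phenotypes, residual_traits, variant = "full") {
  stopifnot(is.data.frame(phenotypes), "sample_id" %in% names(phenotypes))
  m <- as.matrix(residual_traits)
  if (!identical(rownames(m), as.character(phenotypes$sample_id))) {
    stop_miwas("phenotypes and traits must share one sample index")
  }
  phen <- setdiff(names(phenotypes), "sample_id")
  rows <- vector("list", length(phen) * ncol(m))
  k <- 0L
  for (ph in phen) {
    y_all <- phenotypes[[ph]]
    for (j in seq_len(ncol(m))) {
      x_all <- m[, j]
      ok <- !is.na(y_all) & !is.na(x_all)
      y <- y_all[ok]; x <- x_all[ok]
      n_cases <- sum(y == 1L); n_controls <- sum(y == 0L)
      k <- k + 1L
      if (n_cases == 0L || n_controls == 0L) {
        rows[[k]] <- data.frame(phenotype = ph, trait = colnames(m)[j],
                                variant = variant, beta = NA_real_,
                                se = NA_real_, p = NA_real_, q = NA_real_,
                                n_cases = n_cases, n_controls = n_controls,
                                status = "skipped",
                                stringsAsFactors = FALSE)
        next
      }
      f <- logistic_wald(x, y)
      rows[[k]] <- data.frame(phenotype = ph, trait = colnames(m)[j],
                              variant = variant, beta = f$beta, se = f$se,
                              p = f$p, q = NA_real_, n_cases = n_cases,
                              n_controls = n_controls, status = f$status,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment of scan results
#'
#' Step-up adjustment of the p-values of converged (`status == "ok"`) rows;
#' unusable rows keep `q = NA` and do not count toward the number of tests.
#'
#' @param results An [logistic_scan] result (rows from one scan variant).
#' @param scope `"global"` (one adjustment across the whole phenotype x
#'   trait matrix, the default) or `"per_phenotype"`.
#' @return The results with the `q` column filled in.
#' @export
bh_adjust <- function(results, scope = c("global", "per_phenotype")) {
  scope <- match.arg(scope)
  if (nrow(results) == 0L) return(results)
  ok <- results$status == "ok" & !is.na(results$p)
  results$q <- NA_real_
  if (!any(ok)) return(results)
  if (scope == "global") {
    results$q[ok] <- stats::p.adjust(results$p[ok], method = "BH")
  } else {
    for (ph in unique(results$phenotype)) {
      sel <- ok & results$phenotype == ph
      if (any(sel)) {
        results$q[sel] <- stats::p.adjust(results$p[sel], method = "BH")
      }
    }
  }
  results
}

#' Run all covariate-sensitivity scan variants
#'
#' Residualizes the traits under each variant (always adjusting for
#' sequencing depth; dropping BMI, age, or both), scans every phenotype x
#' trait pair, applies FDR adjustment, and reports the Pearson correlation
#' of the slope vectors between variants.
#'
#' @param phenotypes Phenotype data frame.
#' @param traits Raw (non-residualized) trait matrix.
#' @param covariates Covariate data frame.
#' @param variants Subset of `c("full", "no_bmi", "no_age", "neither")`.
#' @param fdr_scope Passed to [bh_adjust].
#' @return List with `results` (row-bound `association_result` across
#'   variants) and `beta_correlations` (variant x variant matrix).
#' @export
run_scan_variants <- function(phenotypes, traits, covariates,
                              variants = SCAN_VARIANTS,
                              fdr_scope = "global") {
  variants <- match.arg(variants, SCAN_VARIANTS, several.ok = TRUE)
  per <- lapply(variants, function(v) {
    res_traits <- residualize(traits, covariates, variant = v)
    bh_adjust(logistic_scan(phenotypes, res_traits, variant = v),
              scope = fdr_scope)
  })
  names(per) <- variants
  k <- length(variants)
  bc <- matrix(NA_real_, k, k, dimnames = list(variants, variants))
  diag(bc) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    a <- per[[i]]; b <- per[[j]]
    ok <- a$status == "ok" & b$status == "ok"
    bc[i, j] <- bc[j, i] <- stats::cor(a$beta[ok], b$beta[ok])
  }
  results <- do.call(rbind, per)
  rownames(results) <- NULL
  class(results) <- c("association_result", "data.frame")
  list(results = results, beta_correlations = bc)
}
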