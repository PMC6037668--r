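# Disease-medication relationships: phi correlation of statuses with FDR,
# and Jaccard overlap of the two phenotypes' nominal microbiota-association
# sets, compared only for eligible pairs (significant phi and both sets of
# size >= 10).

#' Nominal microbiota-association set of one phenotype
#'
#' Traits whose association with the phenotype is nominally significant
#' (`p < alpha`, converged fits only) in one scan variant.
#'
#' @param results `association_result` rows from a single scan variant.
#' @param phenotype Phenotype name.
#' @param alpha Nominal threshold (default 0.05).
#' @return Character vector of trait names.
#' @export
association_set <- function(results, phenotype, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  if (!phenotype %in% results$phenotype) {
    stop_miwas("unknown phenotype: ", phenotype)
  }
  sel <- results$phenotype == phenotype & results$status == "ok" &
    !is.na(results$p) & results$p < alpha
  unique(results$trait[sel])
}

#' Jaccard index of two trait sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 (with a warning) when both
#' sets are empty.
#'
#' @param a,b Character vectors (sets).
#' @return Value in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("Jaccard of two empty sets defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Disease-medication overlap table
#'
#' Scores every disease x medication pair: phi correlation of the two
#' status vectors on pairwise-complete samples (FDR-adjusted over all pairs
#' in the table), sizes of each phenotype's nominal microbiota-association
#' set, their Jaccard overlap, and the eligibility flag (phi FDR < 0.05 and
#' both sets of at least `min_set_size` traits). Rows are sorted by phi
#' descending.
#'
#' @param disease_results,medication_results `association_result` rows (one
#'   scan variant each) for diseases and medications on the same trait set.
#' @param disease_table,medication_table Phenotype data frames sharing a
#'   sample universe (matched on `sample_id`).
#' @param alpha Nominal threshold for the association sets.
#' @param fdr_alpha Phi FDR eligibility threshold.
#' @param min_set_size Minimum association-set size for eligibility.
#' @return Data frame: disease, medication, phi, phi_p, phi_q,
#'   n_assoc_disease, n_assoc_medication, jaccard, eligible.
#' @export
build_overlap_table <- function(disease_results, medication_results,
                                disease_table, medication_table,
                                alpha = 0.05, fdr_alpha = 0.05,
                                min_set_size = 10L) {
  stopifnot(is.data.frame(disease_table), is.data.frame(medication_table))
  shared <- intersect(disease_table$sample_id, medication_table$sample_id)
  if (length(shared) == 0L) stop_miwas("no shared samples for phi")
  dtab <- disease_table[match(shared, disease_table$sample_id), ,
                        drop = FALSE]
  mtab <- medication_table[match(shared, medication_table$sample_id), ,
                           drop = FALSE]
  diseases <- setdiff(names(dtab), "sample_id")
  meds <- setdiff(names(mtab), "sample_id")
  dsets <- lapply(setNames(diseases, diseases), function(d)
    association_set(disease_results, d, alpha))
  msets <- lapply(setNames(meds, meds), function(m)
    association_set(medication_results, m, alpha))
  grid <- expand.grid(disease = diseases, medication = meds,
                      stringsAsFactors = FALSE)
  phi <- p <- jac <- numeric(nrow(grid))
  nA <- nB <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- suppressWarnings(phi_coefficient(dtab[[grid$disease[i]]],
                                          mtab[[grid$medication[i]]]))
    phi[i] <- r$phi; p[i] <- r$p_value
    A <- dsets[[grid$disease[i]]]; B <- msets[[grid$medication[i]]]
    nA[i] <- length(A); nB[i] <- length(B)
    jac[i] <- if (nA[i] == 0L && nB[i] == 0L) 0 else jaccard_index(A, B)
  }
  # same BH implementation as the scan, applied to the phi p-value pool
  stub <- data.frame(phenotype = grid$disease, trait = grid$medication,
                     variant = "phi", beta = phi, se = NA_real_, p = p,
                     q = NA_real_, n_cases = 0L, n_controls = 0L,
                     status = ifelse(is.na(p), "skipped", "ok"),
                     stringsAsFactors = FALSE)
  q <- bh_adjust(stub, scope = "global")$q
  out <- data.frame(disease = grid$disease, medication = grid$medication,
                    phi = phi, phi_p = p, phi_q = q,
                    n_assoc_disease = nA, n_assoc_medication = nB,
                    jaccard = jac,
                    eligible = !is.na(q) & q < fdr_alpha &
                      nA >= min_set_size & nB >= min_set_size,
                    stringsAsFactors = FALSE)
  out[order(-out$phi), , drop = FALSE]
}
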