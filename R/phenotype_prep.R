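# Encoding of questionnaire responses into binary phenotype statuses and
# pairwise phi correlation of the resulting status table.
#
# Statuses use the integer coding 1 = positive, 0 = negative, NA = unknown
# throughout the package, matching the on-disk TSV convention.

#' Encode repeated yes/no questionnaire responses into one status
#'
#' A sample is positive for a condition if it answered yes on any
#' questionnaire wave, negative if it answered at least one no and never yes,
#' and unknown if no wave was answered.
#'
#' @param responses Character vector of responses for one sample across
#'   questionnaires, each `"yes"`, `"no"` or missing (`NA` or `"missing"`).
#'   A matrix or data frame (samples in rows) is encoded row-wise.
#' @return Integer status: `1`, `0` or `NA` (one per row for matrix input).
#' @export
#' @examples
#' encode_any_yes(c("no", "yes", NA))  # 1
#' encode_any_yes(c("no", "no"))       # 0
encode_any_yes <- function(responses) {
  if (is.matrix(responses) || is.data.frame(responses)) {
    return(apply(as.matrix(responses), 1L, encode_any_yes))
  }
  r <- tolower(as.character(responses))
  r[r %in% c("missing", "na", "")] <- NA_character_
  bad <- !is.na(r) & !r %in% c("yes", "no")
  if (any(bad)) {
    stop_miwas("unrecognized response level(s): ",
               paste(unique(r[bad]), collapse = ", "))
  }
  if (any(r == "yes", na.rm = TRUE)) return(1L)
  if (any(r == "no", na.rm = TRUE)) return(0L)
  NA_integer_
}

#' Encode an ordinal 0-4 frequency response into a binary status
#'
#' Responses 0-2 (never through sometimes) are scored negative and 3-4
#' (frequently/always) positive; missing stays unknown. Used for symptom
#' frequency items such as constipation and cystitis.
#'
#' @param response Integer vector with values in `0:4` or `NA`.
#' @return Integer status vector (`1`, `0`, `NA`).
#' @export
encode_ordinal_threshold <- function(response) {
  r <- suppressWarnings(as.integer(response))
  if (any(!is.na(response) & is.na(r))) {
    stop_miwas("non-integer ordinal response")
  }
  bad <- !is.na(r) & (r < 0L | r > 4L)
  if (any(bad)) {
    stop_miwas("ordinal response out of range 0-4: ",
               paste(unique(r[bad]), collapse = ", "))
  }
  ifelse(is.na(r), NA_integer_, as.integer(r >= 3L))
}

#' Encode a composite of binary indicator flags into one status
#'
#' Positive if any indicator is true (e.g. doctor diagnosis, self diagnosis
#' or hearing-aid use for hearing loss), negative if all observed indicators
#' are false, unknown if all are missing.
#'
#' @param flags Logical vector (with `NA` for missing) for one sample; a
#'   matrix or data frame is encoded row-wise.
#' @return Integer status (`1`, `0`, `NA`).
#' @export
encode_any_of <- function(flags) {
  if (is.matrix(flags) || is.data.frame(flags)) {
    return(apply(as.matrix(flags), 1L, encode_any_of))
  }
  f <- as.logical(flags)
  if (any(!is.na(flags) & is.na(f))) {
    stop_miwas("indicator flags must be logical (TRUE/FALSE/NA)")
  }
  if (any(f, na.rm = TRUE)) return(1L)
  if (any(!f, na.rm = TRUE)) return(0L)
  NA_integer_
}

#' Retain phenotypes above a prevalence threshold
#'
#' Keeps phenotypes whose positive count relative to a reference cohort size
#' is at least `threshold` (default: the 1 percent common-disease rule).
#' Dropped phenotype names are attached as attribute `"dropped"`.
#'
#' @param table Phenotype data frame: `sample_id` column plus one 1/0/NA
#'   status column per phenotype.
#' @param reference_n Size of the reference cohort the prevalence is judged
#'   against (defaults to the number of rows of `table`).
#' @param threshold Minimum prevalence in (0, 1).
#' @return Filtered phenotype table, with attribute `"dropped"`.
#' @export
prevalence_filter <- function(table, reference_n = nrow(table),
                              threshold = 0.01) {
  stopifnot(is.data.frame(table), "sample_id" %in% names(table))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop_miwas("threshold must lie strictly in (0, 1)")
  }
  if (!is.numeric(reference_n) || reference_n <= 0) {
    stop_miwas("reference_n must be a positive count")
  }
  phen <- setdiff(names(table), "sample_id")
  positives <- vapply(table[phen], function(x) sum(x == 1L, na.rm = TRUE), 0)
  keep <- (positives / reference_n) >= threshold
  out <- table[, c("sample_id", phen[keep]), drop = FALSE]
  attr(out, "dropped") <- phen[!keep]
  out
}

#' Phi coefficient between two binary vectors
#'
#' Pearson correlation specialized to binary variables, computed from the
#' 2x2 contingency table on pairwise-complete observations:
#' \deqn{\phi = (n_{11} n_{00} - n_{10} n_{01}) /
#'   \sqrt{n_{1\cdot} n_{0\cdot} n_{\cdot 1} n_{\cdot 0}}.}
#' The p-value uses the chi-square relation \eqn{n \phi^2 \sim \chi^2_1}
#' (no continuity correction).
#'
#' @param x,y Binary vectors (0/1, `NA` allowed).
#' @return List with `phi`, `p_value` and `n` (pairwise-complete count).
#'   `phi` is `NA` with a warning if either vector is constant after
#'   pairwise deletion.
#' @export
phi_coefficient <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- as.integer(x[ok]); y <- as.integer(y[ok])
  if (any(!x %in% 0:1) || any(!y %in% 0:1)) {
    stop_miwas("phi_coefficient expects 0/1 vectors")
  }
  n <- length(x)
  if (n == 0L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("phi undefined: constant vector after pairwise deletion")
    return(list(phi = NA_real_, p_value = NA_real_, n = n))
  }
  n11 <- as.numeric(sum(x == 1L & y == 1L))
  n10 <- as.numeric(sum(x == 1L & y == 0L))
  n01 <- as.numeric(sum(x == 0L & y == 1L))
  n00 <- as.numeric(sum(x == 0L & y == 0L))
  phi <- (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  p <- stats::pchisq(n * phi^2, df = 1L, lower.tail = FALSE)
  list(phi = phi, p_value = p, n = n)
}

#' Pairwise phi correlation matrix over a phenotype table
#'
#' Computes phi on pairwise-complete samples for every phenotype pair,
#' together with the companion matrices of p-values and pairwise-complete
#' sample counts.
#'
#' @param table Phenotype data frame (`sample_id` plus 1/0/NA columns).
#' @return Object of class `phi_matrix`: list with square symmetric `phi`,
#'   `p` and `n` matrices (diagonal of `phi` is 1).
#' @export
phi_matrix <- function(table) {
  stopifnot(is.data.frame(table), "sample_id" %in% names(table))
  phen <- setdiff(names(table), "sample_id")
  if (length(phen) < 2L) stop_miwas("need at least 2 phenotypes")
  k <- length(phen)
  phi <- p <- matrix(NA_real_, k, k, dimnames = list(phen, phen))
  n <- matrix(0L, k, k, dimnames = list(phen, phen))
  diag(phi) <- 1
  for (i in seq_len(k)) {
    n[i, i] <- sum(!is.na(table[[phen[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      r <- suppressWarnings(phi_coefficient(table[[phen[i]]],
                                            table[[phen[j]]]))
      phi[i, j] <- phi[j, i] <- r$phi
      p[i, j] <- p[j, i] <- r$p_value
      n[i, j] <- n[j, i] <- r$n
    }
  }
  structure(list(phi = phi, p = p, n = n), class = "phi_matrix")
}

#' @export
print.phi_matrix <- function(x, ...) {
  cat("phi_matrix over", ncol(x$phi), "phenotypes;",
      "median |phi| =", signif(stats::median(abs(
        x$phi[upper.tri(x$phi)]), na.rm = TRUE), 3), "\n")
  invisible(x)
}
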