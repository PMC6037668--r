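# Assembly of the initial microbiota trait matrix: taxonomic collapsing of
# a taxon count table, log relative abundances, alpha diversity, and
# principal-coordinate axes of beta-diversity distance matrices.

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Construct a taxon count table
#'
#' @param counts Integer matrix, samples in rows, taxa in columns.
#' @param lineage Character vector (one per taxon) of semicolon-delimited
#'   ranks kingdom;phylum;class;order;family;genus, or a data frame with
#'   those columns. Unassigned ranks may be empty or `NA`.
#' @return Object of class `taxon_counts`: list with `counts` and a
#'   `lineage` data frame.
#' @export
taxon_counts <- function(counts, lineage) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_miwas("counts must be nonnegative")
  if (is.character(lineage)) {
    parts <- strsplit(lineage, ";", fixed = TRUE)
    lineage <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
      p <- trimws(p)
      p[p == ""] <- NA_character_
      length(p) <- length(RANKS)
      p
    })), stringsAsFactors = FALSE)
    names(lineage) <- RANKS
  }
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  if (!all(RANKS %in% names(lineage))) {
    stop_miwas("lineage must provide ranks: ", paste(RANKS, collapse = ", "))
  }
  if (nrow(lineage) != ncol(counts)) {
    stop_miwas("one lineage per taxon required")
  }
  rownames(lineage) <- colnames(counts)
  structure(list(counts = counts, lineage = lineage[RANKS]),
            class = "taxon_counts")
}

#' Collapse taxon counts to a taxonomic level
#'
#' Sums counts across taxa sharing the full lineage prefix through `level`.
#' Taxa lacking a complete assignment at any rank through `level` are
#' excluded (only fully assigned classes/families enter the trait set), so
#' per-sample totals after collapsing may be below the original depth.
#'
#' @param tc A [taxon_counts] object.
#' @param level One of `"class"`, `"family"`, `"genus"`.
#' @return A `taxon_counts` object of collapsed taxa named by their lineage
#'   prefix.
#' @export
collapse_to_level <- function(tc, level) {
  stopifnot(inherits(tc, "taxon_counts"))
  if (!level %in% c("class", "family", "genus")) {
    stop_miwas("unknown rank: ", level)
  }
  upto <- RANKS[seq_len(match(level, RANKS))]
  lin <- tc$lineage[upto]
  complete <- stats::complete.cases(lin)
  if (!any(complete)) stop_miwas("no taxa fully assigned at level ", level)
  key <- apply(lin[complete, , drop = FALSE], 1L, paste, collapse = ";")
  sub <- tc$counts[, complete, drop = FALSE]
  groups <- split(seq_along(key), key)
  collapsed <- vapply(groups, function(ix) rowSums(sub[, ix, drop = FALSE]),
                      numeric(nrow(sub)))
  if (nrow(tc$counts) == 1L) collapsed <- matrix(collapsed, nrow = 1L,
                                                 dimnames = list(rownames(tc$counts), names(groups)))
  newlin <- do.call(rbind, strsplit(colnames(collapsed), ";", fixed = TRUE))
  lineage <- as.data.frame(matrix(NA_character_, ncol(collapsed),
                                  length(RANKS)), stringsAsFactors = FALSE)
  names(lineage) <- RANKS
  lineage[, seq_along(upto)] <- newlin
  taxon_counts(collapsed, lineage)
}

#' Log-transformed relative abundances
#'
#' Converts counts to pseudocount-stabilized relative abundances and takes
#' natural logs: `log((count + pc) / (depth + pc * n_taxa))`. The adjusted
#' relative abundances of each sample sum to one.
#'
#' @param tc A [taxon_counts] object or a plain count matrix (samples x
#'   taxa).
#' @param pseudocount Nonnegative value added to every count (default 0.5).
#' @return Numeric matrix of log relative abundances (samples x taxa).
#' @export
log_relative_abundance <- function(tc, pseudocount = 0.5) {
  m <- if (inherits(tc, "taxon_counts")) tc$counts else as.matrix(tc)
  depth <- rowSums(m)
  if (any(depth <= 0)) {
    bad <- rownames(m)[depth <= 0] %||% which(depth <= 0)
    stop_miwas("zero-depth sample(s): ", paste(bad, collapse = ", "))
  }
  if (pseudocount < 0) stop_miwas("pseudocount must be nonnegative")
  if (pseudocount == 0 && any(m == 0)) {
    stop_miwas("zero counts require a positive pseudocount")
  }
  log((m + pseudocount) / (depth + pseudocount * ncol(m)))
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log_b p_i} over taxa with nonzero counts.
#' Cross-checked in the test suite against `vegan::diversity`.
#'
#' @param counts Nonnegative count vector, or matrix with samples in rows.
#' @param base Logarithm base (default 2, reporting bits).
#' @return Shannon index (one value per sample).
#' @export
shannon_index <- function(counts, base = 2) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    return(apply(as.matrix(counts), 1L, shannon_index, base = base))
  }
  if (any(counts < 0)) stop_miwas("counts must be nonnegative")
  tot <- sum(counts)
  if (tot <= 0) stop_miwas("all-zero count vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Observed richness
#'
#' Number of taxa with a nonzero count (per sample for matrix input).
#'
#' @param counts Nonnegative count vector or samples-x-taxa matrix.
#' @return Integer richness.
#' @export
richness <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    return(apply(as.matrix(counts), 1L, richness))
  }
  if (any(counts < 0)) stop_miwas("counts must be nonnegative")
  sum(counts > 0)
}

#' Principal-coordinate axes of a distance matrix
#'
#' Classical metric scaling: double-center the squared distances,
#' eigendecompose, and return the top `k` coordinate axes ordered by
#' descending eigenvalue. Axes for negative eigenvalues (non-Euclidean
#' distances) are never returned; if fewer than `k` positive eigenvalues
#' exist the remaining axes are zero-filled with a warning.
#'
#' @param distances Square symmetric matrix with zero diagonal (or a
#'   `dist`).
#' @param k Number of axes to return.
#' @return Samples x `k` matrix of coordinates named `PCo1..PCok`, with
#'   eigenvalues in attribute `"eigenvalues"`.
#' @export
pcoa_axes <- function(distances, k = 6L) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d)) stop_miwas("distance matrix must be square")
  if (any(abs(d - t(d)) > 1e-8)) stop_miwas("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop_miwas("distance matrix diagonal must be zero")
  if (any(d < 0)) stop_miwas("distances must be nonnegative")
  if (k < 1L) stop_miwas("k must be at least 1")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d),
                                          k = min(k, n - 1L), eig = TRUE))
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig), 1))) {
    warning("negative eigenvalues (non-Euclidean distances) dropped")
  }
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {
    warning("fewer than ", k, " positive eigenvalues; zero-filling")
    fill <- matrix(0, n, k - if (is.null(pts)) 0L else ncol(pts))
    pts <- cbind(pts, fill)
  }
  pts <- pts[, seq_len(k), drop = FALSE]
  dimnames(pts) <- list(rownames(d), paste0("PCo", seq_len(k)))
  attr(pts, "eigenvalues") <- eig
  pts
}

#' Assemble the initial microbiota trait matrix
#'
#' Union of (i) log relative abundances of fully assigned classes and
#' families, (ii) supplied alpha-diversity columns, and (iii) the first
#' `k_axes` principal-coordinate axes of each beta-diversity distance
#' matrix. Trait metadata (kind per trait) is attached as attribute
#' `"trait_info"`.
#'
#' @param counts A [taxon_counts] object at the finest available level.
#' @param alpha_columns Optional samples x metrics matrix/data frame of
#'   precomputed alpha-diversity values (conventionally Shannon,
#'   phylogenetic diversity and observed richness; a different number is
#'   accepted with a warning).
#' @param distance_matrices Named list of square beta-diversity distance
#'   matrices sharing the sample index.
#' @param k_axes Ordination axes retained per distance matrix (default 6).
#' @param pseudocount Passed to [log_relative_abundance].
#' @return Numeric samples x traits matrix with attribute `"trait_info"`
#'   (data frame: trait, kind).
#' @export
assemble_initial_traits <- function(counts, alpha_columns = NULL,
                                    distance_matrices = list(),
                                    k_axes = 6L, pseudocount = 0.5) {
  stopifnot(inherits(counts, "taxon_counts"))
  samples <- rownames(counts$counts)
  if (is.null(samples)) stop_miwas("count table needs sample row names")
  blocks <- list(); kinds <- character()
  for (lev in c("class", "family")) {
    cc <- collapse_to_level(counts, lev)
    la <- log_relative_abundance(cc, pseudocount = pseudocount)
    colnames(la) <- paste0(lev, ".",
                           vapply(strsplit(colnames(la), ";"), function(p)
                             p[length(p)], ""))
    blocks[[lev]] <- la
    kinds <- c(kinds, rep(paste0("taxon_", lev), ncol(la)))
  }
  if (!is.null(alpha_columns)) {
    a <- as.matrix(alpha_columns)
    if (ncol(a) != 3L) {
      warning("expected 3 alpha-diversity columns, got ", ncol(a))
    }
    if (is.null(colnames(a))) colnames(a) <- paste0("alpha", seq_len(ncol(a)))
    if (!identical(rownames(a), samples)) {
      stop_miwas("alpha columns: sample index mismatch")
    }
    blocks$alpha <- a
    kinds <- c(kinds, rep("alpha", ncol(a)))
  }
  if (length(distance_matrices)) {
    if (is.null(names(distance_matrices))) {
      names(distance_matrices) <- paste0("beta", seq_along(distance_matrices))
    }
    for (nm in names(distance_matrices)) {
      dm <- as.matrix(distance_matrices[[nm]])
      if (!identical(rownames(dm), samples)) {
        stop_miwas("distance matrix '", nm, "': sample index mismatch")
      }
      ax <- pcoa_axes(dm, k = k_axes)
      colnames(ax) <- paste0(nm, ".", colnames(ax))
      blocks[[nm]] <- ax
      kinds <- c(kinds, rep("beta_axis", ncol(ax)))
    }
  }
  m <- do.call(cbind, blocks)
  rownames(m) <- samples
  if (anyDuplicated(colnames(m))) {
    stop_miwas("duplicate trait name(s): ",
               paste(unique(colnames(m)[duplicated(colnames(m))]),
                     collapse = ", "))
  }
  attr(m, "trait_info") <- data.frame(trait = colnames(m), kind = kinds,
                                      stringsAsFactors = FALSE)
  m
}
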