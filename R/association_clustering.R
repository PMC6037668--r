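# Clustering of association profiles: sparsify the beta-coefficient matrix
# at nominal significance, cosine distances, complete-linkage dendrograms,
# and multiscale-bootstrap cluster support (BP and approximately-unbiased
# AU values, after the standard multiscale construction: bootstrap at
# several resampling ratios r, probit-transform the per-scale recovery
# frequencies, fit z(r) = v*sqrt(r) + c/sqrt(r), and read AU off v - c).

#' Sparsified beta-coefficient matrix
#'
#' Builds the traits x phenotypes matrix of logistic slopes from one scan
#' variant, zeroing every coefficient whose association is not nominally
#' significant (`p < alpha`, strict) and dropping traits/phenotypes left
#' with no nonzero entry.
#'
#' @param results An `association_result` data frame from a single scan
#'   variant.
#' @param alpha Nominal significance threshold (default 0.05).
#' @return Numeric traits x phenotypes matrix; dropped row/column names in
#'   attributes `"dropped_traits"` / `"dropped_phenotypes"`.
#' @export
sparsify <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  if (length(unique(results$variant)) > 1L) {
    stop_miwas("sparsify expects results from a single scan variant")
  }
  traits <- unique(results$trait)
  phen <- unique(results$phenotype)
  m <- matrix(0, length(traits), length(phen),
              dimnames = list(traits, phen))
  keep <- results$status == "ok" & !is.na(results$p) & results$p < alpha
  if (any(keep)) {
    m[cbind(match(results$trait[keep], traits),
            match(results$phenotype[keep], phen))] <- results$beta[keep]
  }
  nz_r <- rowSums(m != 0) > 0
  nz_c <- colSums(m != 0) > 0
  if (!any(nz_r) || !any(nz_c)) {
    stop_miwas("no nominally significant associations at alpha = ", alpha,
               "; nothing to cluster")
  }
  out <- m[nz_r, nz_c, drop = FALSE]
  attr(out, "dropped_traits") <- traits[!nz_r]
  attr(out, "dropped_phenotypes") <- phen[!nz_c]
  attr(out, "alpha") <- alpha
  out
}

cosine_dist_impl <- function(v, warn = TRUE) {
  # v: items in rows, profile coordinates in columns
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm == 0
  if (any(zero) && warn) {
    warning("zero-norm profile(s): cosine similarity defined as 0 for ",
            paste(rownames(v)[zero], collapse = ", "))
  }
  nrm[zero] <- 1
  s <- tcrossprod(v / nrm)
  s[zero, ] <- 0; s[, zero] <- 0
  d <- 1 - s
  diag(d) <- 0
  d[d < 0] <- 0  # numerical guard
  d
}

#' Cosine distance between association profiles
#'
#' `d(u, v) = 1 - cos(u, v)`, in `[0, 2]`; chosen because it is little
#' influenced by the sparsity introduced by zeroed non-significant
#' coefficients. Zero-norm profiles get similarity 0 (distance 1) with a
#' warning.
#'
#' @param matrix Numeric matrix (e.g. a [sparsify] result).
#' @param axis `"rows"` to compare row profiles, `"columns"` for columns.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
cosine_distance <- function(matrix, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  v <- if (axis == "rows") as.matrix(matrix) else t(as.matrix(matrix))
  cosine_dist_impl(v)
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering merging by maximum inter-cluster distance
#' (`stats::hclust(method = "complete")`), so merge heights are
#' non-decreasing.
#'
#' @param dist Distance matrix or `dist` object.
#' @return An `hclust` tree.
#' @export
complete_linkage <- function(dist) {
  d <- if (inherits(dist, "dist")) dist else stats::as.dist(as.matrix(dist))
  if (attr(d, "Size") < 2L) stop_miwas("need at least 2 items to cluster")
  stats::hclust(d, method = "complete")
}

#' Arcsine transform of a beta matrix for visualization
#'
#' Increases visual contrast between small nonzero coefficients and exact
#' zeros in heatmaps. Values are scaled by the matrix maximum absolute value
#' first whenever that maximum exceeds 1 (arcsin is only defined on
#' [-1, 1]); sign, zero pattern and ordering are preserved. Visualization
#' only — never feeds the clustering.
#'
#' @param matrix Numeric matrix.
#' @return Transformed matrix.
#' @export
arcsine_viz <- function(matrix) {
  m <- as.matrix(matrix)
  mx <- max(abs(m))
  if (mx == 0) return(m)
  if (mx > 1) m <- m / mx
  asin(m)
}

# Internal node leaf sets of an hclust tree, as sorted-index keys.
hclust_cluster_keys <- function(hc) {
  n <- length(hc$order)
  merge <- hc$merge
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    get_side <- function(v) if (v < 0) -v else sets[[v]]
    sets[[i]] <- sort(c(get_side(merge[i, 1]), get_side(merge[i, 2])))
  }
  vapply(sets, paste, "", collapse = ",")
}

#' Multiscale bootstrap support for association-profile clusters
#'
#' Clusters one axis of the sparsified beta matrix (complete linkage on
#' cosine distances) and assesses each internal cluster's stability by
#' bootstrap resampling of the profile coordinates (the phenotype axis when
#' clustering traits) at several resampling ratios. For each scale `r`,
#' `round(r * n)` coordinates are resampled with replacement `n_boot`
#' times; the bootstrap probability BP of a cluster is the fraction of
#' replicate trees containing exactly its leaf set. The approximately
#' unbiased value is obtained by fitting
#' `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` by weighted least squares
#' over the scales where BP is strictly inside (0, 1) and reading
#' `AU = 1 - pnorm(v - c)`; clusters with `1 - AU < alpha` are flagged
#' significant. When BP is pinned at 0 or 1 at (nearly) every scale the
#' probit fit is uninformative and the support is read off the majority BP
#' (0 or 1) directly; a cluster never recovered at any scale gets AU = 0.
#' With a single scale AU cannot be estimated and only BP is reported.
#'
#' @param matrix Sparse beta matrix (traits x phenotypes).
#' @param axis `"rows"` (cluster traits; default) or `"columns"`.
#' @param n_boot Bootstrap iterations per scale (>= 100).
#' @param scales Resampling ratios spanning values below and above 1.
#' @param seed Integer seed for the resampling.
#' @param alpha Cluster-significance cutoff on the AU-based p-value.
#' @return Object of class `cluster_support_tree`: `hclust`, per-node `bp`
#'   (at the scale closest to 1), `au`, `significant`, the full
#'   `bp_by_scale` matrix, `scales`, `n_boot`, `seed`, and
#'   `n_zero_profiles` (zero-norm profiles met inside resamples).
#' @export
multiscale_bootstrap <- function(matrix, axis = c("rows", "columns"),
                                 n_boot = 1000L,
                                 scales = seq(0.5, 1.4, length.out = 10),
                                 seed = 1L, alpha = 0.05) {
  axis <- match.arg(axis)
  if (n_boot < 100L) stop_miwas("n_boot must be at least 100")
  if (any(scales <= 0)) stop_miwas("scales must be positive")
  v <- if (axis == "rows") as.matrix(matrix) else t(as.matrix(matrix))
  n_items <- nrow(v); n_prof <- ncol(v)
  if (n_items < 3L) stop_miwas("need at least 3 items to assess clusters")
  hc <- complete_linkage(cosine_dist_impl(v))
  keys <- hclust_cluster_keys(hc)
  n_nodes <- length(keys)
  scales <- sort(unique(scales))
  bp <- matrix(0, n_nodes, length(scales),
               dimnames = list(NULL, paste0("r", signif(scales, 3))))
  n_zero <- 0L
  with_seed(seed, {
    for (si in seq_along(scales)) {
      msize <- max(2L, as.integer(round(scales[si] * n_prof)))
      hits <- integer(n_nodes)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n_prof, msize, replace = TRUE)
        vb <- v[, idx, drop = FALSE]
        if (any(rowSums(vb^2) == 0)) n_zero <- n_zero + 1L
        hb <- stats::hclust(stats::as.dist(cosine_dist_impl(vb,
                                                            warn = FALSE)),
                            method = "complete")
        hits <- hits + (keys %in% hclust_cluster_keys(hb))
      }
      bp[, si] <- hits / n_boot
    }
  })
  # BP at the scale nearest 1 stands for the ordinary bootstrap probability
  near1 <- which.min(abs(scales - 1))
  au <- rep(NA_real_, n_nodes)
  never <- rowSums(bp) == 0
  if (length(scales) >= 2L) {
    for (i in seq_len(n_nodes)) {
      if (never[i]) { au[i] <- 0; next }
      bpi <- bp[i, ]
      use <- bpi > 0 & bpi < 1
      if (sum(use) < 2L) {
        # BP pinned at 0/1 (almost) everywhere: the probit fit carries no
        # information, so support is read off the majority BP directly
        au[i] <- as.numeric(mean(bpi) >= 0.5)
        next
      }
      z <- stats::qnorm(1 - bpi[use])
      w <- (n_boot * stats::dnorm(z)^2) / (bpi[use] * (1 - bpi[use]))
      X <- cbind(sqrt(scales[use]), 1 / sqrt(scales[use]))
      fit <- stats::lm.wfit(X, z, w)
      vc <- fit$coefficients
      au[i] <- 1 - stats::pnorm(vc[1] - vc[2])
    }
  } else {
    warning("AU requires at least 2 distinct scales; reporting BP only")
  }
  structure(list(hclust = hc, bp = bp[, near1], au = au,
                 significant = if (all(is.na(au))) rep(NA, n_nodes) else
                   !is.na(au) & (1 - au) < alpha,
                 never_recovered = never,
                 bp_by_scale = bp, scales = scales, n_boot = n_boot,
                 seed = seed, alpha = alpha,
                 n_zero_profiles = n_zero),
            class = "cluster_support_tree")
}

#' @export
print.cluster_support_tree <- function(x, ...) {
  cat("cluster_support_tree:", length(x$hclust$order), "leaves,",
      length(x$bp), "internal nodes, n_boot =", x$n_boot, "per scale (",
      length(x$scales), "scales )\n")
  if (!all(is.na(x$au))) {
    cat("  significant clusters (AU-based p <", x$alpha, "):",
        sum(x$significant, na.rm = TRUE), "\n")
  }
  invisible(x)
}

#' Export a support tree as Newick with AU labels on internal nodes
#'
#' @param tree A [multiscale_bootstrap] result.
#' @param path Output file path.
#' @return Invisibly, the Newick string.
#' @export
write_support_tree <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_support_tree"))
  hc <- tree$hclust
  lab <- hc$labels %||% as.character(seq_along(hc$order))
  au <- tree$au
  build <- function(i) {
    side <- function(v) {
      if (v < 0) lab[-v] else build(v)
    }
    sup <- if (is.na(au[i])) "" else sprintf("%.3f", au[i])
    sprintf("(%s,%s)%s:%g", side(hc$merge[i, 1]), side(hc$merge[i, 2]),
            sup, hc$height[i])
  }
  nwk <- paste0(sub(":[^:]*$", "", build(nrow(hc$merge))), ";")
  writeLines(nwk, path)
  invisible(nwk)
}
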