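# Redundancy-reducing marker selection: Spearman correlation network with a
# hard edge threshold, then greedy degree-based selection so that every
# discarded trait stays correlated with at least one retained marker.

#' Pairwise Spearman correlation matrix over traits
#'
#' Rank-based, computed on pairwise-complete observations; invariant under
#' monotone transforms of any trait. Entries involving constant traits are
#' `NA` (flagged with a warning).
#'
#' @param traits Numeric samples x traits matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(traits) {
  m <- as.matrix(traits)
  if (ncol(m) < 2L) stop_miwas("need at least 2 traits")
  if (nrow(m) < 3L) stop_miwas("need at least 3 samples")
  rho <- suppressWarnings(stats::cor(m, method = "spearman",
                                     use = "pairwise.complete.obs"))
  if (anyNA(rho)) warning("constant trait(s): undefined correlations set NA")
  diag(rho) <- 1
  rho
}

#' Build a trait correlation graph by thresholding
#'
#' Traits are nodes; an undirected edge joins traits i and j when the
#' correlation magnitude strictly exceeds `threshold` (by default the
#' absolute value is used, so strongly negatively correlated traits are
#' treated as redundant too; set `signed = TRUE` to require positive
#' correlation above threshold). Missing correlations yield no edge.
#'
#' @param corr Square symmetric correlation matrix with trait dimnames.
#' @param threshold Edge threshold in (0, 1); strict inequality (default
#'   0.8).
#' @param signed If `TRUE`, use the signed correlation instead of its
#'   absolute value.
#' @return Object of class `trait_corr_graph`: list with logical
#'   `adjacency`, `threshold`, `signed`.
#' @export
threshold_graph <- function(corr, threshold = 0.8, signed = FALSE) {
  m <- as.matrix(corr)
  if (nrow(m) != ncol(m)) stop_miwas("correlation matrix must be square")
  if (threshold <= 0 || threshold >= 1) {
    stop_miwas("threshold must lie strictly in (0, 1)")
  }
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("t", seq_len(nrow(m))),
                        paste0("t", seq_len(nrow(m))))
  }
  if (anyNA(m)) {
    warning("missing correlation entries treated as no edge")
    m[is.na(m)] <- 0
  }
  v <- if (signed) m else abs(m)
  adj <- v > threshold
  diag(adj) <- FALSE
  adj <- adj | t(adj)  # enforce symmetry against asymmetric numeric noise
  structure(list(adjacency = adj, threshold = threshold, signed = signed),
            class = "trait_corr_graph")
}

#' @export
print.trait_corr_graph <- function(x, ...) {
  cat("trait_corr_graph:", nrow(x$adjacency), "traits,",
      sum(x$adjacency) / 2, "edges, |rho| >", x$threshold, "\n")
  invisible(x)
}

graph_degrees <- function(graph) rowSums(graph$adjacency)

#' Greedy degree-based marker selection
#'
#' Iteratively picks the surviving node of highest degree (uniform random
#' tie-break under `seed`) as a marker, removes it together with all of its
#' surviving neighbours, recomputes degrees on the reduced network, and
#' repeats until the network is empty. The result is an independent
#' dominating set of the correlation graph: markers are pairwise
#' non-adjacent and every discarded trait is adjacent to at least one
#' marker.
#'
#' @param graph A [threshold_graph] result.
#' @param seed Integer seed driving tie-breaks only.
#' @param recompute_degrees If `FALSE`, rank nodes by their degree in the
#'   full graph throughout (sensitivity-analysis variant); default `TRUE`
#'   recomputes on the surviving subgraph each iteration.
#' @return Object of class `marker_selection`: `markers` (ordered), a
#'   `covered_by` list mapping each discarded trait to its adjacent
#'   markers, the `seed`, and a per-iteration `selection_log`.
#' @export
greedy_select_markers <- function(graph, seed = 1L,
                                  recompute_degrees = TRUE) {
  stopifnot(inherits(graph, "trait_corr_graph"))
  adj <- graph$adjacency
  nodes <- rownames(adj)
  alive <- rep(TRUE, length(nodes))
  static_deg <- rowSums(adj)
  markers <- character(0)
  log <- list()
  with_seed(seed, {
    it <- 0L
    while (any(alive)) {
      it <- it + 1L
      deg <- if (recompute_degrees) {
        rowSums(adj[, alive, drop = FALSE])[alive]
      } else {
        static_deg[alive]
      }
      cand <- which(deg == max(deg))
      pick <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
      chosen <- which(alive)[pick]
      neigh <- which(adj[chosen, ] & alive)
      markers <- c(markers, nodes[chosen])
      log[[it]] <- data.frame(iteration = it, marker = nodes[chosen],
                              degree = deg[pick],
                              n_removed = length(neigh),
                              stringsAsFactors = FALSE)
      alive[c(chosen, neigh)] <- FALSE
    }
  })
  discarded <- setdiff(nodes, markers)
  covered_by <- lapply(discarded, function(d) {
    nodes[adj[d, ] & nodes %in% markers]
  })
  names(covered_by) <- discarded
  structure(list(markers = markers, covered_by = covered_by, seed = seed,
                 selection_log = do.call(rbind, log)),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat("marker_selection:", length(x$markers), "markers covering",
      length(x$covered_by), "discarded traits (seed", x$seed, ")\n")
  invisible(x)
}

#' Verify the independent-dominating-set property of a marker selection
#'
#' Checks that (i) markers and discarded traits partition the graph nodes,
#' (ii) no two markers are adjacent, and (iii) every discarded trait is
#' adjacent to at least one marker.
#'
#' @param selection A [greedy_select_markers] result.
#' @param graph The graph the selection was produced from.
#' @return List with logical `ok` and a data frame `violations`
#'   (type, node), empty when valid.
#' @export
verify_coverage <- function(selection, graph) {
  stopifnot(inherits(selection, "marker_selection"),
            inherits(graph, "trait_corr_graph"))
  adj <- graph$adjacency
  nodes <- rownames(adj)
  v <- list()
  extra <- setdiff(c(selection$markers, names(selection$covered_by)), nodes)
  missing <- setdiff(nodes, c(selection$markers, names(selection$covered_by)))
  for (nm in extra) v[[length(v) + 1L]] <- c("unknown_node", nm)
  for (nm in missing) v[[length(v) + 1L]] <- c("uncovered_node", nm)
  mk <- intersect(selection$markers, nodes)
  if (length(mk) > 1L) {
    sub <- adj[mk, mk, drop = FALSE]
    bad <- which(sub, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    for (i in seq_len(nrow(bad))) {
      v[[length(v) + 1L]] <- c("adjacent_markers",
                               paste(mk[bad[i, ]], collapse = "|"))
    }
  }
  for (d in setdiff(nodes, mk)) {
    if (!any(adj[d, mk])) v[[length(v) + 1L]] <- c("not_dominated", d)
  }
  violations <- if (length(v)) {
    data.frame(type = vapply(v, `[`, "", 1L),
               node = vapply(v, `[`, "", 2L), stringsAsFactors = FALSE)
  } else {
    data.frame(type = character(0), node = character(0))
  }
  list(ok = nrow(violations) == 0L, violations = violations)
}
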