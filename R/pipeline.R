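# End-to-end orchestration: simulate (optional) -> phenotype prep ->
# marker selection -> scan variants -> association clustering -> overlap,
# writing every intermediate table plus a machine-readable manifest.

pipeline_defaults <- list(
  prevalence_threshold = 0.01,
  edge_threshold = 0.8,
  nominal_alpha = 0.05,
  fdr_alpha = 0.05,
  overlap_min_set_size = 10L,
  fdr_scope = "global",
  variants = SCAN_VARIANTS,
  n_boot = 1000L,
  scales = seq(0.5, 1.4, length.out = 10),
  signed_edges = FALSE
)

#' Read a pipeline run configuration
#'
#' Flat YAML key-value file; unknown keys are kept, missing keys take the
#' package defaults (prevalence threshold 0.01, correlation edge threshold
#' 0.8, nominal alpha 0.05, FDR alpha 0.05, overlap set-size 10, all four
#' scan variants, 1000 bootstrap iterations per scale). `seed` is
#' mandatory.
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_miwas("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  utils::modifyList(pipeline_defaults, cfg)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(pipeline_defaults, config)
  if (is.null(config$seed)) stop_miwas("config must set a seed")
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_miwas("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full association pipeline
#'
#' Executes simulate (when the config has a `simulate` block) or loads the
#' input tables, then phenotype prevalence filtering and phi correlation,
#' Spearman/threshold-graph marker selection, residualized logistic scans
#' in all configured variants with FDR adjustment, association-profile
#' clustering with multiscale-bootstrap support, and (when disease and
#' medication phenotype groups are configured) the disease-medication
#' overlap table. Every intermediate table is written as TSV under
#' `out_dir` together with `manifest.json` (package version, seed, config
#' and its hash) — no timestamps, so identical config + seed reproduce the
#' run byte for byte.
#'
#' @param config Config list or YAML path. Either a `simulate` block
#'   (arguments for [sim_config]) or `phenotype_file` / `trait_file` /
#'   `covariate_file` paths must be present.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- resolve_config(config)
  if (is.null(config$simulate)) {
    need <- c("phenotype_file", "trait_file", "covariate_file")
    miss <- need[!vapply(need, function(k) !is.null(config[[k]]) &&
                           file.exists(config[[k]]), TRUE)]
    if (length(miss)) {
      stop_miwas("missing input file(s) for: ", paste(miss, collapse = ", "))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    fixture <- stage("simulate", {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% derive_seed(config$seed, 10L)
      if (!is.null(sim_args$phenotypes)) {
        sim_args$phenotypes <- unlist(sim_args$phenotypes)
      }
      if (!is.null(sim_args$planted_effects) &&
          !is.data.frame(sim_args$planted_effects)) {
        # YAML configs carry planted effects as a list of records
        sim_args$planted_effects <-
          do.call(rbind, lapply(sim_args$planted_effects, as.data.frame))
      }
      fx <- simulate_cohort(do.call(sim_config, sim_args))
      inp <- file.path(out_dir, "input")
      dir.create(inp, showWarnings = FALSE)
      write_fixture(fx, inp)
      fx
    })
    phenotypes <- fixture$phenotypes
    traits <- fixture$traits
    covariates <- fixture$covariates
  } else {
    phenotypes <- stage("load", read_phenotype_table(config$phenotype_file))
    traits <- stage("load", read_trait_matrix(config$trait_file))
    covariates <- stage("load",
                        read_covariate_table(config$covariate_file))
  }

  phenotypes <- stage("prep", {
    ft <- prevalence_filter(phenotypes, reference_n = nrow(phenotypes),
                            threshold = config$prevalence_threshold)
    write_tsv(ft, file.path(out_dir, "phenotypes_filtered.tsv"))
    if (ncol(ft) > 2L) {
      pm <- phi_matrix(ft)
      write_tsv(data.frame(phenotype = rownames(pm$phi), pm$phi,
                           check.names = FALSE),
                file.path(out_dir, "phenotype_phi.tsv"))
    }
    ft
  })

  selection <- stage("select", {
    rho <- spearman_matrix(traits)
    g <- threshold_graph(rho, threshold = config$edge_threshold,
                         signed = config$signed_edges)
    sel <- greedy_select_markers(g, seed = derive_seed(config$seed, 20L))
    chk <- verify_coverage(sel, g)
    if (!chk$ok) stop_miwas("marker selection violated coverage")
    write_tsv(sel$selection_log, file.path(out_dir, "markers.tsv"))
    cov_map <- data.frame(
      discarded_trait = names(sel$covered_by),
      covering_markers = vapply(sel$covered_by, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    write_tsv(cov_map, file.path(out_dir, "marker_coverage.tsv"))
    ed <- which(g$adjacency & upper.tri(g$adjacency), arr.ind = TRUE)
    write_tsv(data.frame(trait_a = rownames(g$adjacency)[ed[, 1]],
                         trait_b = rownames(g$adjacency)[ed[, 2]]),
              file.path(out_dir, "trait_edges.tsv"))
    sel
  })
  marker_traits <- traits[, selection$markers, drop = FALSE]

  scan <- stage("scan", {
    sc <- run_scan_variants(phenotypes, marker_traits, covariates,
                            variants = config$variants,
                            fdr_scope = config$fdr_scope)
    write_tsv(sc$results, file.path(out_dir, "scan_results.tsv"))
    write_tsv(data.frame(variant = rownames(sc$beta_correlations),
                         sc$beta_correlations, check.names = FALSE),
              file.path(out_dir, "variant_beta_correlations.tsv"))
    sc
  })
  full_res <- scan$results[scan$results$variant == config$variants[1], ,
                           drop = FALSE]

  stage("cluster", {
    sb <- tryCatch(sparsify(full_res, alpha = config$nominal_alpha),
                   error = function(e) NULL)
    if (is.null(sb) || nrow(sb) < 3L) {
      writeLines("too few significant associations to cluster",
                 file.path(out_dir, "cluster_skipped.txt"))
    } else {
      tree <- multiscale_bootstrap(sb, axis = "rows",
                                   n_boot = config$n_boot,
                                   scales = config$scales,
                                   seed = derive_seed(config$seed, 30L),
                                   alpha = config$nominal_alpha)
      write_support_tree(tree, file.path(out_dir, "trait_dendrogram.nwk"))
      ord <- tree$hclust$order
      viz <- arcsine_viz(sb)[ord, , drop = FALSE]
      write_tsv(data.frame(trait = rownames(viz), viz, check.names = FALSE),
                file.path(out_dir, "heatmap_matrix.tsv"))
      supp <- data.frame(node = seq_along(tree$bp), bp = tree$bp,
                         au = tree$au, significant = tree$significant)
      write_tsv(supp, file.path(out_dir, "cluster_support.tsv"))
      write_tsv(data.frame(trait = rownames(sb),
                           cluster2 = stats::cutree(tree$hclust, k = 2)),
                file.path(out_dir, "cluster_membership.tsv"))
    }
    NULL
  })

  if (!is.null(config$disease_phenotypes) &&
      !is.null(config$medication_phenotypes)) {
    stage("overlap", {
      dz <- intersect(unlist(config$disease_phenotypes), names(phenotypes))
      md <- intersect(unlist(config$medication_phenotypes),
                      names(phenotypes))
      ov <- build_overlap_table(
        full_res[full_res$phenotype %in% dz, , drop = FALSE],
        full_res[full_res$phenotype %in% md, , drop = FALSE],
        phenotypes[, c("sample_id", dz), drop = FALSE],
        phenotypes[, c("sample_id", md), drop = FALSE],
        alpha = config$nominal_alpha, fdr_alpha = config$fdr_alpha,
        min_set_size = config$overlap_min_set_size)
      write_tsv(ov, file.path(out_dir, "overlap_table.tsv"))
      write_tsv(ov[ov$eligible, c("disease", "medication", "phi",
                                  "jaccard"), drop = FALSE],
                file.path(out_dir, "phi_vs_jaccard.tsv"))
      NULL
    })
  }

  cfg_str <- paste(deparse(config[order(names(config))]), collapse = "")
  manifest <- list(
    package = "miwas",
    version = as.character(utils::packageVersion("miwas")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(cfg_str),
    config = config[setdiff(names(config), "simulate")],
    stage_seeds = list(simulate = derive_seed(config$seed, 10L),
                       select = derive_seed(config$seed, 20L),
                       cluster = derive_seed(config$seed, 30L))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize a completed run: association counts and cases-vs-counts data
#'
#' Reads the scan results of a run directory and writes (i) per-phenotype
#' counts of nominal and FDR-significant associations split by direction
#' of effect — every scanned phenotype appears, including those with zero
#' associations — and (ii) the cases-versus-association-count scatter
#' table. Regeneration is idempotent.
#'
#' @param run_dir A [run_pipeline] output directory.
#' @param variant Scan variant to summarize (default `"full"`).
#' @param alpha Nominal threshold.
#' @return Invisibly, the association-count data frame.
#' @export
make_report <- function(run_dir, variant = "full", alpha = 0.05) {
  res_path <- file.path(run_dir, "scan_results.tsv")
  missing <- c(if (!file.exists(res_path)) "scan",
               if (!file.exists(file.path(run_dir, "manifest.json")))
                 "manifest")
  if (length(missing)) {
    stop_miwas("incomplete run; missing stage output(s): ",
               paste(missing, collapse = ", "))
  }
  res <- read_tsv(res_path)
  res <- res[res$variant == variant, , drop = FALSE]
  if (nrow(res) == 0L) stop_miwas("no results for variant ", variant)
  counts <- do.call(rbind, lapply(split(res, res$phenotype), function(d) {
    ok <- d$status == "ok" & !is.na(d$p)
    nom <- ok & d$p < alpha
    fdr <- ok & !is.na(d$q) & d$q < alpha
    data.frame(phenotype = d$phenotype[1],
               n_cases = max(d$n_cases),
               nominal_positive = sum(nom & d$beta > 0),
               nominal_negative = sum(nom & d$beta < 0),
               fdr_positive = sum(fdr & d$beta > 0),
               fdr_negative = sum(fdr & d$beta < 0),
               stringsAsFactors = FALSE)
  }))
  counts$nominal_total <- counts$nominal_positive + counts$nominal_negative
  counts$fdr_total <- counts$fdr_positive + counts$fdr_negative
  rownames(counts) <- NULL
  counts <- counts[order(counts$phenotype), , drop = FALSE]
  write_tsv(counts, file.path(run_dir, "association_counts.tsv"))
  write_tsv(counts[, c("phenotype", "n_cases", "nominal_total")],
            file.path(run_dir, "cases_vs_associations.tsv"))
  invisible(counts)
}
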