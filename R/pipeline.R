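#' Default pipeline configuration
#'
#' Nested list of every tunable of the pipeline with its default:
#' co-expression thresholding fraction, the consequence whitelist,
#' specificity mode, solver settings and the enrichment significance
#' level. Values can be overridden by passing a partial list to
#' [run_pipeline()] or by editing the YAML config of the command-line
#' driver.
#'
#' @param ... Named overrides of the form `section.key = value` given as
#'   nested lists, e.g. `solver = list(k1 = 10)`.
#' @return Nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    coexpression = list(keep_fraction = 0.01),
    variants = list(consequence_whitelist = variant_consequences()),
    specificity = list(mode = "all_diseased", min_diseased = 1L),
    solver = list(k1 = 5L, k2 = 2L, max_iter = 500L, rel_tol = 1e-6,
                  seed = 0L, n_restarts = 10L, epsilon = 1e-10,
                  fixed_P = TRUE),
    enrichment = list(alpha = 0.05),
    stability = list(method = "ari")
  )
  overrides <- list(...)
  for (section in names(overrides)) {
    for (key in names(overrides[[section]])) {
      cfg[[section]][[key]] <- overrides[[section]][[key]]
    }
  }
  cfg
}

config_to_solver <- function(cfg) {
  s <- cfg$solver
  sonmtf_config(k1 = s$k1, k2 = s$k2, max_iter = s$max_iter,
                rel_tol = s$rel_tol, seed = s$seed,
                n_restarts = s$n_restarts, epsilon = s$epsilon)
}

#' Write a planted benchmark to disk in the pipeline's file dialects
#'
#' Produces, under `dir`: one unweighted edge-list TSV per network
#' (`<name>_edges.tsv`), the variant matrix (`variant_matrix.tsv`),
#' phenotypes (`phenotypes.tsv`), annotations (`annotations.gmt`) and
#' the planted ground truth (`ground_truth.tsv`).
#'
#' @param spec A [planted_spec()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_inputs <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data <- generate_planted(spec)
  paths <- character()
  for (net in data$networks) {
    a <- net$adjacency
    ut <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    el <- edge_list(rownames(a)[ut[, 1L]], colnames(a)[ut[, 2L]])
    p <- file.path(dir, paste0(tolower(net$name), "_edges.tsv"))
    write_edge_list(el, p)
    paths[[paste0("edges_", net$name)]] <- p
  }
  p <- file.path(dir, "variant_matrix.tsv")
  write_variant_matrix(data$profile, p)
  paths[["variant_matrix"]] <- p
  p <- file.path(dir, "phenotypes.tsv")
  utils::write.table(
    data.frame(subject = data$profile$subjects,
               label = data$profile$phenotypes[data$profile$subjects]),
    p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths[["phenotypes"]] <- p
  p <- file.path(dir, "annotations.gmt")
  write_gmt(data$annotations, p)
  paths[["annotations"]] <- p
  p <- file.path(dir, "ground_truth.tsv")
  utils::write.table(
    data.frame(gene = names(data$assignment),
               cluster = unname(data$assignment)),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths[["ground_truth"]] <- p
  invisible(paths)
}

#' Run the full fusion pipeline on in-memory inputs
#'
#' Fits the phenotype-constrained tri-factorization, extracts hard gene
#' clusters and their union subnetworks, classifies per-gene variant
#' specificity, summarizes it per cluster, and runs annotation
#' enrichment. When `out_dir` is given, the cluster report, factor
#' matrices, enrichment table and a JSON manifest are written there;
#' reruns with the same config and seed reproduce the outputs
#' byte-identically.
#'
#' @param vp A [variant_profile()] aligned to the network universe.
#' @param networks List of [molecular_network()] over the same universe.
#' @param annotations An [annotation_collection()] or a named list of
#'   collections (one per namespace).
#' @param config Configuration from [default_config()].
#' @param out_dir Optional output directory.
#' @return List with `fit`, `clustering`, `subnetworks`, `labels`,
#'   `specificity`, `enrichment`, `quality` and `config`.
#' @export
run_pipeline <- function(vp, networks, annotations,
                         config = default_config(), out_dir = NULL) {
  universe <- networks[[1L]]$genes
  if (!identical(vp$genes, universe)) {
    stop("variant profile and networks use different gene universes; ",
         "align them with align_profile_to_universe()")
  }
  if (config$solver$k1 > length(universe)) {
    stop("solver.k1 exceeds the number of genes")
  }
  solver <- config_to_solver(config)
  p_fix <- NULL
  if (isTRUE(config$solver$fixed_P)) {
    p_fix <- build_fixed_P(vp$phenotypes, subject_order = vp$subjects)
  }
  fit <- sonmtf_fit(vp, networks, solver, fixed_P = p_fix)
  g <- fit$factors$G
  rownames(g) <- universe
  clustering <- extract_clusters(g)
  subnetworks <- lapply(seq_len(clustering$k), function(cl) {
    extract_subnetwork(cluster_members(clustering, cl), networks,
                       cluster_id = cl)
  })
  labels <- classify_gene_specificity(
    vp, mode = config$specificity$mode,
    min_diseased = config$specificity$min_diseased)
  specificity <- summarize_specificity(clustering, labels)
  if (inherits(annotations, "annotation_collection")) {
    annotations <- list(annotations)
  }
  enrichment <- do.call(rbind, lapply(annotations, function(ann) {
    enrich_clusters(clustering, ann, universe,
                    alpha = config$enrichment$alpha)
  }))
  rownames(enrichment) <- NULL
  quality <- cluster_quality(enrichment, clustering$k)
  result <- list(fit = fit, clustering = clustering,
                 subnetworks = subnetworks, labels = labels,
                 specificity = specificity, enrichment = enrichment,
                 quality = quality, config = config)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  metadata <- list(config = result$config,
                   seed = result$config$solver$seed,
                   objective = result$fit$objective,
                   iterations = result$fit$iterations_run,
                   restart_index = result$fit$restart_index,
                   converged = result$fit$converged,
                   cluster_quality = result$quality,
                   objective_trace = result$fit$objective_trace)
  write_cluster_report(result$clustering, result$subnetworks,
                       result$enrichment, result$labels, out_dir,
                       metadata = metadata)
  utils::write.table(result$enrichment,
                     file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("P", "S", "G")) {
    utils::write.table(result$fit$factors[[nm]],
                       file.path(out_dir, paste0("factor_", nm, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(out_dir)
}

#' Load pipeline inputs from files and run the pipeline
#'
#' File-path front end over [run_pipeline()]: reads edge lists
#' (thresholding the weighted co-expression list when given), builds the
#' PPI-anchored universe, aligns the variant matrix, reads phenotypes
#' and GMT annotation files, then runs the pipeline.
#'
#' @param paths Named list: `ppi` (required), optional `coex_weighted`
#'   (weighted TSV) or `coex` (pre-thresholded), optional `gi`,
#'   `variant_matrix` (required), `phenotypes` (required), `gmt` (one
#'   path or a named vector, names used as namespaces).
#' @param config Configuration from [default_config()].
#' @param out_dir Optional output directory.
#' @return As [run_pipeline()].
#' @export
run_pipeline_files <- function(paths, config = default_config(),
                               out_dir = NULL) {
  ppi <- read_edge_list(paths$ppi)
  others <- list()
  if (!is.null(paths$coex_weighted)) {
    coex_w <- read_edge_list(paths$coex_weighted, weighted = TRUE)
    others$COEX <- threshold_coexpression(
      coex_w, config$coexpression$keep_fraction)
  } else if (!is.null(paths$coex)) {
    others$COEX <- read_edge_list(paths$coex)
  }
  if (!is.null(paths$gi)) others$GI <- read_edge_list(paths$gi)
  aligned <- build_universe_and_align(ppi, others)
  phen <- read_phenotypes(paths$phenotypes)
  vp <- read_variant_matrix(paths$variant_matrix, phenotypes = phen)
  vp <- align_profile_to_universe(vp, aligned$universe)
  gmt_paths <- paths$gmt
  nms <- names(gmt_paths)
  if (is.null(nms)) nms <- paste0("annotations", seq_along(gmt_paths))
  annotations <- lapply(seq_along(gmt_paths), function(i) {
    read_gmt(gmt_paths[[i]], namespace = nms[i])
  })
  run_pipeline(vp, aligned$networks, annotations, config = config,
               out_dir = out_dir)
}

#' Subject-pair stability analysis on in-memory inputs
#'
#' @inheritParams run_pipeline
#' @param out_dir Optional directory for `stability.tsv` (pairwise
#'   agreement) and `stability_summary.json`.
#' @return A [stability_report()].
#' @export
run_stability <- function(vp, networks, config = default_config(),
                          out_dir = NULL) {
  solver <- config_to_solver(config)
  runs <- pairwise_subject_runs(vp, networks, solver,
                                fixed_P = isTRUE(config$solver$fixed_P))
  report <- stability_report(runs, method = config$stability$method)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(report$agreement,
                       file.path(out_dir, "stability.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    jsonlite::write_json(
      list(method = report$method,
           n_runs = nrow(report$agreement),
           mean_agreement = report$mean_agreement,
           min_agreement = report$min_agreement),
      file.path(out_dir, "stability_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
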