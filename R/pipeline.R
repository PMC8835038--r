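#' Default pipeline configuration
#'
#' A config is a plain list: a `seed`, either a `scenario` (parameters for
#' [synthetic_scenario()]) or `inputs` (paths to the four tables), the model
#' settings, and optional `gene_sets` (GMT path) for enrichment. Every
#' numeric setting of the method is present and overridable.
#'
#' @param ... overrides of the defaults.
#' @return A config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    scenario = NULL,     # list of synthetic_scenario() arguments, or NULL
    inputs = NULL,       # list(expression=, network=, descriptors=, responses=)
    gene_sets = NULL,
    k_cells = NULL, k_drugs = NULL, k_min = 2, k_max = 15,
    lambda = NULL, spearman_target = NULL,
    folds = 3, trees = 100, min_leaf = 5,
    max_missing = 0.8, min_coverage = 0.5, near_constant_frac = 0.95,
    epsilon = 0, linkage = "average",
    top_n = 200, alpha = 0.05)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    sc <- do.call(synthetic_scenario,
                  c(config$scenario, list(seed = config$seed)))
    study <- simulate_study(sc)
    list(expr = study$expr, network = study$network,
         descriptors = study$descriptors, responses = study$responses,
         truth = study, digests = list())
  } else if (!is.null(config$inputs)) {
    paths <- config$inputs
    need <- c("expression", "network", "descriptors", "responses")
    missing <- setdiff(need, names(paths))
    if (length(missing))
      stopf("config$inputs lacks: %s", paste(missing, collapse = ", "))
    for (p in unlist(paths))
      if (!file.exists(p)) stopf("input file not found: %s", p)
    list(expr = read_expression(paths$expression),
         network = read_edge_list(paths$network),
         descriptors = read_descriptors(paths$descriptors),
         responses = read_responses(paths$responses),
         truth = NULL,
         digests = as.list(tools::md5sum(unlist(paths))))
  } else stopf("config needs either a scenario or input paths")
}

#' Run the full pipeline and write its artifacts
#'
#' Loads (or simulates) the four input tables, fits the clustered model,
#' runs the pooled and CDCN baselines, the per-paired-cluster significance
#' analysis for the best-predicted pair, optional enrichment, and writes
#' every stage output as CSV plus a JSON run manifest. Outputs are a pure
#' function of the config (no timestamps), so rerunning from the manifest
#' reproduces them byte-identically.
#'
#' @param config a [default_config()]-style list.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the `fit`, baselines, and the manifest.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  config <- do.call(default_config, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- load_pipeline_inputs(config)

  fit <- suppressMessages(drugsense(
    inp$expr, inp$network, inp$descriptors, inp$responses,
    k_cells = config$k_cells, k_drugs = config$k_drugs,
    k_range = c(config$k_min, config$k_max),
    lambda = config$lambda, spearman_target = config$spearman_target,
    folds = config$folds, trees = config$trees, min_leaf = config$min_leaf,
    max_missing = config$max_missing, min_coverage = config$min_coverage,
    near_constant_frac = config$near_constant_frac,
    epsilon = config$epsilon, linkage = config$linkage,
    seed = config$seed))

  pooled <- pooled_crossval(fit)
  cdcn_wd <- suppressMessages(cdcn_baseline(fit, "wasserstein"))
  cdcn_pe <- suppressMessages(cdcn_baseline(fit, "pearson"))

  out <- function(f) file.path(outdir, f)
  write_id_matrix(fit$distances$cells, out("cell_distances.csv"), "cell")
  write_id_matrix(fit$distances$drugs, out("drug_distances.csv"), "drug")
  write.csv(data.frame(id = fit$cells$ids, cluster = fit$cells$labels),
            out("cell_clusters.csv"), row.names = FALSE)
  write.csv(data.frame(id = fit$drugs$ids, cluster = fit$drugs$labels),
            out("drug_clusters.csv"), row.names = FALSE)

  preds <- do.call(rbind, lapply(names(fit$cv), function(key) {
    z <- fit$cv[[key]]
    data.frame(pair = key, cell = z$pairs$cell, drug = z$pairs$drug,
               fold = z$fold, observed = as.numeric(z$observed),
               predicted = as.numeric(z$predictions),
               stringsAsFactors = FALSE)
  }))
  write.csv(preds, out("predictions.csv"), row.names = FALSE)

  sm <- summary(fit)
  ev <- rbind(
    data.frame(model = "rf_clustered", pair = sm$pairs$pair, n = sm$pairs$n,
               r = sm$pairs$r, r2 = sm$pairs$r2, stringsAsFactors = FALSE),
    data.frame(model = "rf_clustered", pair = "concatenated",
               n = fit$evaluation$n, r = fit$evaluation$r,
               r2 = fit$evaluation$r2, stringsAsFactors = FALSE),
    data.frame(model = "rf_pooled", pair = "all",
               n = pooled$evaluation$n, r = pooled$evaluation$r,
               r2 = pooled$evaluation$r2, stringsAsFactors = FALSE),
    data.frame(model = "cdcn_wasserstein", pair = "concatenated",
               n = cdcn_wd$overall$n, r = cdcn_wd$overall$r,
               r2 = cdcn_wd$overall$r2, stringsAsFactors = FALSE),
    data.frame(model = "cdcn_pearson", pair = "concatenated",
               n = cdcn_pe$overall$n, r = cdcn_pe$overall$r,
               r2 = cdcn_pe$overall$r2, stringsAsFactors = FALSE))
  write.csv(ev, out("evaluation.csv"), row.names = FALSE)

  significance <- run_significance(fit, config)
  if (!is.null(significance))
    write.csv(significance$table, out("significance.csv"), row.names = FALSE)

  enrichment <- NULL
  if (!is.null(config$gene_sets) && !is.null(significance) &&
      nrow(significance$significant)) {
    sets <- read_gene_sets(config$gene_sets)
    enrichment <- hypergeom_enrich(significance$significant$gene, sets,
                                   universe = fit$network$nodes)
    write.csv(enrichment, out("enrichment.csv"), row.names = FALSE)
  }

  manifest <- list(
    package = "drugsense",
    version = as.character(utils::packageVersion("drugsense")),
    config = config,
    input_digests = inp$digests,
    counts = list(
      cell_lines = length(fit$cells$ids), drugs = length(fit$drugs$ids),
      genes = length(fit$network$nodes),
      descriptors_lcc = length(fit$drug_network$nodes),
      k_cells = fit$cells$k, k_drugs = fit$drugs$k,
      paired_clusters = length(fit$cv), skipped = length(fit$skipped),
      pairs = fit$evaluation$n))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(fit = fit, pooled = pooled, cdcn_wasserstein = cdcn_wd,
                 cdcn_pearson = cdcn_pe, significance = significance,
                 enrichment = enrichment, manifest = manifest))
}

run_significance <- function(fit, config) {
  sm <- summary(fit)
  best <- sm$pairs[which.max(sm$pairs$r2), ]
  key <- best$pair
  z <- fit$cv[[key]]
  cm <- fit$cells$ids[fit$cells$labels == z$cell_cluster]
  dm <- fit$drugs$ids[fit$drugs$labels == z$drug_cluster]
  groups <- tryCatch(response_groups(fit$tables$responses, cm, dm),
                     error = function(e) NULL)
  if (is.null(groups)) return(NULL)
  design <- assemble_design(cm, dm, fit$tables$expr, fit$tables$descriptors,
                            fit$tables$responses)
  ranked <- importance_rank(design, trees = fit$settings$trees,
                            min_leaf = fit$settings$min_leaf,
                            seed = fit$settings$seed)
  sig <- select_significant(ranked, fit$tables$expr, groups,
                            top_n = config$top_n, alpha = config$alpha)
  sig$pair <- key
  sig
}

#' Rerun a pipeline from its manifest
#'
#' Reads the JSON manifest written by [run_pipeline()] and executes the run
#' again with the identical configuration; with identical inputs the outputs
#' are byte-identical.
#'
#' @param manifest_path path to `manifest.json`.
#' @param outdir output directory for the rerun.
#' @return As [run_pipeline()].
#' @export
rerun_pipeline <- function(manifest_path, outdir) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- manifest$config
  # jsonlite round-trips scalar lists; normalize empties back to NULL
  for (nm in names(cfg)) if (length(cfg[[nm]]) == 0) cfg[nm] <- list(NULL)
  if (!is.null(cfg$scenario)) cfg$scenario <- as.list(cfg$scenario)
  if (!is.null(cfg$inputs)) cfg$inputs <- as.list(cfg$inputs)
  run_pipeline(cfg, outdir)
}
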