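#' Identify spatially variable genes in one call
#'
#' The drop-in entry point: builds the spatial neighbor graph, scores every
#' gene by Moran's I and Geary's C in one pass, and selects SVGs by the
#' requested method.
#'
#' @param dataset a \code{\link{spatial_dataset}}.
#' @param n top genes per statistic (default 2000).
#' @param k spatial neighbors per spot (default 30).
#' @param method \code{"ensemble"}, \code{"moran"} or \code{"geary"}.
#' @param normalize library-size normalize + log1p before scoring (default
#'   TRUE; set FALSE to score the stored values as-is).
#' @return An \code{svg_selection}; the full score table is in
#'   \code{$table} and the per-gene statistics can be recomputed with
#'   \code{\link{compute_autocorrelation}}.
#' @examples
#' sim <- generate_spatial_dataset(synthetic_spec(
#'   grid_shape = c(12, 12), n_spatial_genes = 10, n_noise_genes = 50,
#'   sparsity_target = 0.6))
#' sel <- identify_svgs(sim$dataset, n = 10, k = 8)
#' head(sel$selected_gene_ids)
#' @export
identify_svgs <- function(dataset, n = 2000L, k = 30L,
                          method = c("ensemble", "moran", "geary"),
                          normalize = TRUE) {
  method <- match.arg(method)
  ds <- if (normalize) normalize_expression(dataset) else dataset
  graph <- build_spatial_neighbor_graph(ds, k = k)
  res <- compute_autocorrelation(ds, graph)
  select_svgs(res, n = n, method = method)
}

#' Build a pipeline run configuration
#'
#' Collects every tunable of \code{\link{run_pipeline}} with validated
#' defaults. The configuration round-trips losslessly through JSON
#' (\code{jsonlite}), and every run writes its resolved configuration to the
#' run log so results are reproducible from the log alone.
#'
#' @param input path to the input dataset (h5ad file or MTX directory).
#' @param out_dir output directory.
#' @param format input format (\code{"auto"}, \code{"h5ad"},
#'   \code{"mtx_dir"}).
#' @param k_neighbors spatial-graph neighbor count (default 30).
#' @param n_svgs top genes per statistic (default 2000).
#' @param method selection method (default \code{"ensemble"}).
#' @param normalize normalize before scoring (default TRUE).
#' @param n_components embedding dimensionality (default 50).
#' @param cluster_method \code{"louvain"} or \code{"leiden"}.
#' @param scenario \code{"default"}, \code{"target_k"} or \code{"all"}.
#' @param map_k MAP neighborhood size (default 30).
#' @param resolution_range resolution search interval (default
#'   \code{c(0, 3)}).
#' @param seed global seed (default 0).
#' @param verbose print INFO-level progress (default TRUE).
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(input, out_dir, format = "auto", k_neighbors = 30L,
                       n_svgs = 2000L, method = "ensemble", normalize = TRUE,
                       n_components = 50L, cluster_method = "louvain",
                       scenario = "all", map_k = 30L,
                       resolution_range = c(0, 3), seed = 0L,
                       verbose = TRUE) {
  format <- match.arg(format, c("auto", "h5ad", "mtx_dir"))
  method <- match.arg(method, c("ensemble", "moran", "geary"))
  cluster_method <- match.arg(cluster_method, c("louvain", "leiden"))
  scenario <- match.arg(scenario, c("all", "default", "target_k"))
  for (p in c(k_neighbors = k_neighbors, n_svgs = n_svgs,
              n_components = n_components, map_k = map_k))
    if (p < 1) stop("all numeric parameters must be positive")
  structure(
    list(input = input, out_dir = out_dir, format = format,
         k_neighbors = as.integer(k_neighbors), n_svgs = as.integer(n_svgs),
         method = method, normalize = isTRUE(normalize),
         n_components = as.integer(n_components),
         cluster_method = cluster_method, scenario = scenario,
         map_k = as.integer(map_k),
         resolution_range = as.numeric(resolution_range),
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

pipeline_info <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf(paste0("[svgene] ", fmt), ...))
}

#' Run the full pipeline and write its outputs
#'
#' Loads the dataset, builds the spatial graph, scores and selects SVGs,
#' and (when the dataset carries domain labels) runs the evaluation
#' benchmark. Outputs written to \code{out_dir}:
#' \code{scores.tsv} (per-gene statistics), \code{selection.tsv} (ranks and
#' selection flags), \code{metrics.json} (when labels are present), and
#' \code{run_log.json} (resolved configuration, package versions, dataset
#' and graph summaries). Any stage failure removes partial outputs and
#' re-raises with the stage name.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with the selection, the metrics report (or
#'   NULL), and the output file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(cfg$out_dir,
                       c("scores.tsv", "selection.tsv", "metrics.json",
                         "run_log.json"))
  names(outputs) <- c("scores", "selection", "metrics", "log")
  stage <- "load"
  report <- NULL
  res <- tryCatch({
    dataset <- load_dataset(cfg$input, cfg$format)
    pipeline_info(cfg, "loaded %d spots x %d genes from %s",
                  nrow(dataset$expression), ncol(dataset$expression),
                  cfg$input)
    ds <- if (cfg$normalize) normalize_expression(dataset) else dataset

    stage <- "neighbor_graph"
    graph <- build_spatial_neighbor_graph(ds, k = cfg$k_neighbors)
    pipeline_info(cfg, "graph: k = %d, mean positive out-degree %.2f",
                  graph$k, sum(graph$weights@x > 0) / nrow(graph$weights))

    stage <- "autocorrelation"
    scores <- compute_autocorrelation(ds, graph)
    pipeline_info(cfg, "scored %d genes (%d invalid)",
                  nrow(scores), sum(!scores$valid))
    write_scores_tsv(scores, outputs[["scores"]])

    stage <- "selection"
    selection <- select_svgs(scores, n = cfg$n_svgs, method = cfg$method)
    pipeline_info(cfg, "selected %d SVGs (method %s)",
                  length(selection$selected_gene_ids), cfg$method)
    write_selection_tsv(selection, outputs[["selection"]])

    if (!is.null(dataset$domain_labels)) {
      stage <- "benchmark"
      scen <- if (cfg$scenario == "all") c("default", "target_k")
              else cfg$scenario
      report <- benchmark_selection(
        dataset, selection, scenarios = scen, methods = cfg$cluster_method,
        n_components = cfg$n_components, map_k = cfg$map_k, seed = cfg$seed)
      write_metrics_json(report, outputs[["metrics"]])
    }

    stage <- "log"
    jsonlite::write_json(
      list(config = unclass(cfg),
           versions = list(
             svgene = as.character(utils::packageVersion("svgene")),
             R = paste(R.version$major, R.version$minor, sep = ".")),
           dataset = list(n_spots = nrow(dataset$expression),
                          n_genes = ncol(dataset$expression),
                          has_labels = !is.null(dataset$domain_labels)),
           graph = list(k = graph$k, total_weight = graph$total_weight),
           n_invalid_genes = sum(!scores$valid),
           n_selected = length(selection$selected_gene_ids)),
      outputs[["log"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(selection = selection, report = report, outputs = outputs)
  }, error = function(e) {
    unlink(outputs[file.exists(outputs)])
    stop(sprintf("pipeline failed at stage `%s`: %s",
                 stage, conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
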