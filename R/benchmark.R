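#' Run the full quantitative evaluation of an SVG selection
#'
#' Embeds the dataset on the selected genes
#' (\code{\link{preprocess_and_embed}}), clusters the embedding under the
#' requested scenarios and methods, and scores everything against the
#' dataset's ground-truth domain labels:
#' \itemize{
#'   \item clustering scenarios: \code{"default"} (resolution 1.0) and
#'     \code{"target_k"} (resolution tuned by binary search toward the
#'     number of ground-truth domains), each with Louvain and Leiden — four
#'     AMI/ARI/homogeneity/NMI quadruples;
#'   \item domain resolution: \code{\link{mean_average_precision}} (K = 30);
#'   \item latent-representation quality: \code{\link{mcva}} (5-fold RBF-SVM)
#'     and \code{\link{ilisi}} (perplexity 30), giving its median- and
#'     mean-based summaries.
#' }
#' With both scenarios that is 20 metric values; wall-clock time is recorded
#' separately in the metadata since it is hardware-dependent.
#'
#' @param dataset a \code{spatial_dataset} with \code{domain_labels}.
#' @param selection an \code{svg_selection} (or character vector of genes).
#' @param scenarios subset of \code{c("default", "target_k")}.
#' @param methods subset of \code{c("louvain", "leiden")}.
#' @param n_components,map_k,mcva_folds,perplexity metric parameters.
#' @param seed global seed driving embedding, fold splits and clustering.
#' @return An object of class \code{metrics_report}: list with
#'   \code{clustering} (data.frame: scenario, method, resolution,
#'   n_clusters, ami, ari, homogeneity, nmi), scalar \code{map},
#'   \code{mcva}, \code{ilisi_median}, \code{ilisi_mean}, and
#'   \code{metadata}.
#' @export
benchmark_selection <- function(dataset, selection,
                                scenarios = c("default", "target_k"),
                                methods = c("louvain", "leiden"),
                                n_components = 50L, map_k = 30L,
                                mcva_folds = 5L, perplexity = 30,
                                seed = 0L) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  if (is.null(dataset$domain_labels))
    stop(paste("domain labels are required for AMI/ARI/homogeneity/NMI,",
               "MAP, MCVA and iLISI; the dataset has none"))
  scenarios <- match.arg(scenarios, c("default", "target_k"), several.ok = TRUE)
  methods <- match.arg(methods, c("louvain", "leiden"), several.ok = TRUE)
  truth <- dataset$domain_labels
  t0 <- proc.time()[["elapsed"]]

  emb <- preprocess_and_embed(dataset, selection,
                              n_components = n_components, seed = seed)
  rows <- list()
  for (sc in scenarios) {
    for (m in methods) {
      asg <- if (sc == "default")
        cluster_spots(emb, m, resolution = 1.0, seed = seed)
      else
        cluster_with_target_k(emb, m, target_k = nlevels(truth), seed = seed)
      cm <- clustering_metrics(truth, asg$labels)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, method = m, resolution = asg$resolution,
        n_clusters = asg$n_clusters, ami = cm[["ami"]], ari = cm[["ari"]],
        homogeneity = cm[["homogeneity"]], nmi = cm[["nmi"]],
        stringsAsFactors = FALSE)
    }
  }
  clustering <- do.call(rbind, rows)
  map <- mean_average_precision(emb, truth, K = min(map_k, nrow(emb$matrix) - 1L))
  mcva_score <- mcva(emb, truth, n_folds = mcva_folds, seed = seed)
  il <- ilisi(emb, truth, perplexity = perplexity)

  n_svgs <- if (inherits(selection, "svg_selection"))
    length(selection$selected_gene_ids) else length(selection)
  structure(
    list(clustering = clustering, map = map, mcva = mcva_score,
         ilisi_median = il$ilisi_median, ilisi_mean = il$ilisi_mean,
         metadata = list(
           n_spots = nrow(dataset$expression), n_svgs = n_svgs,
           selection_method = if (inherits(selection, "svg_selection"))
             selection$method else "custom",
           n_components = emb$provenance$n_components,
           map_k = map_k, mcva_folds = mcva_folds, perplexity = perplexity,
           seed = seed,
           elapsed_seconds = proc.time()[["elapsed"]] - t0)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (%d spots, %d SVGs, method %s)\n",
              x$metadata$n_spots, x$metadata$n_svgs,
              x$metadata$selection_method))
  print(x$clustering, row.names = FALSE, digits = 4)
  cat(sprintf("  MAP = %.4f  MCVA = %.4f  iLISI_md = %.4f  iLISI_m = %.4f\n",
              x$map, x$mcva, x$ilisi_median, x$ilisi_mean))
  invisible(x)
}

#' Serialize a metrics report as JSON
#'
#' @param report a \code{metrics_report}.
#' @param path output file path.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(
    list(clustering = report$clustering, map = report$map,
         mcva = report$mcva, ilisi_median = report$ilisi_median,
         ilisi_mean = report$ilisi_mean, metadata = report$metadata),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
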