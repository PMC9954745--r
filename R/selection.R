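#' Rank genes by a spatial autocorrelation statistic
#'
#' Valid genes in descending score order; invalid (zero-variance) genes are
#' excluded entirely. Score ties are broken by input gene order (stable
#' sort), so rankings are reproducible.
#'
#' @param result an \code{autocorr_result} from
#'   \code{\link{compute_autocorrelation}}.
#' @param statistic \code{"moran"} (Moran's I) or \code{"geary_rescaled"}
#'   (C* = 1 - C).
#' @return Character vector of gene ids, best first.
#' @export
rank_genes <- function(result, statistic = c("moran", "geary_rescaled")) {
  stopifnot(inherits(result, "autocorr_result"))
  statistic <- match.arg(statistic)
  if (!any(result$valid))
    stop("no valid genes to rank (all have zero variance)")
  score <- switch(statistic,
                  moran = result$moran_i,
                  geary_rescaled = result$geary_c_rescaled)
  keep <- which(result$valid)
  ord <- keep[order(-score[keep], keep)]
  result$gene_id[ord]
}

#' Select spatially variable genes
#'
#' The single-statistic variants take the top \code{n} genes by Moran's I
#' (\code{method = "moran"}) or by rescaled Geary's C (\code{method =
#' "geary"}). The default ensemble takes the union of those two top-n sets,
#' integrating global (Moran) and local (Geary) spatial autocorrelation; its
#' size is between n and 2n depending on the rankings' overlap.
#'
#' The union is ordered by each gene's best rank across the two rankings
#' (ties by input gene order) purely so output is deterministic; downstream
#' steps use the selection as a set.
#'
#' @param result an \code{autocorr_result}.
#' @param n number of top genes per statistic (default 2000, the convention
#'   for spatial transcriptomics feature selection). If \code{n} exceeds the
#'   number of valid genes, all valid genes are selected with a warning.
#' @param method \code{"ensemble"}, \code{"moran"} or \code{"geary"}.
#' @return An object of class \code{svg_selection}: list with
#'   \code{method}, \code{n_requested}, \code{selected_gene_ids} (ordered),
#'   and \code{table}, a data.frame over all valid genes with columns
#'   \code{gene_id}, \code{moran_i}, \code{geary_c_rescaled},
#'   \code{moran_rank}, \code{geary_rank}, \code{selected_by}
#'   (\code{"moran"}, \code{"geary"}, \code{"both"} or \code{""}) and
#'   \code{selected}.
#' @export
select_svgs <- function(result, n = 2000L,
                        method = c("ensemble", "moran", "geary")) {
  stopifnot(inherits(result, "autocorr_result"))
  method <- match.arg(method)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be a positive integer")

  rank_m <- rank_genes(result, "moran")
  rank_g <- rank_genes(result, "geary_rescaled")
  n_valid <- length(rank_m)
  if (n > n_valid) {
    warning(sprintf("n = %d exceeds the %d valid genes; selecting all valid",
                    n, n_valid))
  }
  neff <- min(n, n_valid)
  top_m <- rank_m[seq_len(neff)]
  top_g <- rank_g[seq_len(neff)]

  # per-gene positions in each full ranking, indexed by gene id
  pos_m <- stats::setNames(seq_len(n_valid), rank_m)
  pos_g <- stats::setNames(seq_len(n_valid), rank_g)

  selected <- switch(
    method,
    moran = top_m,
    geary = top_g,
    ensemble = {
      u <- union(top_m, top_g)
      best <- pmin(pos_m[u], pos_g[u])
      input_pos <- match(u, result$gene_id)
      u[order(best, input_pos)]
    })

  valid_ids <- result$gene_id[result$valid]
  tab <- data.frame(
    gene_id = valid_ids,
    moran_i = result$moran_i[result$valid],
    geary_c_rescaled = result$geary_c_rescaled[result$valid],
    moran_rank = as.integer(pos_m[valid_ids]),
    geary_rank = as.integer(pos_g[valid_ids]),
    stringsAsFactors = FALSE
  )
  in_m <- tab$gene_id %in% top_m
  in_g <- tab$gene_id %in% top_g
  tab$selected_by <- ifelse(in_m & in_g, "both",
                            ifelse(in_m, "moran", ifelse(in_g, "geary", "")))
  tab$selected <- tab$gene_id %in% selected

  structure(
    list(method = method, n_requested = n, selected_gene_ids = selected,
         table = tab),
    class = "svg_selection"
  )
}

#' @export
print.svg_selection <- function(x, ...) {
  cat(sprintf("svg_selection: method = %s, n = %d, selected %d genes\n",
              x$method, x$n_requested, length(x$selected_gene_ids)))
  invisible(x)
}

#' Record a selection in the dataset's gene annotations
#'
#' Writes a logical \code{selected} column (plus the rank columns) into
#' \code{dataset$gene_data} so downstream stages can subset without
#' re-ranking.
#'
#' @param dataset a \code{spatial_dataset}.
#' @param selection an \code{svg_selection} computed on it.
#' @return The dataset with updated \code{gene_data}.
#' @export
annotate_selection <- function(dataset, selection) {
  stopifnot(inherits(dataset, "spatial_dataset"),
            inherits(selection, "svg_selection"))
  gd <- dataset$gene_data
  if (is.null(gd)) gd <- data.frame(row.names = seq_along(dataset$gene_ids))
  m <- match(dataset$gene_ids, selection$table$gene_id)
  gd$selected <- dataset$gene_ids %in% selection$selected_gene_ids
  gd$moran_rank <- selection$table$moran_rank[m]
  gd$geary_rank <- selection$table$geary_rank[m]
  dataset$gene_data <- gd
  dataset
}

#' Write a selection table as TSV
#'
#' Columns: gene_id, moran_rank, geary_rank, selected_by, selected.
#'
#' @param selection an \code{svg_selection}.
#' @param path output file path.
#' @export
write_selection_tsv <- function(selection, path) {
  stopifnot(inherits(selection, "svg_selection"))
  utils::write.table(
    selection$table[, c("gene_id", "moran_rank", "geary_rank",
                        "selected_by", "selected")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
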