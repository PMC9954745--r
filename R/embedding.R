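#' Normalize, subset to SVGs, and embed by principal components
#'
#' The standard characterization pipeline applied downstream of SVG
#' selection: library-size normalize each spot to the median total, log1p,
#' subset to the selected genes, standardize each gene (unit variance,
#' zero mean; genes constant after subsetting are dropped with a warning),
#' and keep the top \code{n_components} principal components.
#'
#' PCA uses the exact \code{stats::prcomp} decomposition when the problem is
#' small and the implicitly-restarted Lanczos solver (\pkg{irlba}) otherwise;
#' the solver's random initialization is seeded, so results are reproducible.
#'
#' @param dataset a \code{spatial_dataset} of raw counts (or already
#'   normalized values with \code{normalize = FALSE}).
#' @param selection an \code{svg_selection}, or a character vector of gene
#'   ids.
#' @param n_components latent dimensionality d (default 50, capped at
#'   \code{min(n_spots, n_genes_selected) - 1}).
#' @param normalize,log1p,scale. toggles for the individual preprocessing
#'   steps; all \code{TRUE} by default.
#' @param seed integer seed for the randomized PCA solver.
#' @return An object of class \code{spot_embedding}: list with
#'   \code{matrix} (n_spots x d), \code{sdev} (component standard
#'   deviations), and \code{provenance}.
#' @export
preprocess_and_embed <- function(dataset, selection, n_components = 50L,
                                 normalize = TRUE, log1p = TRUE,
                                 scale. = TRUE, seed = 0L) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  genes <- if (inherits(selection, "svg_selection"))
    selection$selected_gene_ids else as.character(selection)
  if (length(genes) == 0L) stop("empty gene selection")
  missing <- setdiff(genes, dataset$gene_ids)
  if (length(missing))
    stop(sprintf("selection contains %d gene(s) absent from the dataset",
                 length(missing)))

  ds <- dataset
  if (normalize) {
    X <- ds$expression
    sz <- Matrix::rowSums(X)
    fac <- ifelse(sz > 0, stats::median(sz) / sz, 0)
    X <- if (inherits(X, "sparseMatrix"))
      to_dgc(Matrix::Diagonal(x = fac) %*% X)
    else X * fac
    dimnames(X) <- dimnames(ds$expression)
    ds$expression <- X
  }
  M <- as.matrix(ds$expression[, genes, drop = FALSE])
  if (log1p) M <- log1p(M)

  if (scale.) {
    sds <- apply(M, 2L, stats::sd)
    const <- sds == 0
    if (any(const)) {
      warning(sprintf("dropping %d gene(s) constant after preprocessing",
                      sum(const)))
      M <- M[, !const, drop = FALSE]
      if (ncol(M) == 0L) stop("no non-constant genes left to embed")
    }
    M <- scale(M)
  }

  d <- min(as.integer(n_components), min(dim(M)) - 1L)
  if (d < 1L) stop("n_components must allow at least one component")
  n <- nrow(M)
  if (min(dim(M)) <= 100L || d > 0.5 * min(dim(M))) {
    p <- stats::prcomp(M, center = TRUE, rank. = d)
    emb <- p$x[, seq_len(d), drop = FALSE]
    sdev <- p$sdev[seq_len(d)]
  } else {
    set.seed(seed)
    p <- irlba::prcomp_irlba(M, n = d, center = TRUE, scale. = FALSE)
    emb <- p$x
    sdev <- p$sdev
  }
  rownames(emb) <- dataset$spot_ids
  colnames(emb) <- paste0("PC", seq_len(ncol(emb)))
  structure(
    list(matrix = emb, sdev = sdev,
         provenance = list(n_genes = ncol(M), n_components = ncol(emb),
                           normalize = normalize, log1p = log1p,
                           scale = scale., seed = seed)),
    class = "spot_embedding"
  )
}

#' @export
print.spot_embedding <- function(x, ...) {
  cat(sprintf("spot_embedding: %d spots x %d components\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# kNN graph over embedding rows as an undirected igraph (edge i~j when j is
# among i's nearest neighbors), used by both clustering entry points.
embedding_knn_graph <- function(emb, n_neighbors = 15L) {
  n <- nrow(emb)
  k <- min(n_neighbors, n - 1L)
  nn <- knn_exact(emb, k)
  el <- cbind(rep(seq_len(n), k), as.vector(nn$index))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Cluster spots by community detection on an embedding kNN graph
#'
#' Builds a k-nearest-neighbor graph over the embedding (default 15
#' neighbors) and partitions it by Louvain or Leiden community detection
#' (modularity objective) at the given resolution. Results are seeded and
#' reproducible.
#'
#' @param embedding a \code{spot_embedding} (or a plain numeric matrix).
#' @param method \code{"louvain"} or \code{"leiden"}.
#' @param resolution resolution parameter (default 1.0).
#' @param n_neighbors kNN graph degree (default 15).
#' @param seed integer seed for the community detection heuristic.
#' @return An object of class \code{cluster_assignment}: list with
#'   \code{labels} (0-based integers), \code{method}, \code{resolution},
#'   \code{n_clusters}.
#' @export
cluster_spots <- function(embedding, method = c("louvain", "leiden"),
                          resolution = 1.0, n_neighbors = 15L, seed = 0L) {
  method <- match.arg(method)
  emb <- if (inherits(embedding, "spot_embedding")) embedding$matrix
         else as.matrix(embedding)
  if (resolution <= 0) resolution <- 1e-8
  n <- nrow(emb)
  if (all(abs(sweep(emb, 2L, emb[1L, ])) < 1e-12)) {
    warning("degenerate embedding (all spots identical); returning one cluster")
    return(structure(list(labels = rep(0L, n), method = method,
                          resolution = resolution, n_clusters = 1L),
                     class = "cluster_assignment"))
  }
  g <- embedding_knn_graph(emb, n_neighbors)
  set.seed(seed)
  comm <- switch(method,
    louvain = igraph::cluster_louvain(g, resolution = resolution),
    leiden = igraph::cluster_leiden(g, objective_function = "modularity",
                                    resolution = resolution,
                                    n_iterations = 5L))
  mem <- igraph::membership(comm)
  # relabel by first occurrence so labels are 0..n_clusters-1, reproducibly
  labels <- as.integer(factor(mem, levels = unique(mem))) - 1L
  structure(
    list(labels = labels, method = method, resolution = resolution,
         n_clusters = length(unique(labels))),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %s, resolution %.4g, %d clusters, %d spots\n",
              x$method, x$resolution, x$n_clusters, length(x$labels)))
  invisible(x)
}

#' Tune the clustering resolution toward a target number of clusters
#'
#' Binary search on the resolution parameter within \code{search_range}: the
#' midpoint is evaluated, and the search recurses into the half bracketing
#' the target cluster count, stopping at an exact hit or after
#' \code{max_iter} evaluations. Cluster count is not perfectly monotone in
#' resolution, so the best assignment seen anywhere during the search is
#' tracked throughout; if no resolution yields the target exactly, the
#' assignment with the closest cluster count is returned (ties resolved
#' toward the lower resolution).
#'
#' @inheritParams cluster_spots
#' @param target_k desired number of clusters (typically the number of
#'   ground-truth spatial domains).
#' @param search_range numeric length-2 resolution interval (default
#'   \code{c(0, 3)}).
#' @param max_iter maximum clustering evaluations (default 50).
#' @return A \code{cluster_assignment} (with the resolution that produced it).
#' @export
cluster_with_target_k <- function(embedding, method = c("louvain", "leiden"),
                                  target_k, search_range = c(0, 3),
                                  max_iter = 50L, n_neighbors = 15L,
                                  seed = 0L) {
  method <- match.arg(method)
  target_k <- as.integer(target_k)
  if (is.na(target_k) || target_k < 1L) stop("target_k must be >= 1")
  lo <- search_range[1]; hi <- search_range[2]
  if (!(is.finite(lo) && is.finite(hi) && lo < hi))
    stop("search_range must be a finite increasing interval")

  best <- NULL
  best_gap <- Inf
  evals <- 0L
  try_res <- function(r) {
    evals <<- evals + 1L
    a <- cluster_spots(embedding, method, resolution = r,
                       n_neighbors = n_neighbors, seed = seed)
    gap <- abs(a$n_clusters - target_k)
    if (gap < best_gap || (gap == best_gap && r < best$resolution)) {
      best <<- a
      best_gap <<- gap
    }
    a
  }

  a_lo <- try_res(lo)
  if (best_gap == 0L) return(best)
  a_hi <- try_res(hi)
  k_lo <- a_lo$n_clusters; k_hi <- a_hi$n_clusters
  while (best_gap > 0L && evals < max_iter && (hi - lo) > 1e-6) {
    mid <- (lo + hi) / 2
    a_mid <- try_res(mid)
    if (best_gap == 0L) break
    if (a_mid$n_clusters < target_k) {
      lo <- mid; k_lo <- a_mid$n_clusters
    } else {
      hi <- mid; k_hi <- a_mid$n_clusters
    }
  }
  if (best_gap > 0L)
    warning(sprintf(
      "target_k = %d not reached exactly; returning closest (%d clusters at resolution %.4g)",
      target_k, best$n_clusters, best$resolution))
  best
}

#' Write cluster labels as TSV
#'
#' @param assignment a \code{cluster_assignment}.
#' @param spot_ids spot identifiers (same order as the labels).
#' @param path output file path.
#' @export
write_labels_tsv <- function(assignment, spot_ids, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  utils::write.table(
    data.frame(spot_id = spot_ids, label = assignment$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
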