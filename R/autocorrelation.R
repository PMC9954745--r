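# Shared kernel: given a centered value matrix chunk Xc (n x g dense) and the
# graph, return the cross term t(xc) W xc per gene (shared by both
# statistics), the squared-difference sum per gene, and the variance sum.
# Computing W %*% Xc once is what makes Moran's I and Geary's C come out of a
# single pass over the graph.
autocorr_kernel <- function(Xc, W, wr, wc) {
  WX <- as.matrix(W %*% Xc)
  cross <- colSums(Xc * WX)                       # sum_ij wij (xi-xbar)(xj-xbar)
  sqdiff <- colSums((wr + wc) * Xc^2) - 2 * cross # sum_ij wij (xi-xj)^2
  ss <- colSums(Xc^2)                             # sum_i (xi-xbar)^2
  list(cross = cross, sqdiff = sqdiff, ss = ss)
}

#' Moran's I for one gene
#'
#' Global spatial autocorrelation of a value vector over the spatial neighbor
#' graph:
#' \deqn{I = \frac{N}{W} \frac{\sum_i \sum_j w_{ij}(x_i-\bar x)(x_j-\bar x)}
#'                            {\sum_i (x_i-\bar x)^2}}
#' Values near 1 indicate organized (clustered) spatial patterns, near 0
#' random scatter, near -1 alternating (chess-board) patterns. A
#' zero-variance vector (or a graph with zero total weight) has no defined
#' score and returns \code{NA} rather than raising an error.
#'
#' @param values numeric vector, one value per spot.
#' @param graph a \code{\link{build_spatial_neighbor_graph}} result (or
#'   \code{\link{as_neighbor_graph}}).
#' @return Moran's I, or \code{NA_real_} when invalid.
#' @export
moran_i <- function(values, graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  W <- graph$weights
  n <- nrow(W)
  if (length(values) != n)
    stop(sprintf("values has length %d but graph has %d spots",
                 length(values), n))
  if (graph$total_weight == 0 || min(values) == max(values)) return(NA_real_)
  xc <- values - mean(values)
  (n / graph$total_weight) * sum(xc * as.vector(W %*% xc)) / sum(xc^2)
}

#' Geary's C (and rescaled C*) for one gene
#'
#' \deqn{C = \frac{(N-1)\sum_i \sum_j w_{ij}(x_i-x_j)^2}
#'                {2W\sum_i (x_i-\bar x)^2}}
#' C is non-negative; values below 1 indicate positive spatial
#' autocorrelation. To align its direction with Moran's I it is rescaled to
#' \eqn{C^* = 1 - C}, so that \eqn{C^*} near 1 means strong positive spatial
#' autocorrelation, near 0 none, and negative values negative
#' autocorrelation.
#'
#' @inheritParams moran_i
#' @return Named numeric vector \code{c(C = ..., C_star = ...)}, both
#'   \code{NA} when the gene has zero variance or the graph zero weight.
#' @export
geary_c <- function(values, graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  W <- graph$weights
  n <- nrow(W)
  if (length(values) != n)
    stop(sprintf("values has length %d but graph has %d spots",
                 length(values), n))
  if (graph$total_weight == 0 || min(values) == max(values))
    return(c(C = NA_real_, C_star = NA_real_))
  xc <- values - mean(values)
  wr <- Matrix::rowSums(W)
  wcs <- Matrix::colSums(W)
  sqdiff <- sum((wr + wcs) * xc^2) - 2 * sum(xc * as.vector(W %*% xc))
  C <- (n - 1) * sqdiff / (2 * graph$total_weight * sum(xc^2))
  c(C = C, C_star = 1 - C)
}

#' Per-gene Moran's I and Geary's C in one pass
#'
#' Computes both spatial autocorrelation statistics for every gene of the
#' dataset over the given spatial neighbor graph. The statistics share their
#' expensive intermediates (the sparse matrix-vector products and centered
#' values), so both cost barely more than one. Genes are processed in chunks;
#' results are independent of chunk size and of gene order.
#'
#' Genes with zero variance across spots (detected by an exact min == max
#' comparison) have no defined score: they are flagged \code{valid = FALSE}
#' and carry \code{NA} scores, and downstream ranking excludes them.
#'
#' Scores are computed on the expression values exactly as stored in the
#' dataset; apply \code{\link{normalize_expression}} first if scoring on
#' normalized values is wanted (the \code{\link{run_pipeline}} default).
#'
#' @param dataset a \code{\link{spatial_dataset}}.
#' @param graph a \code{neighbor_graph} over the same spots.
#' @param chunk_size genes per dense chunk (memory/speed trade-off only).
#' @return An object of class \code{autocorr_result}: a data.frame with
#'   columns \code{gene_id}, \code{moran_i}, \code{geary_c},
#'   \code{geary_c_rescaled}, \code{valid}.
#' @export
compute_autocorrelation <- function(dataset, graph, chunk_size = 512L) {
  stopifnot(inherits(dataset, "spatial_dataset"),
            inherits(graph, "neighbor_graph"))
  X <- dataset$expression
  n <- nrow(X)
  if (nrow(graph$weights) != n)
    stop(sprintf("dataset has %d spots but graph has %d",
                 n, nrow(graph$weights)))
  g <- ncol(X)
  W <- graph$weights
  Wtot <- graph$total_weight
  wr <- Matrix::rowSums(W)
  wc <- Matrix::colSums(W)

  moran <- geary <- rep(NA_real_, g)
  valid <- logical(g)
  for (start in seq(1L, g, by = chunk_size)) {
    cols <- start:min(start + chunk_size - 1L, g)
    Xd <- as.matrix(X[, cols, drop = FALSE])
    ok <- apply(Xd, 2L, function(v) min(v) != max(v))
    Xc <- sweep(Xd, 2L, colMeans(Xd))
    kr <- autocorr_kernel(Xc, W, wr, wc)
    m <- (n / Wtot) * kr$cross / kr$ss
    cc <- (n - 1) * kr$sqdiff / (2 * Wtot * kr$ss)
    if (Wtot == 0) ok[] <- FALSE
    moran[cols][ok] <- m[ok]
    geary[cols][ok] <- cc[ok]
    valid[cols] <- ok
  }
  structure(
    data.frame(gene_id = dataset$gene_ids, moran_i = moran, geary_c = geary,
               geary_c_rescaled = 1 - geary, valid = valid,
               stringsAsFactors = FALSE),
    class = c("autocorr_result", "data.frame")
  )
}

#' Write autocorrelation scores as TSV
#'
#' @param result an \code{autocorr_result}.
#' @param path output file path.
#' @export
write_scores_tsv <- function(result, path) {
  stopifnot(inherits(result, "autocorr_result"))
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
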