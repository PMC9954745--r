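#' Build the spatial neighbor graph (SNG)
#'
#' For each spot, finds its \code{k} Euclidean-nearest other spots and assigns
#' the distance-decay edge weight
#' \deqn{w_{ij} = 1 - D_{ij} / \max(D_{i\cdot})}
#' where \eqn{\max(D_{i\cdot})} is the largest of spot i's k neighbor
#' distances. The graph is directed as constructed (no symmetrization, no
#' row-standardization) and stored sparsely: at most \code{k * n} entries, so
#' memory is O(n) rather than O(n^2).
#'
#' Consequences of the weight formula, followed as stated rather than
#' "fixed": the k-th (farthest) neighbor of every spot always receives weight
#' exactly 0, so each row carries at most k-1 positive weights; a row whose k
#' neighbor distances are all equal collapses to an all-zero weight row (a
#' warning is emitted). Duplicate coordinates are allowed: a coincident
#' neighbor is at distance 0 and gets weight 1. Distance ties at the k-th
#' rank are broken by ascending spot index so construction is deterministic,
#' including on regular grids.
#'
#' @param dataset a \code{\link{spatial_dataset}} (only coordinates are used).
#' @param k number of nearest neighbors per spot. Default 30, sized so the
#'   effective positive neighborhood suits Visium-scale data. Values above
#'   \code{n_spots - 1} are clamped with a warning.
#' @return An object of class \code{neighbor_graph}: list with
#'   \code{weights} (n x n \code{dgCMatrix}, row i = out-edges of spot i),
#'   \code{k}, and \code{total_weight} (the scalar W, the sum of all weights).
#' @examples
#' ds <- spatial_dataset(matrix(1, 4, 2), cbind(0:3, 0))
#' g <- build_spatial_neighbor_graph(ds, k = 2)
#' g$weights[1, ]  # neighbor at distance 1 has weight 0.5, at 2 has weight 0
#' @export
build_spatial_neighbor_graph <- function(dataset, k = 30L) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  coords <- dataset$coordinates
  n <- nrow(coords)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a positive integer")
  if (k > n - 1L) {
    warning(sprintf("k = %d exceeds n_spots - 1 = %d; clamping", k, n - 1L))
    k <- n - 1L
  }
  nn <- knn_exact(coords, k)
  dmax <- nn$dist[, k]
  w <- 1 - nn$dist / dmax          # rows with dmax == 0 become NaN
  degenerate <- dmax == 0
  if (any(degenerate)) w[degenerate, ] <- 0
  # rows whose k distances are all equal (dmax > 0) are forced to all-zero
  allzero <- rowSums(w) == 0
  if (any(allzero))
    warning(sprintf(
      "%d spot(s) have equidistant neighbor sets; their weight rows are all zero",
      sum(allzero)))
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = as.vector(nn$index), x = as.vector(w),
    dims = c(n, n)
  )
  structure(
    list(weights = W, k = k, total_weight = sum(w)),
    class = "neighbor_graph"
  )
}

#' Wrap an arbitrary sparse weight matrix as a neighbor graph
#'
#' Mainly for tests and for scoring with externally defined weights (e.g. a
#' binary adjacency matrix). The diagonal must be zero.
#'
#' @param weights square matrix (dense or sparse) of non-negative weights.
#' @param k nominal neighbor count recorded in the object.
#' @return A \code{neighbor_graph}.
#' @export
as_neighbor_graph <- function(weights, k = NA_integer_) {
  W <- to_dgc(Matrix::Matrix(weights, sparse = TRUE))
  if (nrow(W) != ncol(W)) stop("weights must be square")
  if (any(Matrix::diag(W) != 0)) stop("diagonal weights must be zero")
  structure(
    list(weights = W, k = as.integer(k), total_weight = sum(W@x)),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  n <- nrow(x$weights)
  pos <- sum(x$weights@x > 0)
  cat(sprintf(
    "neighbor_graph: %d spots, k = %s, %d stored edges (%d positive), W = %.4f\n",
    n, x$k, length(x$weights@x), pos, x$total_weight))
  cat(sprintf("  mean positive out-degree: %.2f\n", pos / n))
  invisible(x)
}
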