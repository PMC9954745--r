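#' Assemble a spatial transcriptomics dataset
#'
#' The universal input container for the package: a spots x genes expression
#' matrix together with 2-D spot coordinates, identifiers, and (optionally)
#' per-spot ground-truth spatial-domain labels used by the evaluation
#' functions.
#'
#' Dense input matrices with more than 50\% zeros are converted to sparse
#' (\code{dgCMatrix}) storage; sparse inputs are kept sparse.
#'
#' @param expression spots x genes matrix of non-negative finite values
#'   (raw counts or normalized). Base matrices and \pkg{Matrix} sparse
#'   matrices are both accepted.
#' @param coordinates spots x 2 numeric matrix of spatial coordinates, in the
#'   same length unit on both axes.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   \code{colnames(expression)}).
#' @param spot_ids character vector of unique spot identifiers (defaults to
#'   \code{rownames(expression)}, else \code{"spot_1"...}).
#' @param domain_labels optional per-spot labels (factor or vector) naming
#'   the ground-truth spatial domain of each spot.
#' @param gene_data optional data.frame of per-gene annotations with
#'   \code{nrow == n_genes} (e.g. planted-gene flags from the simulator).
#'
#' @return An object of class \code{spatial_dataset}: a list with elements
#'   \code{expression}, \code{coordinates}, \code{gene_ids}, \code{spot_ids},
#'   \code{domain_labels}, \code{gene_data}.
#' @examples
#' X <- matrix(rpois(60, 1), nrow = 6)
#' xy <- cbind(rep(1:3, 2), rep(1:2, each = 3))
#' ds <- spatial_dataset(X, xy)
#' dim(ds)
#' @export
spatial_dataset <- function(expression, coordinates,
                            gene_ids = colnames(expression),
                            spot_ids = rownames(expression),
                            domain_labels = NULL,
                            gene_data = NULL) {
  if (is.data.frame(coordinates)) coordinates <- as.matrix(coordinates)
  if (!is.matrix(coordinates) || ncol(coordinates) != 2L)
    stop("`coordinates` must be a spots x 2 matrix")
  storage.mode(coordinates) <- "double"
  n <- nrow(coordinates)
  if (n < 2L) stop("a spatial dataset needs at least 2 spots")
  if (nrow(expression) != n)
    stop(sprintf("expression has %d rows but coordinates has %d",
                 nrow(expression), n))
  if (any(!is.finite(coordinates))) stop("non-finite values in coordinates")

  if (inherits(expression, "sparseMatrix")) {
    expression <- to_dgc(expression)
    if (any(!is.finite(expression@x))) stop("non-finite values in expression")
  } else {
    expression <- as.matrix(expression)
    storage.mode(expression) <- "double"
    if (any(!is.finite(expression))) stop("non-finite values in expression")
    if (mean(expression == 0) > 0.5)
      expression <- to_dgc(expression)
  }
  vals <- if (inherits(expression, "sparseMatrix")) expression@x else expression
  if (length(vals) && min(vals) < 0)
    stop("expression values must be non-negative")

  g <- ncol(expression)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(g))
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != g) stop("gene_ids length does not match gene count")
  if (length(spot_ids) != n) stop("spot_ids length does not match spot count")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique")

  if (!is.null(domain_labels)) {
    if (length(domain_labels) != n)
      stop("domain_labels length does not match spot count")
    domain_labels <- as.factor(domain_labels)
  }
  if (!is.null(gene_data)) {
    gene_data <- as.data.frame(gene_data)
    if (nrow(gene_data) != g) stop("gene_data must have one row per gene")
  }

  dimnames(expression) <- list(spot_ids, gene_ids)
  dimnames(coordinates) <- list(spot_ids, c("x", "y"))
  structure(
    list(expression = expression, coordinates = coordinates,
         gene_ids = gene_ids, spot_ids = spot_ids,
         domain_labels = domain_labels, gene_data = gene_data),
    class = "spatial_dataset"
  )
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expression)

#' @export
print.spatial_dataset <- function(x, ...) {
  d <- dim(x)
  sp <- if (inherits(x$expression, "sparseMatrix"))
    sprintf("sparse, %.1f%% zeros",
            100 * (1 - length(x$expression@x) / prod(d)))
  else "dense"
  cat(sprintf("spatial_dataset: %d spots x %d genes (%s)\n", d[1], d[2], sp))
  if (!is.null(x$domain_labels))
    cat(sprintf("  domain labels: %d domains\n", nlevels(x$domain_labels)))
  invisible(x)
}

#' Library-size normalize and log-transform expression
#'
#' Scales each spot's counts so its total equals the median spot total, then
#' applies \code{log1p}. This is the default preprocessing applied before
#' autocorrelation scoring and embedding.
#'
#' @param dataset a \code{\link{spatial_dataset}}.
#' @return A \code{spatial_dataset} with the transformed expression matrix.
#' @export
normalize_expression <- function(dataset) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  X <- dataset$expression
  sz <- Matrix::rowSums(X)
  target <- stats::median(sz)
  fac <- ifelse(sz > 0, target / sz, 0)
  if (inherits(X, "sparseMatrix")) {
    Xn <- Matrix::Diagonal(x = fac) %*% X
    Xn <- to_dgc(Xn)
    Xn@x <- log1p(Xn@x)
  } else {
    Xn <- log1p(X * fac)
  }
  out <- dataset
  out$expression <- Xn
  dimnames(out$expression) <- list(dataset$spot_ids, dataset$gene_ids)
  out
}

# Coerce any matrix to general sparse column-compressed form.
to_dgc <- function(x) {
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"),
              "dMatrix")
}

# Exact k-nearest-neighbor search, blocked so that at most `block` x n
# distances are held at once (never a full n x n matrix). Ties in distance
# are broken by ascending index so results are reproducible on regular grids.
# Returns list(index = n x k integer, dist = n x k double), self excluded.
knn_exact <- function(X, k, block = 1024L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1L || k > n - 1L) stop("k must be in [1, n_spots - 1]")
  rn <- rowSums(X^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D2 <- outer(rn[rows], rn, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    D2[D2 < 0] <- 0
    for (r in seq_along(rows)) {
      i <- rows[r]
      d <- D2[r, ]
      d[i] <- Inf
      o <- order(d, seq_len(n))[seq_len(k)]
      idx[i, ] <- o
      dst[i, ] <- sqrt(d[o])
    }
  }
  list(index = idx, dist = dst)
}
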