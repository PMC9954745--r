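#' Read a spatial dataset from disk
#'
#' Two on-disk forms are supported:
#' \itemize{
#'   \item \code{"h5ad"}: an annotated-matrix HDF5 container with the
#'     expression matrix in \code{X} (dense, CSR or CSC), spot/gene ids as
#'     the \code{obs}/\code{var} index, and spot coordinates in
#'     \code{obsm/spatial} (the conventional slot). A \code{domain} column
#'     in \code{obs} (or the column named by \code{label_col}) is read as
#'     ground-truth labels.
#'   \item \code{"mtx_dir"}: a directory with \code{matrix.mtx} (spots x
#'     genes MatrixMarket), \code{genes.tsv} (one gene id per line),
#'     \code{coordinates.tsv} (header \code{spot_id}, \code{x}, \code{y} -
#'     exactly two coordinate columns), and optionally \code{labels.tsv}
#'     (header \code{spot_id}, \code{label}).
#' }
#'
#' @param path file (h5ad) or directory (mtx_dir) path.
#' @param format \code{"auto"} (by extension), \code{"h5ad"} or
#'   \code{"mtx_dir"}.
#' @param label_col obs column holding domain labels (h5ad only); default
#'   \code{"domain"} when present.
#' @return A \code{\link{spatial_dataset}}; ids are preserved verbatim and
#'   the matrix is kept sparse.
#' @export
load_dataset <- function(path, format = c("auto", "h5ad", "mtx_dir"),
                         label_col = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx_dir" else "h5ad"
  if (format == "h5ad") read_h5ad(path, label_col = label_col)
  else read_mtx_dir(path)
}

read_mtx_dir <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("directory not found: %s", dir))
  need <- file.path(dir, c("matrix.mtx", "genes.tsv", "coordinates.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stop(sprintf("missing file(s) in MTX directory: %s",
                 paste(basename(miss), collapse = ", ")))
  X <- to_dgc(Matrix::readMM(need[1]))
  genes <- readLines(need[2])
  co <- utils::read.delim(need[3], stringsAsFactors = FALSE)
  if (ncol(co) != 3L)
    stop(sprintf(
      "coordinates.tsv must have exactly columns spot_id, x, y; found %d columns",
      ncol(co)))
  if (nrow(co) != nrow(X))
    stop(sprintf("matrix has %d spots but coordinates.tsv has %d rows",
                 nrow(X), nrow(co)))
  if (length(genes) != ncol(X))
    stop(sprintf("matrix has %d genes but genes.tsv has %d lines",
                 ncol(X), length(genes)))
  labels <- NULL
  lf <- file.path(dir, "labels.tsv")
  if (file.exists(lf)) {
    lab <- utils::read.delim(lf, stringsAsFactors = FALSE)
    labels <- lab[[2]][match(co[[1]], lab[[1]])]
  }
  spatial_dataset(X, as.matrix(co[, 2:3]), gene_ids = genes,
                  spot_ids = as.character(co[[1]]), domain_labels = labels)
}

#' Write a spatial dataset as an MTX directory
#'
#' @param dataset a \code{spatial_dataset}.
#' @param dir output directory (created if absent).
#' @export
write_mtx_dir <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- dataset$expression
  if (!inherits(X, "sparseMatrix")) X <- Matrix::Matrix(X, sparse = TRUE)
  Matrix::writeMM(X, file.path(dir, "matrix.mtx"))
  writeLines(dataset$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(
    data.frame(spot_id = dataset$spot_ids,
               x = dataset$coordinates[, 1], y = dataset$coordinates[, 2]),
    file.path(dir, "coordinates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$domain_labels))
    utils::write.table(
      data.frame(spot_id = dataset$spot_ids,
                 label = as.character(dataset$domain_labels)),
      file.path(dir, "labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

h5_write_attr <- function(file, name, attr, value, scalar = TRUE) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE)
  rhdf5::h5writeAttribute(value, oid, attr, variableLengthString = TRUE,
                          asScalar = scalar && length(value) == 1L)
}

#' Write a spatial dataset as h5ad
#'
#' Writes a minimal annotated-matrix HDF5 container readable by standard
#' Python tooling: sparse expression as a CSR \code{X} group, ids in
#' \code{obs}/\code{var}, coordinates in \code{obsm/spatial}, and domain
#' labels (if present) as a string column \code{obs/domain}.
#'
#' @param dataset a \code{spatial_dataset}.
#' @param path output .h5ad file path (overwritten).
#' @export
write_h5ad <- function(dataset, path) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  if (file.exists(path)) unlink(path)
  X <- dataset$expression
  if (!inherits(X, "sparseMatrix")) X <- Matrix::Matrix(X, sparse = TRUE)
  tx <- to_dgc(Matrix::t(X))
  n <- nrow(X); g <- ncol(X)

  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "X")
  rhdf5::h5write(tx@x, path, "X/data")
  rhdf5::h5write(tx@i, path, "X/indices")
  rhdf5::h5write(tx@p, path, "X/indptr")
  h5_write_attr(path, "X", "encoding-type", "csr_matrix")
  h5_write_attr(path, "X", "encoding-version", "0.1.0")
  h5_write_attr(path, "X", "shape", c(n, g))

  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(dataset$spot_ids, path, "obs/spot_id")
  cols <- character(0)
  if (!is.null(dataset$domain_labels)) {
    rhdf5::h5write(as.character(dataset$domain_labels), path, "obs/domain")
    h5_write_attr(path, "obs/domain", "encoding-type", "string-array")
    h5_write_attr(path, "obs/domain", "encoding-version", "0.2.0")
    cols <- "domain"
  }
  h5_write_attr(path, "obs", "encoding-type", "dataframe")
  h5_write_attr(path, "obs", "encoding-version", "0.2.0")
  h5_write_attr(path, "obs", "_index", "spot_id")
  h5_write_attr(path, "obs", "column-order", cols, scalar = FALSE)
  h5_write_attr(path, "obs/spot_id", "encoding-type", "string-array")
  h5_write_attr(path, "obs/spot_id", "encoding-version", "0.2.0")

  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(dataset$gene_ids, path, "var/gene_id")
  vcols <- character(0)
  if (!is.null(dataset$gene_data)) {
    for (cn in colnames(dataset$gene_data)) {
      v <- dataset$gene_data[[cn]]
      if (is.logical(v)) v <- as.integer(v)
      if (is.factor(v)) v <- as.character(v)
      rhdf5::h5write(v, path, paste0("var/", cn))
      h5_write_attr(path, paste0("var/", cn), "encoding-type",
                    if (is.character(v)) "string-array" else "array")
      h5_write_attr(path, paste0("var/", cn), "encoding-version", "0.2.0")
      vcols <- c(vcols, cn)
    }
  }
  h5_write_attr(path, "var", "encoding-type", "dataframe")
  h5_write_attr(path, "var", "encoding-version", "0.2.0")
  h5_write_attr(path, "var", "_index", "gene_id")
  h5_write_attr(path, "var", "column-order", vcols, scalar = FALSE)
  h5_write_attr(path, "var/gene_id", "encoding-type", "string-array")
  h5_write_attr(path, "var/gene_id", "encoding-version", "0.2.0")

  rhdf5::h5createGroup(path, "obsm")
  # transpose so the dataset is (n_spots, 2) in the file's C-order layout
  rhdf5::h5write(t(unname(dataset$coordinates)), path, "obsm/spatial")
  h5_write_attr(path, "obsm", "encoding-type", "dict")
  h5_write_attr(path, "obsm", "encoding-version", "0.1.0")
  h5_write_attr(path, "obsm/spatial", "encoding-type", "array")
  h5_write_attr(path, "obsm/spatial", "encoding-version", "0.2.0")
  h5_write_attr(path, "/", "encoding-type", "anndata")
  h5_write_attr(path, "/", "encoding-version", "0.1.0")
  rhdf5::h5closeAll()
  invisible(path)
}

h5_attr <- function(path, name, attr) {
  at <- tryCatch(rhdf5::h5readAttributes(path, name), error = function(e) list())
  at[[attr]]
}

#' Read a spatial dataset from h5ad
#'
#' @param path .h5ad file path.
#' @param label_col obs column holding domain labels; default picks
#'   \code{"domain"} when present.
#' @return A \code{\link{spatial_dataset}}.
#' @export
read_h5ad <- function(path, label_col = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ls <- rhdf5::h5ls(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  paths <- file.path(ls$group, ls$name)
  paths <- sub("^//", "/", paths)

  obs_index <- h5_attr(path, "obs", "_index")
  if (is.null(obs_index)) obs_index <- "_index"
  var_index <- h5_attr(path, "var", "_index")
  if (is.null(var_index)) var_index <- "_index"
  spot_ids <- as.character(rhdf5::h5read(path, paste0("obs/", obs_index)))
  gene_ids <- as.character(rhdf5::h5read(path, paste0("var/", var_index)))
  n <- length(spot_ids); g <- length(gene_ids)

  enc <- h5_attr(path, "X", "encoding-type")
  if (!is.null(enc) && grepl("sr_matrix$", enc)) {
    dat <- as.numeric(rhdf5::h5read(path, "X/data"))
    idx <- as.integer(rhdf5::h5read(path, "X/indices"))
    ptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    X <- if (enc == "csr_matrix") {
      Matrix::t(methods::new("dgCMatrix", x = dat, i = idx, p = ptr,
                             Dim = c(g, n)))
    } else {
      methods::new("dgCMatrix", x = dat, i = idx, p = ptr, Dim = c(n, g))
    }
    X <- to_dgc(X)
  } else {
    A <- rhdf5::h5read(path, "X")
    X <- if (all(dim(A) == c(g, n))) t(A) else A
  }

  if (!"/obsm/spatial" %in% paths)
    stop("no spot coordinates: expected an `obsm/spatial` array in the h5ad file")
  co <- rhdf5::h5read(path, "obsm/spatial")
  if (nrow(co) == 2L && ncol(co) == n) co <- t(co)
  if (nrow(co) != n)
    stop(sprintf("obsm/spatial has %d rows but obs has %d spots", nrow(co), n))

  labels <- NULL
  if (is.null(label_col) && "/obs/domain" %in% paths) label_col <- "domain"
  if (!is.null(label_col)) {
    lp <- paste0("/obs/", label_col)
    if (!lp %in% paths)
      stop(sprintf("label column `%s` not found in obs", label_col))
    lab <- rhdf5::h5read(path, lp)
    # anndata categoricals are a group of codes + categories
    labels <- if (is.list(lab))
      as.character(lab$categories)[as.integer(lab$codes) + 1L]
    else as.character(lab)
  }
  spatial_dataset(X, as.matrix(co)[, 1:2], gene_ids = gene_ids,
                  spot_ids = spot_ids, domain_labels = labels)
}

#' Spatial scatter plot of spots
#'
#' Minimal base-graphics view of the tissue: spots at their coordinates,
#' colored by cluster labels, domain labels, or any per-spot value.
#'
#' @param dataset a \code{spatial_dataset}.
#' @param color per-spot values (defaults to the dataset's domain labels).
#' @param ... passed to \code{plot}.
#' @export
plot_spots <- function(dataset, color = dataset$domain_labels, ...) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  col <- if (is.null(color)) "grey30" else as.integer(as.factor(color)) + 1L
  plot(dataset$coordinates, col = col, pch = 16, asp = 1,
       xlab = "x", ylab = "y", ...)
  invisible(dataset)
}
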