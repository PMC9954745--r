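test_that("embedding has the requested shape and ordered variance", {
  set.seed(6)
  n <- 40
  X <- matrix(rpois(n * 10, 4) + 0.0, n, 10)
  ds <- spatial_dataset(X, matrix(runif(2 * n), n, 2))
  emb <- preprocess_and_embed(ds, ds$gene_ids, n_components = 5)
  expect_equal(dim(emb$matrix), c(n, 5L))
  expect_true(all(is.finite(emb$matrix)))
  expect_true(all(diff(emb$sdev) <= 1e-12))

  expect_error(preprocess_and_embed(ds, character(0)), "empty")
  expect_error(preprocess_and_embed(ds, "nope"), "absent")
})

test_that("constant genes after preprocessing are dropped with a warning", {
  n <- 30
  X <- cbind(matrix(rpois(n * 4, 4) + 0.0, n, 4), 2)
  ds <- spatial_dataset(X, matrix(runif(2 * n), n, 2),
                        gene_ids = c(paste0("g", 1:4), "flat"))
  expect_warning(
    emb <- preprocess_and_embed(ds, ds$gene_ids, n_components = 3,
                                normalize = FALSE),
    "constant")
  expect_equal(emb$provenance$n_genes, 4L)
})

test_that("two components reconstruct a rank-2 matrix", {
  set.seed(44)
  n <- 60
  u <- matrix(rnorm(2 * n), n, 2)
  v <- matrix(rnorm(2 * 8), 8, 2)
  M <- u %*% t(v)
  M <- sweep(M, 2, apply(M, 2, min))   # non-negative; centered rank still 2
  ds <- spatial_dataset(M, matrix(runif(2 * n), n, 2))
  emb <- preprocess_and_embed(ds, ds$gene_ids, n_components = 2,
                              normalize = FALSE, log1p = FALSE,
                              scale. = FALSE)
  centered <- sweep(M, 2, colMeans(M))
  # recover the rotation from regression of the centered data on the scores
  recon <- emb$matrix %*% qr.solve(emb$matrix, centered)
  expect_equal(recon, centered, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("well-separated blobs cluster cleanly and reproducibly", {
  blobs <- make_blobs(100, rbind(c(0, 0), c(8, 8), c(16, 0)))
  for (m in c("louvain", "leiden")) {
    a <- cluster_spots(blobs$emb, m, seed = 0)
    # default resolution may refine blobs into subclusters, but never
    # merges across blobs: the partition is pure w.r.t. blob identity
    cm <- clustering_metrics(blobs$labels, a$labels)
    expect_equal(unname(cm["homogeneity"]), 1, tolerance = 1e-12)
    expect_gte(a$n_clusters, 3L)
    # determinism under a fixed seed
    b <- cluster_spots(blobs$emb, m, seed = 0)
    expect_identical(a$labels, b$labels)
  }
})

test_that("resolution near zero collapses a connected graph to one cluster", {
  set.seed(19)
  cloud <- matrix(rnorm(160), 80, 2)   # one cloud: connected kNN graph
  a <- cluster_spots(cloud, "louvain", resolution = 1e-6)
  expect_equal(a$n_clusters, 1L)
  expect_gt(cluster_spots(cloud, "louvain", resolution = 1)$n_clusters, 1L)
})

test_that("degenerate embeddings yield one cluster with a warning", {
  emb <- matrix(1, 20, 3)
  expect_warning(a <- cluster_spots(emb, "louvain"), "degenerate")
  expect_equal(a$n_clusters, 1L)
  expect_equal(a$labels, rep(0L, 20))
})

test_that("binary search on resolution reaches a target cluster count", {
  blobs <- make_blobs(75, rbind(c(0, 0), c(9, 0), c(0, 9), c(9, 9)), seed = 7)
  for (m in c("louvain", "leiden")) {
    a <- cluster_with_target_k(blobs$emb, m, target_k = 4)
    expect_equal(a$n_clusters, 4L)
    cm <- clustering_metrics(blobs$labels, a$labels)
    expect_gt(unname(cm["ari"]), 0.95)
  }
  # target_k = 1 drives the resolution to the lower bound (connected cloud)
  set.seed(29)
  cloud <- matrix(rnorm(200), 100, 2)
  a2 <- cluster_with_target_k(cloud, "louvain", target_k = 1)
  expect_equal(a2$n_clusters, 1L)
  expect_lte(a2$resolution, 1e-6)
  # a target equal to an achievable count is hit within the search budget
  k_def <- cluster_spots(blobs$emb, "louvain", resolution = 1)$n_clusters
  a3 <- cluster_with_target_k(blobs$emb, "louvain", target_k = k_def)
  expect_equal(a3$n_clusters, k_def)
})

test_that("full pipeline is deterministic under a fixed seed", {
  sim <- generate_spatial_dataset(synthetic_spec(
    grid_shape = c(12, 12), n_spatial_genes = 15, n_noise_genes = 45,
    sparsity_target = 0.8, seed = 5))
  run_once <- function() {
    sel <- identify_svgs(sim$dataset, n = 15, k = 10)
    emb <- preprocess_and_embed(sim$dataset, sel, n_components = 10, seed = 0)
    cluster_spots(emb, "leiden", seed = 0)$labels
  }
  expect_identical(run_once(), run_once())
})
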