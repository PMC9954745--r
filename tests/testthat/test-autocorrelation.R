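test_that("chess-board pattern on the 4-cycle gives the hand-worked values", {
  A <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1
  }
  g <- as_neighbor_graph(A)
  v <- c(1, -1, 1, -1)
  expect_equal(moran_i(v, g), -1, tolerance = 1e-12)
  gc <- geary_c(v, g)
  expect_equal(unname(gc["C"]), 1.5, tolerance = 1e-12)
  expect_equal(unname(gc["C_star"]), -0.5, tolerance = 1e-12)
})

test_that("zero-variance and degenerate inputs are flagged, not errors", {
  fx <- random_fixture()
  expect_true(is.na(moran_i(rep(3, 30), fx$graph)))
  expect_true(all(is.na(geary_c(rep(3, 30), fx$graph))))
  expect_error(moran_i(1:10, fx$graph), "length")

  # perfect local agreement on two disconnected pairs: C = 0, C* = 1
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  gp <- as_neighbor_graph(A)
  gc <- geary_c(c(5, 5, 1, 1), gp)
  expect_equal(unname(gc["C"]), 0)
  expect_equal(unname(gc["C_star"]), 1)
})

test_that("sparse statistics match literal double-loop oracles", {
  for (case in 1:20) {
    set.seed(100 + case)
    n <- sample(10:60, 1)
    k <- sample(2:8, 1)
    coords <- matrix(runif(2 * n), n, 2)
    x <- rnorm(n)
    ds <- spatial_dataset(matrix(1, n, 1), coords)
    g <- suppressWarnings(build_spatial_neighbor_graph(ds, k))
    W <- as.matrix(g$weights)
    expect_equal(moran_i(x, g), oracle_moran(x, W), tolerance = 1e-10)
    expect_equal(unname(geary_c(x, g)["C"]), oracle_geary(x, W),
                 tolerance = 1e-10)
  }
})

test_that("batch computation equals stacked single-gene calls", {
  set.seed(7)
  n <- 20; gct <- 10
  X <- matrix(rpois(n * gct, 3) + 0.0, n, gct)
  X[, 4] <- 2                      # a zero-variance gene
  ds <- spatial_dataset(X, matrix(runif(2 * n), n, 2))
  g <- build_spatial_neighbor_graph(ds, 4)
  res <- compute_autocorrelation(ds, g, chunk_size = 3L)
  expect_s3_class(res, "autocorr_result")
  expect_false(res$valid[4])
  expect_true(is.na(res$moran_i[4]))
  for (j in seq_len(gct)[-4]) {
    expect_equal(res$moran_i[j], moran_i(X[, j], g), tolerance = 1e-10)
    expect_equal(res$geary_c[j], unname(geary_c(X[, j], g)["C"]),
                 tolerance = 1e-10)
  }
  expect_equal(res$geary_c_rescaled, 1 - res$geary_c)
  # dimension mismatch is a shape error
  expect_error(compute_autocorrelation(random_fixture(n = 25)$ds, g), "spots")
})

test_that("both statistics are invariant to affine maps of the values", {
  fx <- random_fixture(n = 40, k = 5, seed = 21)
  for (case in 1:10) {
    set.seed(case)
    x <- rnorm(40)
    a <- runif(1, 0.5, 4); b <- runif(1, -5, 5)
    expect_equal(moran_i(x, fx$graph), moran_i(a * x + b, fx$graph),
                 tolerance = 1e-9)
    expect_equal(geary_c(x, fx$graph), geary_c(a * x + b, fx$graph),
                 tolerance = 1e-9)
  }
})

test_that("scores are invariant under a consistent spot permutation", {
  set.seed(31)
  n <- 35; gct <- 6
  X <- matrix(rpois(n * gct, 2) + 0.0, n, gct)
  coords <- matrix(runif(2 * n), n, 2)
  ds <- spatial_dataset(X, coords)
  g <- build_spatial_neighbor_graph(ds, 5)
  res <- compute_autocorrelation(ds, g)
  p <- sample(n)
  ds_p <- spatial_dataset(X[p, ], coords[p, ],
                          spot_ids = paste0("s", seq_len(n)))
  g_p <- build_spatial_neighbor_graph(ds_p, 5)
  res_p <- compute_autocorrelation(ds_p, g_p)
  expect_equal(res_p$moran_i, res$moran_i, tolerance = 1e-9)
  expect_equal(res_p$geary_c, res$geary_c, tolerance = 1e-9)
  # the same holds when the permutation is applied to the graph directly
  W <- as.matrix(g$weights)
  g_perm <- as_neighbor_graph(W[p, p])
  expect_equal(moran_i(X[p, 1], g_perm), moran_i(X[, 1], g),
               tolerance = 1e-12)
})

test_that("Geary's C is non-negative and results are run-to-run identical", {
  fx <- random_fixture(n = 50, g = 20, k = 6, seed = 12)
  r1 <- compute_autocorrelation(fx$ds, fx$graph)
  r2 <- compute_autocorrelation(fx$ds, fx$graph)
  expect_identical(r1, r2)
  expect_true(all(r1$geary_c[r1$valid] >= 0))
})
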