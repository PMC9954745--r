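test_that("identity and relabeling give perfect agreement scores", {
  t1 <- c(0, 0, 1, 1, 2, 2)
  for (pred in list(t1, c(5, 5, 9, 9, 7, 7), c("b", "b", "c", "c", "a", "a"))) {
    cm <- clustering_metrics(t1, pred)
    expect_equal(unname(cm), rep(1, 4), tolerance = 1e-12)
  }
  expect_error(clustering_metrics(t1, t1[-1]), "length")
})

test_that("the worked 3x2 contingency case matches the formula oracle", {
  truth <- c(0, 0, 1, 1, 2, 2)
  pred <- c(0, 0, 0, 1, 1, 1)
  cm <- clustering_metrics(truth, pred)
  expect_equal(cm, oracle_metrics(truth, pred), tolerance = 1e-12)
  # frozen values from independent evaluation of the contingency formulas
  expect_equal(unname(cm["ami"]), 0.2987924581708903, tolerance = 1e-10)
  expect_equal(unname(cm["ari"]), 0.24242424242424243, tolerance = 1e-10)
  expect_equal(unname(cm["homogeneity"]), 0.420619835714305, tolerance = 1e-10)
  expect_equal(unname(cm["nmi"]), 0.5295405780575617, tolerance = 1e-10)
})

test_that("metrics agree with oracles over exhaustive and sampled partitions", {
  # exhaustive over all partition pairs of 4 items
  parts <- all_partitions(4)
  for (t in parts) for (p in parts)
    expect_equal(clustering_metrics(t, p), oracle_metrics(t, p),
                 tolerance = 1e-10)
  # sampled pairs at larger n
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(6:8, 1)
    t <- sample(1:3, n, replace = TRUE)
    p <- sample(1:4, n, replace = TRUE)
    expect_equal(clustering_metrics(t, p), oracle_metrics(t, p),
                 tolerance = 1e-10)
  }
})

test_that("expected MI matches literal permutation-model enumeration", {
  cases <- list(
    list(t = c(1, 1, 2, 2, 3), p = c(1, 2, 2, 1, 1)),
    list(t = c(1, 1, 1, 2, 2, 2), p = c(1, 2, 3, 1, 2, 3)),
    list(t = c(1, 2, 1, 2, 1, 2), p = c(1, 1, 2, 2, 3, 3)))
  for (cs in cases) {
    n <- length(cs$t)
    tab <- table(cs$p, cs$t)
    emi_formula <- svgene:::expected_mi(rowSums(tab), colSums(tab), n)
    expect_equal(emi_formula, oracle_emi_permutation(cs$t, cs$p),
                 tolerance = 1e-10)
  }
})

test_that("ARI agrees with the established independent implementation", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    t <- sample(1:4, n, replace = TRUE)
    p <- sample(1:5, n, replace = TRUE)
    expect_equal(unname(clustering_metrics(t, p)["ari"]),
                 mclust::adjustedRandIndex(t, p), tolerance = 1e-10)
  }
})

test_that("single-class truth yields homogeneity 1 by convention", {
  expect_message(cm <- clustering_metrics(rep(1, 6), c(1, 1, 2, 2, 3, 3)),
                 "homogeneity")
  expect_equal(unname(cm["homogeneity"]), 1)
})

test_that("MAP matches hand-worked examples and boundary cases", {
  # all neighbors share the label -> MAP = 1
  blobs <- make_blobs(40, rbind(c(0, 0), c(50, 50)), sd = 0.5, seed = 3)
  expect_equal(mean_average_precision(blobs$emb, blobs$labels, K = 10), 1)
  # no neighbor ever matches -> MAP = 0 (the zero branch)
  expect_equal(mean_average_precision(cbind(c(1, 2), 0), c(1, 2), K = 1), 0)
  # hand case: match pattern (match, miss, match) -> AP = (1/1 + 2/3)/2 = 5/6
  ap1 <- local({
    m <- c(TRUE, FALSE, TRUE)
    sum((cumsum(m) / seq_len(3))[m]) / sum(m)
  })
  expect_equal(ap1, 5 / 6)
  # full-vector check against a literal per-spot loop
  set.seed(23)
  emb_r <- matrix(rnorm(60), 30, 2)
  lab_r <- sample(1:3, 30, replace = TRUE)
  K <- 7
  ap_all <- sapply(seq_len(30), function(i) {
    d <- sqrt(colSums((t(emb_r) - emb_r[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(30))[seq_len(K)]
    m <- lab_r[nb] == lab_r[i]
    if (!any(m)) return(0)
    sum((cumsum(m) / seq_len(K))[m]) / sum(m)
  })
  expect_equal(mean_average_precision(emb_r, lab_r, K), mean(ap_all),
               tolerance = 1e-12)
  expect_error(mean_average_precision(emb_r, lab_r, K = 30), "K must be")
})

test_that("matching an earlier neighbor never lowers average precision", {
  ap_of <- function(m) {
    if (!any(m)) return(0)
    sum((cumsum(m) / seq_along(m))[m]) / sum(m)
  }
  # AP normalizes by the match count, so flipping a mismatch *before* the
  # first match can only improve the precision profile
  set.seed(31)
  checked <- 0
  for (rep in 1:80) {
    m <- runif(10) < 0.4
    first <- which(m)[1]
    if (is.na(first) || first == 1L) next
    i <- sample.int(first - 1L, 1)
    m2 <- m; m2[i] <- TRUE
    expect_gte(ap_of(m2), ap_of(m))
    expect_true(ap_of(m2) >= 0 && ap_of(m2) <= 1)
    checked <- checked + 1
  }
  expect_gt(checked, 20)
})

test_that("MCVA separates blobs, is chance-level on random labels, seeded", {
  blobs <- make_blobs(50, rbind(c(0, 0), c(10, 10), c(0, 10)), seed = 5)
  expect_equal(mcva(blobs$emb, blobs$labels, seed = 1), 1.0)
  set.seed(77)
  rand_lab <- sample(1:2, 150, replace = TRUE)
  acc <- mcva(blobs$emb, rand_lab, seed = 1)
  expect_lt(abs(acc - 0.5), 0.12)
  expect_identical(mcva(blobs$emb, blobs$labels, seed = 3),
                   mcva(blobs$emb, blobs$labels, seed = 3))
  expect_error(mcva(blobs$emb, c(99, blobs$labels[-1]), seed = 1), "99")
})

test_that("LISI is 1 for a single label and ~2 for interleaved labels", {
  set.seed(41)
  emb <- matrix(rnorm(400), 200, 2)
  one <- ilisi(emb, rep("a", 200), perplexity = 30)
  expect_equal(one$per_spot_lisi, rep(1, 200), tolerance = 1e-10)
  expect_equal(one$ilisi_median, 1)
  expect_equal(one$ilisi_mean, 1)

  mixed <- ilisi(emb, rep(1:2, 100), perplexity = 30)
  expect_true(all(mixed$per_spot_lisi >= 1 - 1e-9))
  expect_true(all(mixed$per_spot_lisi <= 2 + 1e-9))
  expect_equal(mixed$ilisi_mean, 0.5, tolerance = 0.05)
  expect_equal(mixed$ilisi_median, 0.5, tolerance = 0.05)

  expect_warning(ilisi(emb[1:20, ], rep(1:2, 10), perplexity = 30),
                 "perplexity")
})
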