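# Independent oracles used across the suite. These deliberately share no code
# with the package: dense all-pairs constructions, literal double loops, and
# direct formula evaluation on contingency tables.

# Dense brute-force spatial-graph constructor: full distance matrix, per-row
# stable sort, decay weights.
oracle_graph <- function(coords, k) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    dmax <- d[nb[k]]
    if (dmax > 0) W[i, nb] <- 1 - d[nb] / dmax
  }
  W
}

# Literal double-loop Moran's I on a dense weight matrix.
oracle_moran <- function(x, W) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * xc[i] * xc[j]
  (n / sum(W)) * num / sum(xc^2)
}

# Literal double-loop Geary's C.
oracle_geary <- function(x, W) {
  n <- length(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (x[i] - x[j])^2
  (n - 1) * num / (2 * sum(W) * sum((x - mean(x))^2))
}

# All set partitions of n items as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_label) {
    pos <- length(labels) + 1L
    if (pos > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(next_label))
      recurse(c(labels, l), next_label + (l == next_label))
  }
  recurse(integer(0), 1L)
  out
}

# Direct formula evaluation of AMI/ARI/Homo/NMI from the contingency table.
# Entropies and MI as explicit sums; expected MI as the exact hypergeometric
# sum; ARI by exhaustive pair counting over all item pairs.
oracle_metrics <- function(truth, pred) {
  n <- length(truth)
  tl <- unique(truth); pl <- unique(pred)
  tab <- matrix(0, length(pl), length(tl))
  for (i in seq_len(n))
    tab[match(pred[i], pl), match(truth[i], tl)] <-
      tab[match(pred[i], pl), match(truth[i], tl)] + 1
  a <- rowSums(tab); b <- colSums(tab)
  ent <- function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log(p))
  }
  hp <- ent(a); ht <- ent(b)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] / n * log(n * tab[i, j] / (a[i] * b[j]))
  emi <- 0
  for (ai in a) for (bj in b) {
    for (nij in max(1, ai + bj - n):min(ai, bj)) {
      if (nij < 1) next
      lp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
      emi <- emi + nij / n * log(n * nij / (ai * bj)) * exp(lp)
    }
  }
  trivial <- (length(a) == 1 && length(b) == 1) ||
    (length(a) == n && length(b) == n)
  ami <- if (trivial) 1 else {
    den <- (hp + ht) / 2 - emi
    if (abs(den) < .Machine$double.eps) den <- .Machine$double.eps
    (mi - emi) / den
  }
  nmi <- if (trivial) 1 else if (hp == 0 || ht == 0) 0 else mi / sqrt(hp * ht)
  homo <- if (ht == 0) 1 else 1 - (ent(tab) - hp) / ht
  # ARI: count agreeing/disagreeing item pairs directly
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st && sp) s11 <- s11 + 1
    else if (!st && !sp) s00 <- s00 + 1
    else if (st) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  ari <- if (max_idx == exp_idx) 1 else (s11 - exp_idx) / (max_idx - exp_idx)
  c(ami = ami, ari = ari, homogeneity = homo, nmi = nmi)
}

# Expected MI by literal enumeration of all n! relabel permutations —
# independent of the hypergeometric formula. Only viable for small n.
oracle_emi_permutation <- function(truth, pred) {
  n <- length(truth)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  mi_of <- function(t, p) {
    tab <- table(p, t)
    a <- rowSums(tab); b <- colSums(tab); mi <- 0
    for (i in seq_along(a)) for (j in seq_along(b))
      if (tab[i, j] > 0)
        mi <- mi + tab[i, j] / n * log(n * tab[i, j] / (a[i] * b[j]))
    mi
  }
  mean(vapply(perms(seq_len(n)),
              function(pm) mi_of(truth, pred[pm]), numeric(1)))
}

# Gaussian blobs fixture for clustering/metric tests.
make_blobs <- function(n_per, centers, sd = 1, seed = 42) {
  set.seed(seed)
  emb <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(stats::rnorm(n_per, centers[i, 1], sd),
          stats::rnorm(n_per, centers[i, 2], sd))))
  list(emb = emb, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Small random dataset + graph for autocorrelation tests.
random_fixture <- function(n = 30, g = 5, k = 4, seed = 1) {
  set.seed(seed)
  ds <- spatial_dataset(matrix(stats::rpois(n * g, 2) + 0.0, n, g),
                        matrix(stats::runif(2 * n), n, 2))
  list(ds = ds, graph = build_spatial_neighbor_graph(ds, k))
}
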