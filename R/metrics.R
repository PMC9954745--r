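# Entropy of a count vector (natural log), and mutual information of a
# contingency table. Shared by the clustering metrics.
count_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

contingency_mi <- function(tab) {
  N <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[idx]
  sum(nij / N * log(N * nij / (a[idx[, 1]] * b[idx[, 2]])))
}

# Expected mutual information under the permutation (hypergeometric) model,
# exact summation over all feasible cell counts.
expected_mi <- function(a, b, N) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - N)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      lp <- lchoose(bj, nij) + lchoose(N - bj, ai - nij) - lchoose(N, ai)
      emi <- emi + sum(nij / N * log(N * nij / (ai * bj)) * exp(lp))
    }
  }
  emi
}

#' Clustering agreement metrics (AMI, ARI, homogeneity, NMI)
#'
#' Compares a predicted partition against ground-truth labels:
#' \itemize{
#'   \item AMI: mutual information corrected by its expectation under the
#'     permutation model and normalized by the arithmetic mean of the two
#'     entropies, \eqn{(MI - E[MI]) / (avg(H(P), H(T)) - E[MI])}.
#'   \item ARI: pair-counting Rand index adjusted for chance.
#'   \item Homogeneity: \eqn{1 - H(T|P)/H(T)}; when the truth has a single
#'     class, \eqn{H(T) = 0} and homogeneity is 1 by convention (a message
#'     is logged).
#'   \item NMI: \eqn{MI / \sqrt{H(P) H(T)}}.
#' }
#' All four equal 1 when the partitions are identical up to class renaming,
#' and are invariant to relabeling either partition.
#'
#' @param truth,predicted equal-length label vectors (any atomic type).
#' @return Named numeric vector \code{c(ami, ari, homogeneity, nmi)}.
#' @export
clustering_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop(sprintf("truth has length %d but predicted has length %d",
                 length(truth), length(predicted)))
  if (length(truth) == 0L) stop("empty label vectors")
  tab <- table(predicted, truth)
  N <- length(truth)
  a <- rowSums(tab)   # cluster sizes of P
  b <- colSums(tab)   # class sizes of T
  hp <- count_entropy(a)
  ht <- count_entropy(b)
  mi <- contingency_mi(tab)

  trivial <- (length(a) == 1L && length(b) == 1L) ||
    (length(a) == N && length(b) == N)
  ami <- if (trivial) 1 else {
    emi <- expected_mi(a, b, N)
    denom <- mean(c(hp, ht)) - emi
    if (abs(denom) < .Machine$double.eps) denom <- .Machine$double.eps
    (mi - emi) / denom
  }
  nmi <- if (trivial) 1 else if (hp == 0 || ht == 0) 0 else mi / sqrt(hp * ht)
  homo <- if (ht == 0) {
    message("single-class truth: homogeneity defined as 1")
    1
  } else 1 - (count_entropy(tab) - hp) / ht   # H(T|P) = H(T,P) - H(P)

  sum_comb_n <- function(x) sum(choose(x, 2))
  s_all <- sum_comb_n(as.vector(tab))
  s_a <- sum_comb_n(a); s_b <- sum_comb_n(b)
  exp_idx <- s_a * s_b / choose(N, 2)
  max_idx <- (s_a + s_b) / 2
  ari <- if (max_idx == exp_idx) 1 else (s_all - exp_idx) / (max_idx - exp_idx)

  c(ami = ami, ari = ari, homogeneity = homo, nmi = nmi)
}

#' Mean average precision of domain labels over embedding neighborhoods
#'
#' For each spot, its K Euclidean nearest neighbors in the embedding are
#' found (self excluded, distance ties broken by spot index). Average
#' precision for a spot is the mean of the precisions evaluated at each
#' label-matched neighbor position; a spot with no matched neighbor scores
#' 0. MAP, the mean over spots, lies in [0, 1]; higher values mean the
#' embedding resolves domains more sharply.
#'
#' @param embedding a \code{spot_embedding} or numeric matrix.
#' @param labels per-spot domain labels.
#' @param K neighborhood size (default 30).
#' @return MAP score in [0, 1].
#' @export
mean_average_precision <- function(embedding, labels, K = 30L) {
  emb <- if (inherits(embedding, "spot_embedding")) embedding$matrix
         else as.matrix(embedding)
  n <- nrow(emb)
  if (length(labels) != n) stop("labels length does not match embedding rows")
  K <- as.integer(K)
  if (is.na(K) || K < 1L || K > n - 1L)
    stop(sprintf("K must be in [1, %d]", n - 1L))
  labels <- as.integer(as.factor(labels))
  nn <- knn_exact(emb, K)
  ap <- vapply(seq_len(n), function(i) {
    match_k <- labels[nn$index[i, ]] == labels[i]
    nm <- sum(match_k)
    if (nm == 0L) return(0)
    prec <- cumsum(match_k) / seq_len(K)
    sum(prec[match_k]) / nm
  }, numeric(1))
  mean(ap)
}

#' Cross-validated SVM accuracy of domain prediction (MCVA)
#'
#' Stratified n-fold cross-validation (default 5) of a radial-basis-function
#' kernel support vector classifier predicting domain labels from the
#' embedding; returns the mean held-out accuracy over folds. Classifier
#' hyperparameters are the conventional defaults (unit cost, kernel
#' bandwidth 1 / n_features on standardized inputs). Fold assignment is
#' seeded.
#'
#' @param embedding a \code{spot_embedding} or numeric matrix.
#' @param labels per-spot domain labels; every class must have at least
#'   \code{n_folds} members.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold split.
#' @return Mean cross-validation accuracy in [0, 1].
#' @export
mcva <- function(embedding, labels, n_folds = 5L, seed = 0L) {
  emb <- if (inherits(embedding, "spot_embedding")) embedding$matrix
         else as.matrix(embedding)
  n <- nrow(emb)
  if (length(labels) != n) stop("labels length does not match embedding rows")
  y <- as.factor(labels)
  sizes <- table(y)
  small <- names(sizes)[sizes < n_folds]
  if (length(small))
    stop(sprintf("class(es) smaller than n_folds = %d: %s",
                 n_folds, paste(small, collapse = ", ")))
  set.seed(seed)
  fold <- integer(n)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))[sample.int(length(idx))]
  }
  acc <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    fit <- e1071::svm(emb[tr, , drop = FALSE], y[tr], kernel = "radial",
                      scale = TRUE)
    mean(stats::predict(fit, emb[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(acc)
}

#' Local inverse Simpson's index of domain mixing (LISI / iLISI)
#'
#' For each spot, a Gaussian-kernel distribution is built over its
#' \code{3 * perplexity} nearest embedding neighbors, with the bandwidth
#' tuned by binary search so the distribution's entropy equals
#' \code{log(perplexity)} (the standard perplexity calibration on squared
#' distances). The spot's LISI is the inverse Simpson's index of the
#' kernel-weighted label proportions: 1 when the neighborhood is one
#' domain, up to the number of labels when fully mixed. Summary scores
#' \code{ilisi_median = 1/median(LISI)} and \code{ilisi_mean = 1/mean(LISI)}
#' are higher when neighborhoods are purer.
#'
#' @param embedding a \code{spot_embedding} or numeric matrix.
#' @param labels per-spot domain labels.
#' @param perplexity kernel perplexity (default 30); reduced with a warning
#'   when the dataset has fewer than \code{3 * perplexity + 1} spots.
#' @return List with \code{ilisi_median}, \code{ilisi_mean}, and
#'   \code{per_spot_lisi}.
#' @export
ilisi <- function(embedding, labels, perplexity = 30) {
  emb <- if (inherits(embedding, "spot_embedding")) embedding$matrix
         else as.matrix(embedding)
  n <- nrow(emb)
  if (length(labels) != n) stop("labels length does not match embedding rows")
  labels <- as.integer(as.factor(labels))
  if (n - 1L < 3 * perplexity) {
    perplexity <- max(1, floor((n - 1L) / 3))
    warning(sprintf("too few spots for the requested perplexity; reduced to %g",
                    perplexity))
  }
  k <- min(as.integer(ceiling(3 * perplexity)), n - 1L)
  nn <- knn_exact(emb, k)
  target <- log(perplexity)
  lisi <- vapply(seq_len(n), function(i) {
    d2 <- nn$dist[i, ]^2
    beta <- 1
    lo <- -Inf; hi <- Inf
    p <- NULL
    for (iter in 1:64) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      if (sw == 0) { p <- rep(1 / k, k); break }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < 1e-6) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    props <- vapply(split(p, labels[nn$index[i, ]]), sum, numeric(1))
    1 / sum(props^2)
  }, numeric(1))
  list(ilisi_median = 1 / stats::median(lisi),
       ilisi_mean = 1 / mean(lisi),
       per_spot_lisi = lisi)
}
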