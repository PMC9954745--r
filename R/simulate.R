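#' Specify a synthetic spatial transcriptomics dataset
#'
#' Describes a regular spot grid partitioned into contiguous spatial domains
#' (a Voronoi partition around seeded centers, mimicking layered tissue
#' structure), with a subset of genes carrying planted spatial expression
#' patterns and the remainder pure noise, at Visium-like sparsity.
#'
#' Two planted pattern families are used, chosen per gene at random: a
#' domain block (expected expression elevated in one randomly chosen domain)
#' and a smooth radial gradient (a Gaussian bump around a random grid
#' point), exercising global and local spatial autocorrelation respectively.
#' The elevated mean is \code{base_mean * (1 + effect_size)}, so
#' \code{effect_size = 0} is an exact null in which planted and noise genes
#' are statistically indistinguishable.
#'
#' @param grid_shape integer (rows, cols) of the spot grid.
#' @param n_domains number of contiguous spatial domains.
#' @param n_spatial_genes genes with a planted spatial pattern.
#' @param n_noise_genes genes with a spatially constant mean.
#' @param effect_size elevation of the pattern over baseline (elevated mean
#'   = baseline x (1 + effect_size)); default 3.
#' @param sparsity_target fraction of zeros to aim for (counts are randomly
#'   thinned after sampling to reach it); default 0.9.
#' @param noise_model \code{"poisson"} or \code{"negative_binomial"}.
#' @param dispersion negative-binomial dispersion (variance = mu + mu^2 *
#'   dispersion); only used by the NB model. Default 0.5.
#' @param base_mean baseline expected count per spot per gene (default 0.5,
#'   a realistic low-coverage spot-level rate).
#' @param gradient_fraction fraction of spatial genes using the radial
#'   gradient pattern (default 0.5).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(grid_shape = c(40L, 40L), n_domains = 4L,
                           n_spatial_genes = 100L, n_noise_genes = 1900L,
                           effect_size = 3, sparsity_target = 0.9,
                           noise_model = c("poisson", "negative_binomial"),
                           dispersion = 0.5, base_mean = 0.5,
                           gradient_fraction = 0.5, seed = 0L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("grid_shape must be two positive integers")
  if (prod(grid_shape) < n_domains)
    stop("grid must have at least n_domains spots")
  if (n_spatial_genes + n_noise_genes < 1L)
    stop("at least one gene is required")
  if (sparsity_target < 0 || sparsity_target >= 1)
    stop("sparsity_target must be in [0, 1)")
  if (effect_size < 0) stop("effect_size must be non-negative")
  structure(
    list(grid_shape = grid_shape, n_domains = as.integer(n_domains),
         n_spatial_genes = as.integer(n_spatial_genes),
         n_noise_genes = as.integer(n_noise_genes),
         effect_size = effect_size, sparsity_target = sparsity_target,
         noise_model = noise_model, dispersion = dispersion,
         base_mean = base_mean, gradient_fraction = gradient_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic spatial dataset with planted SVGs
#'
#' Realizes a \code{\link{synthetic_spec}}: spots on the grid, Voronoi
#' domains around \code{n_domains} randomly seeded grid points (every domain
#' contains at least its own center, and the domains partition the grid),
#' per-gene expected expression surfaces, counts drawn from the noise model,
#' then binomial downsampling of molecules (each count thinned
#' \code{Binomial(x, r)}, with the keep rate r solved so the expected zero
#' fraction equals the sparsity target; infeasible targets below the
#' structural zero fraction produce a warning and are left as sampled).
#'
#' @param spec a \code{synthetic_spec}.
#' @return A list: \code{dataset} (a \code{\link{spatial_dataset}} with
#'   domain labels and a \code{gene_data$planted} truth column) and
#'   \code{truth} (logical vector flagging planted genes).
#' @examples
#' sim <- generate_spatial_dataset(synthetic_spec(
#'   grid_shape = c(10, 10), n_spatial_genes = 5, n_noise_genes = 20))
#' sim$dataset
#' @export
generate_spatial_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  coords <- cbind(x = rep(seq_len(nc), each = nr), y = rep(seq_len(nr), nc))
  n <- nrow(coords)

  centers <- coords[sample.int(n, spec$n_domains), , drop = FALSE]
  d2c <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
    2 * tcrossprod(coords, centers)
  domain <- max.col(-d2c, ties.method = "first")

  g_sp <- spec$n_spatial_genes; g_no <- spec$n_noise_genes
  g <- g_sp + g_no
  mu <- matrix(spec$base_mean, n, g)
  pattern <- rep("noise", g)
  if (g_sp > 0L) {
    is_grad <- stats::runif(g_sp) < spec$gradient_fraction
    pattern[seq_len(g_sp)] <- ifelse(is_grad, "gradient", "domain")
    sigma <- max(nr, nc) / 4
    # gradient bumps are rescaled so their spatial standard deviation matches
    # a domain block of relative size 1/n_domains at the same effect size:
    # both pattern families are planted at equal spatial signal strength
    p_dom <- 1 / spec$n_domains
    for (j in seq_len(g_sp)) {
      if (is_grad[j]) {
        ctr <- coords[sample.int(n, 1L), ]
        bump <- exp(-((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2) /
                      (2 * sigma^2))
        bump <- bump * sqrt(p_dom * (1 - p_dom)) / stats::sd(bump)
        mu[, j] <- spec$base_mean * (1 + spec$effect_size * bump)
      } else {
        d <- sample.int(spec$n_domains, 1L)
        mu[domain == d, j] <- spec$base_mean * (1 + spec$effect_size)
      }
    }
  }

  counts <- if (spec$noise_model == "poisson")
    matrix(stats::rpois(n * g, mu), n, g)
  else
    matrix(stats::rnbinom(n * g, mu = mu, size = 1 / spec$dispersion), n, g)

  z0 <- mean(counts == 0)
  if (z0 < spec$sparsity_target) {
    # binomial downsampling of molecules: keep each count with probability r,
    # with r solved so the expected zero fraction equals the target
    zero_frac <- function(r) mean((1 - r)^counts)
    r <- stats::uniroot(function(r) zero_frac(r) - spec$sparsity_target,
                        c(1e-9, 1), tol = 1e-9)$root
    counts[] <- stats::rbinom(length(counts), counts, r)
  } else if (z0 > spec$sparsity_target + 0.03) {
    warning(sprintf(
      "sparsity target %.2f is below the structural zero fraction %.2f; leaving counts as sampled",
      spec$sparsity_target, z0))
  }

  truth <- c(rep(TRUE, g_sp), rep(FALSE, g_no))
  dataset <- spatial_dataset(
    expression = counts, coordinates = coords,
    gene_ids = sprintf("gene_%04d", seq_len(g)),
    spot_ids = sprintf("spot_%04d", seq_len(n)),
    domain_labels = factor(domain),
    gene_data = data.frame(planted = truth, pattern = pattern,
                           stringsAsFactors = FALSE)
  )
  list(dataset = dataset, truth = truth)
}
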