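#' Population parameters for a synthetic cluster condition
#'
#' Bundles the generative distribution parameters that define one simulated
#' experimental condition (one coating concentration). Cluster areas are
#' lognormal, eccentricities beta, and normalized edge distances gamma
#' (truncated to \[0, 1) by resampling, since the measured quantity is a
#' normalized fraction while the gamma has unbounded support).
#'
#' @param size_alpha Log-scale location of cluster area; areas are in um^2,
#'   so `exp(size_alpha)` is the median cluster area.
#' @param size_beta Log-scale shape (standard deviation of log area), > 0
#'   (0 allowed for the degenerate all-equal case).
#' @param ecc_alpha,ecc_beta Beta-distribution shape parameters (> 0) for
#'   cluster eccentricity.
#' @param loc_alpha Gamma shape parameter (> 0) for normalized edge distance.
#' @param loc_beta Gamma scale parameter (> 0); the untruncated mean edge
#'   distance is `loc_alpha * loc_beta`.
#' @param n_clusters_per_cell Positive integer, clusters rendered per cell.
#' @param size_ecc_coupling Coupling coefficient in \[0, 1\] linking size rank
#'   to eccentricity rank via a Gaussian copula; 0 means independent, larger
#'   values make big clusters systematically more elongated.
#'
#' @return An object of class `population_params`.
#' @export
#' @examples
#' population_params(size_alpha = -1.4, size_beta = 0.9,
#'                   ecc_alpha = 7, ecc_beta = 1.6,
#'                   loc_alpha = 2, loc_beta = 0.12,
#'                   n_clusters_per_cell = 150)
population_params <- function(size_alpha, size_beta,
                              ecc_alpha, ecc_beta,
                              loc_alpha, loc_beta,
                              n_clusters_per_cell,
                              size_ecc_coupling = 0) {
  stopifnot(is.numeric(size_alpha), length(size_alpha) == 1L, is.finite(size_alpha))
  if (!is.numeric(size_beta) || size_beta < 0)
    stop("'size_beta' must be >= 0")
  for (nm in c("ecc_alpha", "ecc_beta", "loc_alpha", "loc_beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  n_clusters_per_cell <- as.integer(n_clusters_per_cell)
  if (is.na(n_clusters_per_cell) || n_clusters_per_cell < 1L)
    stop("'n_clusters_per_cell' must be a positive integer")
  if (!is.numeric(size_ecc_coupling) || size_ecc_coupling < 0 ||
      size_ecc_coupling > 1)
    stop("'size_ecc_coupling' must lie in [0, 1]")
  structure(
    list(size_alpha = size_alpha, size_beta = size_beta,
         ecc_alpha = ecc_alpha, ecc_beta = ecc_beta,
         loc_alpha = loc_alpha, loc_beta = loc_beta,
         n_clusters_per_cell = n_clusters_per_cell,
         size_ecc_coupling = size_ecc_coupling),
    class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Cluster population parameters\n")
  cat(sprintf("  area      ~ lognormal(alpha = %.4g, beta = %.4g) um^2\n",
              x$size_alpha, x$size_beta))
  cat(sprintf("  ecc       ~ beta(%.4g, %.4g)\n", x$ecc_alpha, x$ecc_beta))
  cat(sprintf("  edge dist ~ gamma(shape = %.4g, scale = %.4g), truncated < 1\n",
              x$loc_alpha, x$loc_beta))
  cat(sprintf("  clusters/cell = %d, size-ecc coupling = %.2f\n",
              x$n_clusters_per_cell, x$size_ecc_coupling))
  invisible(x)
}

#' Sample a ground-truth cluster population
#'
#' Draws one cell's worth of true cluster descriptors from a
#' [population_params] object: lognormal areas, beta eccentricities, gamma
#' edge distances (resampled until < 1), and uniform angular placement.
#' When `size_ecc_coupling > 0`, area and eccentricity are drawn from a
#' Gaussian copula with that latent correlation, so larger clusters tend to
#' be more elongated while the two marginal distributions are unchanged.
#'
#' @param params A [population_params] object.
#' @param rng_seed Integer seed; the draw is fully reproducible.
#' @param n Number of clusters to draw (defaults to
#'   `params$n_clusters_per_cell`).
#' @return A data.frame with columns `area_um2`, `ecc`, `edge_dist`, `theta`
#'   (placement angle, radians in \[0, 2*pi)).
#' @export
sample_cluster_population <- function(params, rng_seed, n = NULL) {
  stopifnot(inherits(params, "population_params"))
  if (is.null(n)) n <- params$n_clusters_per_cell
  n <- as.integer(n)
  set.seed(as.integer(rng_seed))

  # Gaussian copula between size and eccentricity; marginals untouched.
  z_size <- rnorm(n)
  c0 <- params$size_ecc_coupling
  z_ecc <- c0 * z_size + sqrt(1 - c0^2) * rnorm(n)
  area <- qlnorm(pnorm(z_size), meanlog = params$size_alpha,
                 sdlog = params$size_beta)
  ecc <- qbeta(pnorm(z_ecc), params$ecc_alpha, params$ecc_beta)

  # Gamma edge distances truncated to [0, 1) by resampling.
  edge <- rgamma(n, shape = params$loc_alpha, scale = params$loc_beta)
  for (i in seq_len(1000L)) {
    bad <- edge >= 1
    if (!any(bad)) break
    edge[bad] <- rgamma(sum(bad), shape = params$loc_alpha,
                        scale = params$loc_beta)
  }
  if (any(edge >= 1))
    stop("gamma edge-distance truncation failed to converge; ",
         "loc_alpha * loc_beta is too close to or above 1")

  theta <- runif(n, 0, 2 * pi)
  data.frame(area_um2 = area, ecc = ecc, edge_dist = edge, theta = theta)
}
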