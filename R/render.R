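#' Render a synthetic two-channel cell image with ground truth
#'
#' Paints each true cluster as an anisotropic Gaussian-profile ellipse on the
#' integrin channel and a dim uniform fill of the cell mask on the
#' cytoskeleton channel, adds Gaussian background noise, and quantizes to
#' 8 bits. The intensity profile is `A * 2^(-rho^2)` where `rho` is the
#' normalized elliptical radius, so the half-maximum contour is exactly the
#' ellipse whose area equals the cluster's true area: thresholding at half
#' the peak amplitude recovers the true footprint (up to discretization),
#' while other thresholds give systematically smaller or larger footprints,
#' mimicking the threshold dependence of real immunofluorescence spots.
#'
#' Cluster centers are placed along the ray at each sampled angle at the
#' fraction `1 - edge_dist` of the centroid-to-edge distance, so the true
#' normalized edge distance of the rendered cluster matches its sampled
#' value by construction.
#'
#' @param cell A `cell_geometry` (see [generate_cell_mask]).
#' @param clusters Data.frame of true descriptors from
#'   [sample_cluster_population] (columns `area_um2`, `ecc`, `edge_dist`,
#'   `theta`).
#' @param pixel_area_um2 Pixel calibration (um^2 per pixel).
#' @param snr Peak-signal-to-noise ratio: background noise sd is
#'   `255 / snr`. Use `Inf` for noise-free images.
#' @param rng_seed Integer seed (noise and ellipse orientations).
#' @param condition_label,cell_id Labels carried into the image and truth.
#' @return A list with `image` (an [intensity_image]) and `truth`, a
#'   data.frame with one row per rendered cluster: `cluster_id`,
#'   `true_area_um2`, `true_ecc`, `true_edge_dist`, `x_px`, `y_px` (center,
#'   1-based column/row), and `overlaps` (TRUE if the half-maximum footprint
#'   overlaps another cluster's).
#' @export
render_image <- function(cell, clusters, pixel_area_um2 = 0.02, snr = 20,
                         rng_seed = 1, condition_label = "", cell_id = "") {
  stopifnot(inherits(cell, "cell_geometry"), pixel_area_um2 > 0, snr > 0)
  set.seed(as.integer(rng_seed))
  nr <- nrow(cell$mask); nc <- ncol(cell$mask)
  n <- nrow(clusters)

  # place centers along each cluster's ray
  d_ce <- vapply(clusters$theta, function(th) .ray_edge_at_angle(cell, th),
                 numeric(1))
  d_cc <- (1 - clusters$edge_dist) * d_ce
  cy <- cell$centroid[1] + d_cc * sin(clusters$theta)
  cx <- cell$centroid[2] + d_cc * cos(clusters$theta)
  in_mask <- cell$mask[cbind(pmin(pmax(round(cy), 1), nr),
                             pmin(pmax(round(cx), 1), nc))]
  if (!all(in_mask))
    stop("internal error: placed cluster center outside the cell mask")

  signal <- matrix(0, nr, nc)
  core_count <- matrix(0L, nr, nc)  # how many half-max footprints cover a px
  phi <- runif(n, 0, pi)            # ellipse orientation, uniform
  amp <- 255

  for (k in seq_len(n)) {
    area_px <- clusters$area_um2[k] / pixel_area_um2
    ratio <- sqrt(1 - clusters$ecc[k]^2)        # minor/major axis ratio
    a <- sqrt(area_px / (pi * ratio))           # semi-major axis, px
    b <- a * ratio
    # the cluster proper is its half-maximum ellipse (extent a); that must
    # fit inside the image. The Gaussian tail painted out to 2.2a
    # (2^(-2.2^2) < 0.04, negligible) may be cropped at the border.
    core_ext <- ceiling(a) + 1L
    if (floor(cy[k]) - core_ext < 1 || floor(cx[k]) - core_ext < 1 ||
        ceiling(cy[k]) + core_ext > nr || ceiling(cx[k]) + core_ext > nc)
      stop(sprintf("cluster %d footprint extends past the image bounds", k))
    ext <- ceiling(2.2 * a) + 1L
    rr <- max(1L, floor(cy[k]) - ext):min(nr, ceiling(cy[k]) + ext)
    cc <- max(1L, floor(cx[k]) - ext):min(nc, ceiling(cx[k]) + ext)
    dy <- matrix(rr - cy[k], length(rr), length(cc))
    dx <- matrix(cc - cx[k], length(rr), length(cc), byrow = TRUE)
    u <- dx * cos(phi[k]) + dy * sin(phi[k])    # along major axis
    v <- -dx * sin(phi[k]) + dy * cos(phi[k])
    rho2 <- (u / a)^2 + (v / b)^2
    signal[rr, cc] <- signal[rr, cc] + amp * 2^(-rho2)
    core_count[rr, cc] <- core_count[rr, cc] + (rho2 <= 1)
  }

  # A cluster is flagged as overlapping when it is not separable from a
  # neighbor in the noiseless image: either its elliptical core intersects
  # another core, or the summed half-maximum footprints form one connected
  # component containing several cluster centers (tail bridging).
  overlaps <- logical(n)
  half_lab <- label_components(signal > amp / 2, connectivity = 8)
  comp <- half_lab[cbind(pmin(pmax(round(cy), 1), nr),
                         pmin(pmax(round(cx), 1), nc))]
  comp_tab <- tabulate(comp[comp > 0L])
  for (k in seq_len(n)) {
    area_px <- clusters$area_um2[k] / pixel_area_um2
    ratio <- sqrt(1 - clusters$ecc[k]^2)
    a <- sqrt(area_px / (pi * ratio)); b <- a * ratio
    ext <- ceiling(a) + 1L
    rr <- max(1, floor(cy[k]) - ext):min(nr, ceiling(cy[k]) + ext)
    cc <- max(1, floor(cx[k]) - ext):min(nc, ceiling(cx[k]) + ext)
    dy <- matrix(rr - cy[k], length(rr), length(cc))
    dx <- matrix(cc - cx[k], length(rr), length(cc), byrow = TRUE)
    u <- dx * cos(phi[k]) + dy * sin(phi[k])
    v <- -dx * sin(phi[k]) + dy * cos(phi[k])
    core <- (u / a)^2 + (v / b)^2 <= 1
    core_overlap <- any(core_count[rr, cc][core] > 1L)
    bridged <- comp[k] > 0L && comp_tab[comp[k]] > 1L
    overlaps[k] <- core_overlap || bridged
  }

  noise_sd <- if (is.finite(snr)) amp / snr else 0
  ch1 <- signal + if (noise_sd > 0) rnorm(nr * nc, 0, noise_sd) else 0
  ch2 <- 80 * cell$mask + if (noise_sd > 0) rnorm(nr * nc, 0, noise_sd) else 0
  quantize <- function(m) {
    m <- round(m); m[m < 0] <- 0; m[m > 255] <- 255
    matrix(as.integer(m), nr, nc)
  }

  img <- intensity_image(quantize(ch1), quantize(ch2), pixel_area_um2,
                         condition_label, cell_id)
  truth <- data.frame(
    condition = rep(condition_label, n), cell_id = rep(cell_id, n),
    cluster_id = seq_len(n),
    true_area_um2 = clusters$area_um2, true_ecc = clusters$ecc,
    true_edge_dist = clusters$edge_dist,
    x_px = cx, y_px = cy, overlaps = overlaps)
  list(image = img, truth = truth,
       cell_centroid = cell$centroid, rng_seed = as.integer(rng_seed))
}
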