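#' Calibrated cluster area
#'
#' Area is pixel count times the pixel calibration; no sub-pixel boundary
#' correction is applied, matching pixel-count-based size conventions
#' (e.g. 5 pixels at 0.02 um^2/px = 0.1 um^2).
#'
#' @param pixels n x 2 matrix of (row, col) pixel coordinates.
#' @param pixel_area_um2 Pixel area in um^2.
#' @return Area in um^2.
#' @export
cluster_area <- function(pixels, pixel_area_um2) {
  if (is.null(pixels) || nrow(pixels) == 0L)
    stop("empty pixel set has no area")
  stopifnot(pixel_area_um2 > 0)
  nrow(pixels) * pixel_area_um2
}

#' Equivalent-ellipse eccentricity of a pixel region
#'
#' The region is idealized as the ellipse having the same normalized second
#' central moments as its pixel coordinates: each pixel is treated as a unit
#' square, contributing 1/12 to each diagonal moment, so even a single pixel
#' has a well-defined (isotropic) moment matrix. With eigenvalues
#' `l1 >= l2 > 0` of that matrix, the eccentricity is `sqrt(1 - l2/l1)` --
#' the focal distance of the ellipse divided by its major axis length.
#' 0 is a circle, values near 1 an elongated streak.
#'
#' @param pixels n x 2 matrix of (row, col) pixel coordinates.
#' @return Eccentricity in \[0, 1\].
#' @export
#' @examples
#' cluster_eccentricity(cbind(1, 1:5))  # a 1 x 5 row: sqrt(1 - 1/25)
cluster_eccentricity <- function(pixels) {
  if (is.null(pixels) || nrow(pixels) == 0L)
    stop("empty pixel set has no eccentricity")
  n <- nrow(pixels)
  r <- pixels[, 1] - mean(pixels[, 1])
  c <- pixels[, 2] - mean(pixels[, 2])
  mrr <- sum(r * r) / n + 1 / 12
  mcc <- sum(c * c) / n + 1 / 12
  mrc <- sum(r * c) / n
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2
  l2 <- (mrr + mcc - common) / 2
  sqrt(max(0, 1 - l2 / l1))
}

#' Edge point and radial distances along the centroid-to-cluster ray
#'
#' Marches from the cell centroid along the ray through the cluster centroid
#' in 0.25 px steps; the edge point is the last inside-mask sample before
#' the first exit. Returns the distance from the cell centroid to the
#' cluster (`d_cc`) and to the edge point (`d_ce`).
#'
#' @param cell A `cell_geometry`.
#' @param cluster_centroid Sub-pixel (row, col) of the cluster centroid.
#' @return List with `edge_point` (row, col), `d_cc`, `d_ce`, and
#'   `outside_mask` (TRUE when the cluster centroid lies beyond the first
#'   mask exit, i.e. `d_cc > d_ce`).
#' @export
ray_edge_point <- function(cell, cluster_centroid) {
  stopifnot(inherits(cell, "cell_geometry"))
  dvec <- cluster_centroid - cell$centroid
  d_cc <- sqrt(sum(dvec^2))
  if (d_cc < 1e-9)
    stop("cluster centroid coincides with the cell centroid; ray direction undefined")
  mr <- .ray_march(cell$mask, cell$centroid, dvec / d_cc)
  list(edge_point = mr$edge_point, d_cc = d_cc, d_ce = mr$d_ce,
       outside_mask = d_cc > mr$d_ce)
}

#' Normalized distance from the cell edge
#'
#' `(d_ce - d_cc) / d_ce`: 0 for a cluster on the cell periphery, 1 for a
#' cluster at the cell centroid. On irregular cells a cluster can lie beyond
#' its own ray's edge point (`d_cc > d_ce`); the value is then clamped to 0
#' and flagged so that downstream gamma fits keep a valid domain.
#'
#' @param d_cc,d_ce Centroid-to-cluster and centroid-to-edge distances
#'   (vectors of equal length).
#' @return Data.frame with `value` in \[0, 1\] and logical `clamped`.
#' @export
normalized_edge_distance <- function(d_cc, d_ce) {
  stopifnot(length(d_cc) == length(d_ce))
  if (any(d_ce <= 0))
    stop("degenerate geometry: centroid-to-edge distance must be positive")
  raw <- (d_ce - d_cc) / d_ce
  value <- pmin(pmax(raw, 0), 1)
  data.frame(value = value, clamped = raw < 0 | raw > 1)
}

#' Normalized distance from the cell center
#'
#' Each cluster's centroid distance `d_cc` is normalized by the cell's
#' average radius, defined as the mean over that cell's clusters of the
#' centroid-to-edge distance measured along each cluster's own ray. Values
#' may exceed 1 for clusters lying further out than the average radius.
#'
#' @param d_cc,d_ce Per-cluster distances for one cell.
#' @return Numeric vector of normalized center distances (empty for zero
#'   clusters).
#' @export
normalized_center_distance <- function(d_cc, d_ce) {
  stopifnot(length(d_cc) == length(d_ce))
  if (length(d_cc) == 0L) return(numeric(0))
  d_cc / mean(d_ce)
}

#' Measure all clusters of one cell
#'
#' Combines segmentation output into per-cluster records: calibrated area,
#' equivalent-ellipse eccentricity, and the two normalized location metrics.
#' Cluster centroids are unweighted means of pixel coordinates (measurement
#' is on the binary segmentation, not the intensities). The rare cluster
#' whose centroid coincides with the cell centroid (< 1e-9 px) is assigned
#' edge and center distances of 1 and 0 without ray marching.
#'
#' @param image An [intensity_image] (supplies calibration and labels).
#' @param cell A `cell_geometry` from [segment_cell_body].
#' @param clusters A `labeled_clusters` from [segment_clusters].
#' @return Data.frame with one row per cluster: `condition`, `cell_id`,
#'   `cluster_id`, `n_px`, `area_um2`, `eccentricity`, `edge_dist_norm`,
#'   `center_dist_norm`, `d_cc`, `d_ce`, `centroid_row`, `centroid_col`,
#'   `edge_clamped`, `outside_mask`.
#' @export
measure_clusters <- function(image, cell, clusters) {
  stopifnot(inherits(clusters, "labeled_clusters"),
            inherits(cell, "cell_geometry"))
  n <- length(clusters$pixels)
  if (n == 0L) {
    return(data.frame(condition = character(0), cell_id = character(0),
                      cluster_id = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), eccentricity = numeric(0),
                      edge_dist_norm = numeric(0),
                      center_dist_norm = numeric(0),
                      d_cc = numeric(0), d_ce = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      edge_clamped = logical(0), outside_mask = logical(0)))
  }
  n_px <- vapply(clusters$pixels, nrow, integer(1))
  area <- n_px * image$pixel_area_um2
  ecc <- vapply(clusters$pixels, cluster_eccentricity, numeric(1))
  cr <- vapply(clusters$pixels, function(p) mean(p[, 1]), numeric(1))
  cc <- vapply(clusters$pixels, function(p) mean(p[, 2]), numeric(1))

  d_cc <- d_ce <- numeric(n)
  outside <- logical(n)
  for (k in seq_len(n)) {
    dvec <- c(cr[k], cc[k]) - cell$centroid
    if (sqrt(sum(dvec^2)) < 1e-9) {
      d_cc[k] <- 0
      d_ce[k] <- mean(vapply(
        seq(0, 2 * pi, length.out = 9)[-9],
        function(th) .ray_edge_at_angle(cell, th), numeric(1)))
      outside[k] <- FALSE
    } else {
      rp <- ray_edge_point(cell, c(cr[k], cc[k]))
      d_cc[k] <- rp$d_cc; d_ce[k] <- rp$d_ce; outside[k] <- rp$outside_mask
    }
  }
  ed <- normalized_edge_distance(d_cc, d_ce)
  data.frame(
    condition = rep(image$condition_label, n),
    cell_id = rep(image$cell_id, n),
    cluster_id = seq_len(n), n_px = n_px, area_um2 = area,
    eccentricity = ecc, edge_dist_norm = ed$value,
    center_dist_norm = normalized_center_distance(d_cc, d_ce),
    d_cc = d_cc, d_ce = d_ce, centroid_row = cr, centroid_col = cc,
    edge_clamped = ed$clamped, outside_mask = outside)
}

#' Total bound-integrin area per cell
#'
#' Sum of all cluster areas in a condition divided by the number of cells
#' analysed, a per-cell measure of how much membrane area is occupied by
#' bound integrin.
#'
#' @param records Cluster records (as from [measure_clusters]) for one
#'   condition.
#' @param n_cells Number of cells analysed; defaults to the number of
#'   distinct `cell_id` values in `records` (pass explicitly if some cells
#'   had zero clusters).
#' @return Total cluster area per cell, um^2.
#' @export
total_bound_area <- function(records, n_cells = NULL) {
  if (is.null(n_cells)) n_cells <- length(unique(records$cell_id))
  if (n_cells < 1L) stop("at least one cell is required")
  sum(records$area_um2) / n_cells
}
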