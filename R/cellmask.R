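#' Cell geometry container
#'
#' Internal constructor shared by the synthetic generator and the cell-body
#' segmenter: wraps a filled binary mask together with its (unweighted)
#' centroid, calibrated area, and angle-ordered boundary pixel coordinates.
#'
#' @param mask Logical matrix (rows = y, cols = x), a single filled
#'   connected component.
#' @param pixel_area_um2 Pixel area calibration in um^2.
#' @return An object of class `cell_geometry` with elements `mask`,
#'   `centroid` (c(row, col), sub-pixel), `area_um2`, `area_px`,
#'   `perimeter_points` (matrix of boundary pixel (row, col), ordered by
#'   angle around the centroid).
#' @keywords internal
cell_geometry <- function(mask, pixel_area_um2) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_area_um2 > 0)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty cell mask")
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))

  # Boundary pixels: mask pixels with at least one 4-neighbor outside (or on
  # the image border). Ordered by angle about the centroid.
  padded <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  r <- idx[, 1] + 1L; c <- idx[, 2] + 1L
  interior <- padded[cbind(r - 1L, c)] & padded[cbind(r + 1L, c)] &
    padded[cbind(r, c - 1L)] & padded[cbind(r, c + 1L)]
  per <- idx[!interior, , drop = FALSE]
  ang <- atan2(per[, 1] - centroid[1], per[, 2] - centroid[2])
  per <- per[order(ang), , drop = FALSE]
  colnames(per) <- c("row", "col")

  structure(
    list(mask = mask, centroid = centroid,
         area_px = nrow(idx), area_um2 = nrow(idx) * pixel_area_um2,
         pixel_area_um2 = pixel_area_um2, perimeter_points = per),
    class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "Cell geometry: %d x %d mask, area %.1f um^2 (%d px), centroid (%.1f, %.1f)\n",
    nrow(x$mask), ncol(x$mask), x$area_um2, x$area_px,
    x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Generate a synthetic spread-cell mask
#'
#' Builds a star-convex cell outline as a radial-harmonic perturbation of a
#' disk: the boundary radius is `mean_radius_px * (1 + roughness * s(theta))`
#' where `s` is a smooth random combination of low-order harmonics normalized
#' to max |s| = 1. Star convexity guarantees that every ray from the centroid
#' crosses the boundary exactly once, which keeps the radial location metric
#' single-valued.
#'
#' @param rng_seed Integer seed.
#' @param mean_radius_px Mean boundary radius in pixels (>= 20).
#' @param boundary_roughness Relative perturbation amplitude in \[0, 1\];
#'   0 gives a discrete disk. Values above ~0.4 are rejected because large
#'   perturbations can break star convexity about the mask centroid.
#' @param image_shape Integer vector c(rows, cols) of the target image.
#' @param pixel_area_um2 Pixel calibration used for the mask area.
#' @return A `cell_geometry` object.
#' @export
#' @examples
#' cell <- generate_cell_mask(1, mean_radius_px = 40,
#'                            boundary_roughness = 0.2,
#'                            image_shape = c(128, 128))
#' cell$area_um2
generate_cell_mask <- function(rng_seed, mean_radius_px = 160,
                               boundary_roughness = 0.2,
                               image_shape = c(512L, 512L),
                               pixel_area_um2 = 0.02) {
  if (mean_radius_px < 20) stop("'mean_radius_px' must be >= 20")
  if (boundary_roughness < 0 || boundary_roughness > 0.4)
    stop("'boundary_roughness' must lie in [0, 0.4]")
  rmax <- mean_radius_px * (1 + boundary_roughness)
  if (2 * rmax + 4 > min(image_shape))
    stop(sprintf(
      "cell of maximum radius %.1f px does not fit in a %d x %d image with a 2 px margin",
      rmax, image_shape[1], image_shape[2]))

  set.seed(as.integer(rng_seed))
  # Low-order harmonics (k = 2..5) with decaying amplitude; k = 1 is skipped
  # because it mostly translates the shape rather than deforming it.
  ks <- 2:5
  a <- rnorm(length(ks)) * 0.7^(ks - 2)
  b <- rnorm(length(ks)) * 0.7^(ks - 2)
  radius_at <- function(theta) {
    s <- rep(0, length(theta))
    if (boundary_roughness > 0) {
      for (i in seq_along(ks))
        s <- s + a[i] * cos(ks[i] * theta) + b[i] * sin(ks[i] * theta)
      smax <- max(abs(s), 1e-12)
      # normalize on a fine grid so max |s| = 1 independent of query points
      grid <- seq(0, 2 * pi, length.out = 720L)
      sg <- rep(0, length(grid))
      for (i in seq_along(ks))
        sg <- sg + a[i] * cos(ks[i] * grid) + b[i] * sin(ks[i] * grid)
      s <- s / max(abs(sg))
    }
    mean_radius_px * (1 + boundary_roughness * s)
  }

  cy <- (image_shape[1] + 1) / 2
  cx <- (image_shape[2] + 1) / 2
  rows <- matrix(seq_len(image_shape[1]), image_shape[1], image_shape[2])
  cols <- matrix(seq_len(image_shape[2]), image_shape[1], image_shape[2],
                 byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  theta <- atan2(dy, dx)
  mask <- sqrt(dy^2 + dx^2) <= radius_at(as.numeric(theta))
  dim(mask) <- image_shape

  geom <- cell_geometry(mask, pixel_area_um2)
  geom$mean_radius_px <- mean_radius_px
  geom$generator_center <- c(cy, cx)
  geom
}
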