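#' Automatic intensity threshold
#'
#' Reproducible stand-in for per-image manual threshold selection. `"otsu"`
#' maximizes between-class variance on the 8-bit histogram; `"quantile"`
#' returns the empirical `q`-quantile (type-1 order statistic, so at most a
#' fraction `1 - q` of pixels lies strictly above it).
#'
#' @param channel Numeric matrix of intensities.
#' @param method `"otsu"` or `"quantile"`.
#' @param q Quantile level when `method = "quantile"`.
#' @return A single threshold value, strictly between the channel minimum
#'   and maximum.
#' @export
auto_threshold <- function(channel, method = c("otsu", "quantile"),
                           q = 0.99) {
  method <- match.arg(method)
  rng <- range(channel)
  if (rng[1] == rng[2])
    stop("cannot threshold a constant channel (all pixels = ",
         rng[1], ")")
  t <- if (method == "otsu") {
    255 * EBImage::otsu(EBImage::Image(channel / 255), range = c(0, 1),
                        levels = 256)
  } else {
    as.numeric(quantile(channel, q, type = 1, names = FALSE))
  }
  # guarantee a usable threshold strictly inside the intensity range
  min(max(t, rng[1]), rng[2] - 1e-9)
}

#' Label connected components of a binary mask
#'
#' Two-pass union-find labeling with selectable pixel connectivity. Labels
#' are assigned in row-major raster order of each component's first pixel
#' (label 1 is the component whose first pixel is encountered first reading
#' the image row by row).
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edges + diagonals).
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(lab)
  fg <- fg[order(fg[, 1], fg[, 2]), , drop = FALSE]  # row-major scan

  parent <- integer(0)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != i) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  nlab <- 0L
  for (k in seq_len(nrow(fg))) {
    r <- fg[k, 1]; c <- fg[k, 2]
    nb <- integer(0)
    if (c > 1L && lab[r, c - 1L] > 0L) nb <- c(nb, lab[r, c - 1L])
    if (r > 1L) {
      if (lab[r - 1L, c] > 0L) nb <- c(nb, lab[r - 1L, c])
      if (connectivity == 8) {
        if (c > 1L && lab[r - 1L, c - 1L] > 0L) nb <- c(nb, lab[r - 1L, c - 1L])
        if (c < nc && lab[r - 1L, c + 1L] > 0L) nb <- c(nb, lab[r - 1L, c + 1L])
      }
    }
    if (length(nb) == 0L) {
      nlab <- nlab + 1L
      parent[nlab] <- nlab
      lab[r, c] <- nlab
    } else {
      roots <- unique(vapply(nb, find, integer(1)))
      keep <- min(roots)
      lab[r, c] <- keep
      for (rt in roots[roots != keep]) parent[rt] <- keep
    }
  }
  # resolve equivalences, then relabel by first occurrence in raster order
  roots <- vapply(seq_len(nlab), find, integer(1))
  flat <- roots[lab[cbind(fg[, 1], fg[, 2])]]
  new_id <- integer(nlab)
  nxt <- 0L
  for (k in seq_along(flat)) {
    if (new_id[flat[k]] == 0L) { nxt <- nxt + 1L; new_id[flat[k]] <- nxt }
  }
  lab[cbind(fg[, 1], fg[, 2])] <- new_id[flat]
  lab
}

#' Segment integrin clusters from a calibrated image
#'
#' Thresholds the integrin channel (pixels strictly above the threshold are
#' foreground), labels connected components, and discards components whose
#' calibrated area is below `min_area_um2` (the filter is inclusive: a
#' component of exactly `min_area_um2` is kept). Surviving components are
#' relabeled consecutively in raster-scan order.
#'
#' @param image An [intensity_image].
#' @param threshold Numeric intensity threshold, or `"auto"` for Otsu on the
#'   integrin channel.
#' @param connectivity 4 or 8 (default 8, the convention under which
#'   pixel-count size statements for small clusters hold).
#' @param min_area_um2 Minimum retained cluster area in um^2.
#' @return An object of class `labeled_clusters`: list with `pixels` (list
#'   of n x 2 matrices of (row, col)), `label_matrix`, `threshold`,
#'   `connectivity`, `pixel_area_um2`.
#' @export
segment_clusters <- function(image, threshold = "auto", connectivity = 8,
                             min_area_um2 = 0.02) {
  stopifnot(inherits(image, "intensity_image"))
  if (identical(threshold, "auto"))
    threshold <- auto_threshold(image$integrin, "otsu")
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  mask <- image$integrin > threshold
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  pixels <- list()
  if (n > 0L) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    ids <- lab[idx]
    min_px <- ceiling(min_area_um2 / image$pixel_area_um2 - 1e-9)
    keep_id <- which(tabulate(ids, n) >= min_px)
    relab <- matrix(0L, nrow(lab), ncol(lab))
    for (new in seq_along(keep_id)) {
      sel <- idx[ids == keep_id[new], , drop = FALSE]
      colnames(sel) <- c("row", "col")
      pixels[[new]] <- sel
      relab[sel] <- new
    }
    lab <- relab
  }
  structure(
    list(pixels = pixels, label_matrix = lab, threshold = threshold,
         connectivity = connectivity, pixel_area_um2 = image$pixel_area_um2,
         condition_label = image$condition_label, cell_id = image$cell_id),
    class = "labeled_clusters")
}

#' @export
print.labeled_clusters <- function(x, ...) {
  cat(sprintf(
    "%d integrin clusters (threshold %.1f, connectivity %d, >= %s px)\n",
    length(x$pixels), x$threshold, x$connectivity,
    if (length(x$pixels)) min(vapply(x$pixels, nrow, integer(1))) else "-"))
  invisible(x)
}

#' Segment the cell body and extract its geometry
#'
#' Thresholds the per-pixel maximum of the integrin and cytoskeleton
#' channels, applies morphological closing (dilation then erosion with a
#' disk structuring element) to bridge gaps between stress-fiber remnants,
#' fills remaining interior holes, and keeps the largest connected
#' component. The result is a single filled region from which the cell
#' centroid, area, and ordered boundary are computed.
#'
#' @param image An [intensity_image].
#' @param threshold Numeric threshold or `"auto"` (Otsu on the fused
#'   channel).
#' @param closing_radius_px Radius of the disk structuring element.
#' @return A `cell_geometry` object.
#' @export
segment_cell_body <- function(image, threshold = "auto",
                              closing_radius_px = 5) {
  stopifnot(inherits(image, "intensity_image"))
  fused <- pmax(image$integrin, image$actin)
  if (identical(threshold, "auto"))
    threshold <- auto_threshold(fused, "otsu")
  mask <- fused > threshold
  if (!any(mask))
    stop(sprintf("cell body segmentation failed for '%s': no pixel above threshold %.1f",
                 image$cell_id, threshold))
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                                shape = "disc")
    mask <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
  }
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  counts <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(counts)
  geom <- cell_geometry(mask, image$pixel_area_um2)
  geom$threshold <- threshold
  geom$cell_id <- image$cell_id
  geom
}
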