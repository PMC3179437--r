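#' Calibrated two-channel intensity image for one cell
#'
#' @param integrin,actin Integer matrices (0-255), same shape; rows = y.
#' @param pixel_area_um2 Area of one pixel in um^2.
#' @param condition_label Condition label, e.g. `"20 ug/mL"`.
#' @param cell_id Cell identifier.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(integrin, actin, pixel_area_um2,
                            condition_label = "", cell_id = "") {
  stopifnot(is.matrix(integrin), is.matrix(actin),
            all(dim(integrin) == dim(actin)))
  if (pixel_area_um2 <= 0) stop("'pixel_area_um2' must be positive")
  rng <- range(integrin, actin)
  if (rng[1] < 0 || rng[2] > 255)
    stop("channel intensities must lie in [0, 255]")
  structure(
    list(integrin = integrin, actin = actin,
         pixel_area_um2 = pixel_area_um2,
         condition_label = condition_label, cell_id = cell_id),
    class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf(
    "Intensity image '%s' / '%s': %d x %d px, %.3g um^2/px\n",
    x$condition_label, x$cell_id, nrow(x$integrin), ncol(x$integrin),
    x$pixel_area_um2))
  invisible(x)
}
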