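#' Default pipeline configuration
#'
#' All tunables of the segmentation and analysis stages with their
#' defaults:
#' \describe{
#'   \item{pixel_area_um2}{0.02 um^2/px (about 0.141 um/px), under which a
#'     0.1 um^2 cluster spans 5 pixels.}
#'   \item{cluster_threshold}{127: half of the synthetic peak amplitude,
#'     which recovers the true footprint of Gaussian-profile spots. Use
#'     `"auto"` (Otsu) or an explicit per-dataset value for real images.}
#'   \item{cell_threshold}{`"auto"` (Otsu on the fused channels).}
#'   \item{connectivity}{8.}
#'   \item{closing_radius_px}{5, disk structuring element.}
#'   \item{min_area_um2}{0.02, inclusive minimum cluster area.}
#'   \item{location_min_area}{0.5, strict filter for the gamma location
#'     fit.}
#'   \item{shape_min_area}{0.1, inclusive filter for the beta shape fit.}
#'   \item{size_bin_edges}{c(0.1, 0.2, 0.3, 0.4, 0.6, 1.0) um^2 for the
#'     size-stratified shape table.}
#'   \item{seed}{1.}
#' }
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    pixel_area_um2 = 0.02,
    cluster_threshold = 127,
    cell_threshold = "auto",
    connectivity = 8L,
    closing_radius_px = 5L,
    min_area_um2 = 0.02,
    location_min_area = 0.5,
    shape_min_area = 0.1,
    size_bin_edges = c(0.1, 0.2, 0.3, 0.4, 0.6, 1.0),
    seed = 1L), class = "run_config")
}

#' Resolve and validate a pipeline configuration
#'
#' Merges a partial configuration (list or YAML file path) over
#' [default_config]. Unknown keys are rejected rather than silently
#' ignored.
#'
#' @param config A named list of overrides, a path to a YAML file, or a
#'   complete `run_config`.
#' @return A validated `run_config`.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_config()
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(config)) base[[nm]] <- config[[nm]]

  with(base, {
    stopifnot(pixel_area_um2 > 0,
              connectivity %in% c(4, 8),
              closing_radius_px >= 0,
              min_area_um2 >= 0, location_min_area >= 0,
              shape_min_area >= 0,
              length(size_bin_edges) >= 2)
    if (!identical(cluster_threshold, "auto"))
      stopifnot(is.numeric(cluster_threshold))
    if (!identical(cell_threshold, "auto"))
      stopifnot(is.numeric(cell_threshold))
  })
  base
}
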