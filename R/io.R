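#' Read a single-cell TIFF as a calibrated two-channel image
#'
#' Accepts 8-bit RGB TIFFs (red = integrin, green = cytoskeleton, blue
#' ignored) or two-page grayscale TIFFs (page 1 = integrin, page 2 =
#' cytoskeleton). Non-8-bit files are rejected with a message naming the
#' bit depth.
#'
#' @param path TIFF file path.
#' @param pixel_area_um2 Pixel calibration in um^2.
#' @param condition_label,cell_id Labels attached to the image.
#' @return An [intensity_image] with integer 0-255 channels.
#' @export
read_cell_image <- function(path, pixel_area_um2,
                            condition_label = "", cell_id = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- tiff::readTIFF(path, payload = FALSE)
  bits <- if (is.data.frame(info)) info$bits.per.sample[1] else info$bits.per.sample
  if (!identical(as.integer(bits), 8L))
    stop(sprintf("'%s' is a %d-bit TIFF; only 8-bit images are supported",
                 path, as.integer(bits)))
  pages <- tiff::readTIFF(path, all = TRUE)
  to_int <- function(m) matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  first <- pages[[1]]
  if (length(dim(first)) == 3 && dim(first)[3] >= 3) {
    integrin <- to_int(first[, , 1])
    actin <- to_int(first[, , 2])
  } else if (length(pages) >= 2) {
    g1 <- if (length(dim(pages[[1]])) == 3) pages[[1]][, , 1] else pages[[1]]
    g2 <- if (length(dim(pages[[2]])) == 3) pages[[2]][, , 1] else pages[[2]]
    integrin <- to_int(g1)
    actin <- to_int(g2)
  } else {
    stop(sprintf("'%s' has a single grayscale channel; need RGB or two pages",
                 path))
  }
  intensity_image(integrin, actin, pixel_area_um2, condition_label, cell_id)
}

#' Write a two-channel image as an 8-bit RGB TIFF
#'
#' Red = integrin, green = cytoskeleton, blue = 0. Inverse of
#' [read_cell_image] up to the empty blue channel.
#'
#' @param image An [intensity_image].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cell_image <- function(image, path) {
  stopifnot(inherits(image, "intensity_image"))
  arr <- array(0, c(dim(image$integrin), 3L))
  arr[, , 1] <- image$integrin / 255
  arr[, , 2] <- image$actin / 255
  tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  invisible(path)
}

# CSV writer with fixed numeric formatting (9 significant digits) so that
# reruns with identical inputs produce byte-identical files.
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 9)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read cluster records
#'
#' @param records Data.frame of cluster records ([measure_clusters]).
#' @param path CSV path.
#' @return `write_records` invisibly returns `path`; `read_records`
#'   returns the data.frame.
#' @export
write_records <- function(records, path) write_table_csv(records, path)

#' @rdname write_records
#' @export
read_records <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Serialize a distribution fit to JSON
#'
#' Full-precision round trip of a `dist_fit` (parameters, intervals,
#' method, sample size, goodness, bin specification).
#'
#' @param fit A `dist_fit`.
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dist_fit"))
  x <- unclass(fit)
  x$bin_spec <- if (!is.null(x$bin_spec)) unclass(x$bin_spec) else NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bs <- x$bin_spec
  if (!is.null(bs) && length(bs))
    bs <- structure(list(type = bs$type, n = as.integer(bs$n),
                         range = bs$range), class = "bin_spec")
  else bs <- NULL
  .new_fit(x$family,
           if (is.null(x$alpha)) NA_real_ else x$alpha,
           x$beta_param,
           if (is.null(x$se_alpha)) NA_real_ else x$se_alpha,
           x$se_beta, x$method, as.integer(x$n), x$goodness,
           bin_spec = bs, degenerate = isTRUE(x$degenerate))
}

#' Write all pipeline outputs to a directory
#'
#' @param result The list returned by [run_pipeline].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits_dir <- file.path(out_dir, "fits")
  dir.create(fits_dir, showWarnings = FALSE)
  write_records(result$records, file.path(out_dir, "cluster_records.csv"))
  write_table_csv(result$summaries$summary,
                  file.path(out_dir, "condition_summary.csv"))

  sst <- result$size_shape
  heat_df <- data.frame(ecc_lo = sst$ecc_edges[-length(sst$ecc_edges)],
                        ecc_hi = sst$ecc_edges[-1])
  heat_df <- cbind(heat_df, as.data.frame(sst$heatmap))
  write_table_csv(heat_df, file.path(out_dir, "size_shape_table.csv"))

  safe <- function(s) gsub("[^A-Za-z0-9._-]+", "_", s)
  for (kind in c("size", "location", "shape")) {
    fits <- result$summaries[[kind]]$fits
    for (lab in names(fits)) {
      if (!is.null(fits[[lab]]))
        write_fit_json(fits[[lab]],
                       file.path(fits_dir,
                                 sprintf("%s_%s.json", kind, safe(lab))))
    }
  }
  jsonlite::write_json(unclass(result$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
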