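#' Parse the numeric coating concentration from a condition label
#'
#' Extracts the leading numeric value of labels like `"20 ug/mL"` or
#' `"2 ug/mL Fg"`; conditions are ordered by this value in all
#' cross-condition tables.
#'
#' @param label Character vector of condition labels.
#' @return Numeric concentrations (NA when no number is present).
#' @export
parse_concentration <- function(label) {
  m <- regexpr("[0-9]*\\.?[0-9]+", label)
  out <- rep(NA_real_, length(label))
  out[m > 0] <- suppressWarnings(as.numeric(regmatches(label, m)))
  out
}

.split_conditions <- function(records) {
  conc <- parse_concentration(unique(records$condition))
  labs <- unique(records$condition)[order(conc)]
  lapply(setNames(labs, labs), function(l)
    records[records$condition == l, , drop = FALSE])
}

#' Cluster-size analysis per condition
#'
#' Fits the lognormal size model by maximum likelihood to all cluster areas
#' of each condition (every segmented cluster >= the segmentation area
#' filter enters the size analysis) and tabulates the fitted scale and
#' shape parameters, the population mean `exp(alpha + beta^2/2)`, and the
#' median `exp(alpha)` across conditions ordered by concentration.
#'
#' @param records Cluster records (see [measure_clusters]) for one or more
#'   conditions.
#' @return List with `fits` (named list of `dist_fit`) and `table`, a
#'   data.frame with one row per condition: `condition`, `concentration`,
#'   `n`, `alpha`, `beta`, CIs, `mean_um2`, `median_um2`.
#' @export
size_analysis <- function(records) {
  by_cond <- .split_conditions(records)
  fits <- lapply(by_cond, function(d) fit_mle("lognormal", d$area_um2))
  table <- data.frame(
    condition = names(fits),
    concentration = parse_concentration(names(fits)),
    n = vapply(fits, function(f) f$n, integer(1)),
    alpha = vapply(fits, function(f) f$alpha, numeric(1)),
    beta = vapply(fits, function(f) f$beta_param, numeric(1)),
    alpha_lo = vapply(fits, function(f) f$ci95_alpha[1], numeric(1)),
    alpha_hi = vapply(fits, function(f) f$ci95_alpha[2], numeric(1)),
    beta_lo = vapply(fits, function(f) f$ci95_beta[1], numeric(1)),
    beta_hi = vapply(fits, function(f) f$ci95_beta[2], numeric(1)),
    mean_um2 = vapply(fits, expected_value, numeric(1)),
    median_um2 = vapply(fits, median_value, numeric(1)),
    row.names = NULL)
  list(fits = fits, table = table)
}

#' Cluster-location analysis per condition
#'
#' Restricts to clusters strictly larger than `min_area_um2` (the
#' unrestricted population shows no clear location trend), fits the gamma
#' model to normalized edge distances by histogram least squares, and
#' reports the fitted mean `alpha * beta`. Separately reports the
#' arithmetic mean normalized center distance over all clusters of the
#' condition (no size filter), a complementary periphery measure that grows
#' as clusters move outward.
#'
#' Conditions with fewer than 50 filtered clusters are skipped with a
#' warning and appear in the table with NA fit columns.
#'
#' @param records Cluster records.
#' @param min_area_um2 Strict lower area bound for the gamma fit
#'   (default 0.5).
#' @param spec [bin_spec] for the edge-distance histogram (default 25
#'   linear bins on \[0, 1\]).
#' @return List with `fits` and `table` (`condition`, `concentration`,
#'   `n_filtered`, `alpha`, `beta`, CIs, `mean_edge_dist` = alpha*beta,
#'   `center_dist_mean`).
#' @export
location_analysis <- function(records, min_area_um2 = 0.5,
                              spec = bin_spec("linear", 25L, c(0, 1))) {
  by_cond <- .split_conditions(records)
  fits <- vector("list", length(by_cond))
  names(fits) <- names(by_cond)
  rows <- vector("list", length(by_cond))
  for (i in seq_along(by_cond)) {
    d <- by_cond[[i]]
    filt <- d[d$area_um2 > min_area_um2, , drop = FALSE]
    fit <- NULL
    if (nrow(filt) >= 50L) {
      fit <- fit_lsq("gamma", filt$edge_dist_norm, spec = spec)
    } else {
      warning(sprintf(
        "condition '%s' skipped in location analysis: only %d clusters > %.2f um^2",
        names(by_cond)[i], nrow(filt), min_area_um2))
    }
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      condition = names(by_cond)[i],
      concentration = parse_concentration(names(by_cond)[i]),
      n_filtered = nrow(filt),
      alpha = if (is.null(fit)) NA_real_ else fit$alpha,
      beta = if (is.null(fit)) NA_real_ else fit$beta_param,
      alpha_lo = if (is.null(fit)) NA_real_ else fit$ci95_alpha[1],
      alpha_hi = if (is.null(fit)) NA_real_ else fit$ci95_alpha[2],
      beta_lo = if (is.null(fit)) NA_real_ else fit$ci95_beta[1],
      beta_hi = if (is.null(fit)) NA_real_ else fit$ci95_beta[2],
      mean_edge_dist = if (is.null(fit)) NA_real_ else expected_value(fit),
      center_dist_mean = mean(d$center_dist_norm))
  }
  list(fits = fits, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Cluster-shape analysis per condition
#'
#' Excludes clusters smaller than `min_area_um2` (their few pixels only
#' allow a handful of discrete eccentricity values, which would skew the
#' distribution), fits the beta model to eccentricities by histogram least
#' squares, and reports the fitted mean `alpha / (alpha + beta)`.
#'
#' @param records Cluster records.
#' @param min_area_um2 Inclusive lower area bound (default 0.1; clusters
#'   with area >= 0.1 um^2 are kept).
#' @param spec [bin_spec] for the eccentricity histogram.
#' @return List with `fits` and `table` (`condition`, `concentration`,
#'   `n_filtered`, `alpha`, `beta`, CIs, `mean_ecc`).
#' @export
shape_analysis <- function(records, min_area_um2 = 0.1,
                           spec = bin_spec("linear", 25L, c(0, 1))) {
  by_cond <- .split_conditions(records)
  fits <- vector("list", length(by_cond))
  names(fits) <- names(by_cond)
  rows <- vector("list", length(by_cond))
  for (i in seq_along(by_cond)) {
    d <- by_cond[[i]]
    filt <- d[d$area_um2 >= min_area_um2, , drop = FALSE]
    fit <- NULL
    if (nrow(filt) >= 50L) {
      fit <- fit_lsq("beta", filt$eccentricity, spec = spec)
    } else {
      warning(sprintf(
        "condition '%s' skipped in shape analysis: only %d clusters >= %.2f um^2",
        names(by_cond)[i], nrow(filt), min_area_um2))
    }
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      condition = names(by_cond)[i],
      concentration = parse_concentration(names(by_cond)[i]),
      n_filtered = nrow(filt),
      alpha = if (is.null(fit)) NA_real_ else fit$alpha,
      beta = if (is.null(fit)) NA_real_ else fit$beta_param,
      alpha_lo = if (is.null(fit)) NA_real_ else fit$ci95_alpha[1],
      alpha_hi = if (is.null(fit)) NA_real_ else fit$ci95_alpha[2],
      beta_lo = if (is.null(fit)) NA_real_ else fit$ci95_beta[1],
      beta_hi = if (is.null(fit)) NA_real_ else fit$ci95_beta[2],
      mean_ecc = if (is.null(fit)) NA_real_ else expected_value(fit))
  }
  list(fits = fits, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Size-stratified eccentricity distributions
#'
#' Assigns clusters to size bins (left-closed, right-open; clusters at or
#' above the last edge are excluded), builds a column-normalized
#' eccentricity histogram per size bin (each column sums to 1), and fits a
#' beta model per bin when it holds at least `min_n_fit` clusters. Rising
#' per-bin means expose the coupling between cluster size and elongation.
#'
#' @param records Cluster records (typically pooled across conditions).
#' @param size_edges Size bin edges in um^2
#'   (default c(0.1, 0.2, 0.3, 0.4, 0.6, 1.0)).
#' @param ecc_spec [bin_spec] for the per-bin eccentricity histograms.
#' @param min_n_fit Minimum clusters per bin for a beta fit (default 30;
#'   smaller bins are reported histogram-only with NA fit columns).
#' @return A `size_shape_table`: list with `size_edges`, `bin_labels`,
#'   `heatmap` (eccentricity-bin x size-bin matrix, columns summing to 1),
#'   `ecc_edges`, `fits` (list of `dist_fit` or NULL), and `table`
#'   (per-bin n, alpha, beta, mean_ecc).
#' @export
shape_by_size <- function(records,
                          size_edges = c(0.1, 0.2, 0.3, 0.4, 0.6, 1.0),
                          ecc_spec = bin_spec("linear", 25L, c(0, 1)),
                          min_n_fit = 30L) {
  stopifnot(length(size_edges) >= 2L, !is.unsorted(size_edges))
  nb <- length(size_edges) - 1L
  labels <- sprintf("%.1f-%.1f", size_edges[-length(size_edges)],
                    size_edges[-1])
  bin_of <- findInterval(records$area_um2, size_edges,
                         rightmost.closed = FALSE, left.open = FALSE)
  bin_of[records$area_um2 >= size_edges[length(size_edges)]] <- NA
  bin_of[bin_of < 1L] <- NA

  ecc_hist_template <- make_histogram(c(0, 1), ecc_spec)
  heat <- matrix(0, length(ecc_hist_template$counts), nb,
                 dimnames = list(NULL, labels))
  fits <- vector("list", nb)
  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    ecc <- records$eccentricity[!is.na(bin_of) & bin_of == b]
    cnt <- .bincount(ecc, ecc_hist_template$edges)
    heat[, b] <- if (sum(cnt) > 0) cnt / sum(cnt) else 0
    fit <- NULL
    # fit through the histogram path: the per-bin minimum is lower than the
    # raw-data minimum of fit_lsq because the histogram is already in hand
    if (length(ecc) >= min_n_fit)
      fit <- fit_lsq("beta", histogram = make_histogram(ecc, ecc_spec))
    fits[[b]] <- fit
    rows[[b]] <- data.frame(
      size_bin = labels[b], n = length(ecc),
      alpha = if (is.null(fit)) NA_real_ else fit$alpha,
      beta = if (is.null(fit)) NA_real_ else fit$beta_param,
      mean_ecc = if (is.null(fit)) NA_real_ else expected_value(fit))
  }
  structure(
    list(size_edges = size_edges, bin_labels = labels, heatmap = heat,
         ecc_edges = ecc_hist_template$edges, fits = fits,
         table = do.call(rbind, c(rows, make.row.names = FALSE))),
    class = "size_shape_table")
}

#' Per-condition summary of all cluster analyses
#'
#' Combines the size, location, and shape analyses with cluster counts and
#' the total bound-integrin area per cell into one row per condition.
#'
#' @param records Cluster records for all conditions.
#' @param cells_per_condition Optional named integer vector giving the
#'   number of cells analysed per condition (defaults to distinct cell ids
#'   present in the records).
#' @param location_min_area,shape_min_area Area filters passed through to
#'   [location_analysis] and [shape_analysis].
#' @return List with `summary` (data.frame, one row per condition) and the
#'   three analysis objects (`size`, `location`, `shape`).
#' @export
condition_summaries <- function(records, cells_per_condition = NULL,
                                location_min_area = 0.5,
                                shape_min_area = 0.1) {
  size <- size_analysis(records)
  location <- location_analysis(records, location_min_area)
  shape <- shape_analysis(records, shape_min_area)
  labs <- size$table$condition
  n_cells <- vapply(labs, function(l) {
    if (!is.null(cells_per_condition) && l %in% names(cells_per_condition))
      as.integer(cells_per_condition[[l]])
    else length(unique(records$cell_id[records$condition == l]))
  }, integer(1))
  total_area <- vapply(seq_along(labs), function(i)
    total_bound_area(records[records$condition == labs[i], ], n_cells[i]),
    numeric(1))
  summary <- data.frame(
    condition = labs,
    concentration = size$table$concentration,
    n_cells = n_cells,
    n_clusters = size$table$n,
    size_alpha = size$table$alpha, size_beta = size$table$beta,
    size_mean_um2 = size$table$mean_um2,
    size_median_um2 = size$table$median_um2,
    loc_alpha = location$table$alpha, loc_beta = location$table$beta,
    loc_mean_edge_dist = location$table$mean_edge_dist,
    center_dist_mean = location$table$center_dist_mean,
    shape_alpha = shape$table$alpha, shape_beta = shape$table$beta,
    shape_mean_ecc = shape$table$mean_ecc,
    total_area_per_cell_um2 = total_area,
    clusters_per_cell = size$table$n / n_cells,
    row.names = NULL)
  list(summary = summary, size = size, location = location, shape = shape)
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Reads every cell image of every condition (layout as written by
#' [generate_condition_dataset]: one sub-directory per condition plus a
#' `manifest.json`, or any directory of per-condition sub-directories of
#' 8-bit TIFFs), segments the cell body and the integrin clusters, measures
#' every cluster, and runs the size, location, shape, and size-shape
#' analyses. Per-cell segmentation failures are logged and skipped; the run
#' aborts only if a condition loses more than half of its cells.
#'
#' @param input_dir Dataset directory.
#' @param config Run configuration, see [default_config].
#' @param out_dir Optional output directory; when given, writes
#'   `cluster_records.csv`, `condition_summary.csv`,
#'   `size_shape_table.csv`, per-condition fit JSONs under `fits/`,
#'   `run_log.txt`, and the resolved `config.json`.
#' @return List with `records`, `summaries` (see [condition_summaries]),
#'   `size_shape`, `model_comparison` (lognormal vs exponential on the
#'   pooled sizes), and `log` (character vector).
#' @export
run_pipeline <- function(input_dir, config = default_config(),
                         out_dir = NULL) {
  config <- resolve_config(config)
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  conds <- .discover_conditions(input_dir)
  if (length(conds) == 0L)
    stop("no condition sub-directories with TIFF images under ", input_dir)

  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  say("pipeline start: %d condition(s), pixel area %.3g um^2/px",
      length(conds), config$pixel_area_um2)

  all_records <- list()
  cells_per_condition <- integer(0)
  for (label in names(conds)) {
    tiffs <- conds[[label]]
    n_ok <- 0L
    for (path in tiffs) {
      cid <- sub("\\.tiff?$", "", basename(path))
      rec <- tryCatch({
        img <- read_cell_image(path, config$pixel_area_um2,
                               condition_label = label, cell_id = cid)
        cell <- segment_cell_body(img, config$cell_threshold,
                                  config$closing_radius_px)
        clus <- segment_clusters(img, config$cluster_threshold,
                                 config$connectivity, config$min_area_um2)
        measure_clusters(img, cell, clus)
      }, error = function(e) {
        say("  SKIP %s/%s: %s", label, cid, conditionMessage(e))
        NULL
      })
      if (!is.null(rec)) {
        n_ok <- n_ok + 1L
        all_records[[length(all_records) + 1L]] <- rec
      }
    }
    if (n_ok < length(tiffs) / 2)
      stop(sprintf("condition '%s' lost more than half of its cells (%d/%d usable)",
                   label, n_ok, length(tiffs)))
    cells_per_condition[label] <- n_ok
    say("condition '%s': %d/%d cells segmented", label, n_ok, length(tiffs))
  }
  records <- do.call(rbind, c(all_records, make.row.names = FALSE))
  say("measured %d clusters in total", nrow(records))

  summaries <- condition_summaries(
    records, cells_per_condition,
    location_min_area = config$location_min_area,
    shape_min_area = config$shape_min_area)
  size_shape <- shape_by_size(records, config$size_bin_edges)
  comparison <- compare_models(records$area_um2)
  say("pooled size model comparison: best = %s", comparison$best)

  result <- list(records = records, summaries = summaries,
                 size_shape = size_shape, model_comparison = comparison,
                 config = config, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

.discover_conditions <- function(input_dir) {
  manifest_path <- file.path(input_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path)
    out <- lapply(manifest$conditions, function(ci)
      sort(list.files(file.path(input_dir, ci$directory),
                      pattern = "\\.tiff?$", full.names = TRUE)))
    return(out[order(parse_concentration(names(out)))])
  }
  dirs <- list.dirs(input_dir, recursive = FALSE)
  out <- lapply(setNames(dirs, basename(dirs)), function(d)
    sort(list.files(d, pattern = "\\.tiff?$", full.names = TRUE)))
  out <- out[vapply(out, length, integer(1)) > 0]
  out[order(parse_concentration(names(out)))]
}
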