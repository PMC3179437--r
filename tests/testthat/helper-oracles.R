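# Independent brute-force oracles and small fixture builders shared by the
# test files. These deliberately use the most naive possible algorithms so
# they stay independent of the package implementation.

# Connected components by breadth-first flood fill. Returns a list of
# pixel-index sets (sorted linear indices), one per component, in no
# particular order.
flood_fill_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    moves <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                   dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    moves <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  comps <- list()
  queue <- integer(sum(mask))
  for (start in which(mask)) {
    if (seen[start]) next
    head <- 1L; tail <- 1L
    queue[1L] <- start
    seen[start] <- TRUE
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (m in seq_len(nrow(moves))) {
        rr <- r + moves[m, 1]; cc <- c + moves[m, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          tail <- tail + 1L
          queue[tail] <- (cc - 1L) * nr + rr
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(queue[seq_len(tail)])
  }
  comps
}

# Second-central-moment eccentricity by explicit double loop over pixel
# pairs of sums; no vectorization, no shared code with the package.
ecc_oracle <- function(pixels) {
  n <- nrow(pixels)
  mr <- 0; mc <- 0
  for (i in seq_len(n)) { mr <- mr + pixels[i, 1]; mc <- mc + pixels[i, 2] }
  mr <- mr / n; mc <- mc / n
  srr <- 0; scc <- 0; src <- 0
  for (i in seq_len(n)) {
    dr <- pixels[i, 1] - mr; dc <- pixels[i, 2] - mc
    srr <- srr + dr * dr; scc <- scc + dc * dc; src <- src + dr * dc
  }
  srr <- srr / n + 1 / 12; scc <- scc / n + 1 / 12; src <- src / n
  disc <- sqrt((srr - scc)^2 + 4 * src^2)
  l1 <- (srr + scc + disc) / 2
  l2 <- (srr + scc - disc) / 2
  sqrt(max(0, 1 - l2 / l1))
}

# Random connected-ish binary mask (independent Bernoulli pixels).
random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Random blob of pixels: a filled random-radius disk plus jitter pixels.
random_pixel_blob <- function(max_extent = 12L) {
  r <- sample(1:max_extent, 1)
  cx <- sample(20:40, 2)
  grid <- as.matrix(expand.grid(row = (cx[1] - r):(cx[1] + r),
                                col = (cx[2] - r):(cx[2] + r)))
  d <- sqrt((grid[, 1] - cx[1])^2 + ((grid[, 2] - cx[2]) / runif(1, 0.3, 1))^2)
  blob <- grid[d <= r, , drop = FALSE]
  if (nrow(blob) == 0L) blob <- matrix(cx, 1, 2)
  blob
}

# A perfect-disk cell geometry centered in a square image.
make_disk_cell <- function(radius_px, margin = 8L, pixel_area_um2 = 0.02) {
  n <- 2L * (radius_px + margin) + 1L
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  mask <- sqrt((rows - ctr)^2 + (cols - ctr)^2) <= radius_px
  integrinclust:::cell_geometry(mask, pixel_area_um2)
}

# Default synthetic population used across tests (one mid-density
# condition).
test_params <- function(n = 150, coupling = 0) {
  population_params(size_alpha = -1.4, size_beta = 0.9,
                    ecc_alpha = 7, ecc_beta = 1.6,
                    loc_alpha = 2, loc_beta = 0.12,
                    n_clusters_per_cell = n,
                    size_ecc_coupling = coupling)
}

# Render one fully segmented + measured synthetic cell; returns records,
# truth, and the intermediate objects.
measured_cell <- function(seed, n_clusters = 150, snr = 20,
                          params = test_params(n_clusters),
                          threshold = 127) {
  cell <- generate_cell_mask(seed, boundary_roughness = 0.2)
  clus <- sample_cluster_population(params, seed + 1000L)
  ren <- render_image(cell, clus, pixel_area_um2 = 0.02, snr = snr,
                      rng_seed = seed + 2000L,
                      condition_label = "20 ug/mL",
                      cell_id = sprintf("cell_%03d", seed))
  body <- segment_cell_body(ren$image)
  labeled <- segment_clusters(ren$image, threshold = threshold)
  records <- measure_clusters(ren$image, body, labeled)
  list(cell = cell, clusters = clus, render = ren, body = body,
       labeled = labeled, records = records)
}
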