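# Shared ray-marching primitive for radial location metrics and cluster
# placement. The edge point along a ray is defined operationally: starting
# from the cell centroid, sample every 0.25 px along the ray and take the
# last inside-mask sample before the first inside->outside transition
# ("first exit" rule). On star-convex masks there is exactly one exit; on
# irregular real masks the rule makes the metric deterministic.

RAY_STEP_PX <- 0.25

# direction: unit vector c(dy, dx). Returns list(d_ce, edge_point) where
# edge_point is the (row, col) of the last inside sample.
.ray_march <- function(mask, origin, direction) {
  nr <- nrow(mask); nc <- ncol(mask)
  # maximum useful distance: to the image border along this ray
  tmax <- sqrt(nr^2 + nc^2)
  t <- seq(RAY_STEP_PX, tmax, by = RAY_STEP_PX)
  rr <- round(origin[1] + t * direction[1])
  cc <- round(origin[2] + t * direction[2])
  inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  inside[inside] <- mask[cbind(rr[inside], cc[inside])]
  first_out <- which(!inside)[1]
  if (is.na(first_out)) first_out <- length(t) + 1L
  if (first_out == 1L) {
    # origin is on the boundary already; treat origin itself as edge point
    return(list(d_ce = 0, edge_point = origin))
  }
  k <- first_out - 1L
  list(d_ce = t[k],
       edge_point = c(origin[1] + t[k] * direction[1],
                      origin[2] + t[k] * direction[2]))
}

# Distance from the cell centroid to the mask edge along angle theta
# (theta in image convention: dy = sin, dx = cos).
.ray_edge_at_angle <- function(cell, theta) {
  .ray_march(cell$mask, cell$centroid, c(sin(theta), cos(theta)))$d_ce
}
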