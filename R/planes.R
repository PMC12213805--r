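#' Analysis plane
#'
#' A plane used to cut vessel cross-sections, defined by an origin and a unit
#' normal in world coordinates (mm, origin at the volume corner).  Two
#' orthonormal in-plane basis vectors are attached for sampling.
#'
#' @param origin numeric length-3, plane origin (mm).
#' @param normal numeric length-3, plane normal (any nonzero length).
#' @return a list of class `analysis_plane` with `origin`, `normal`, `u`, `v`.
#' @export
analysis_plane <- function(origin, normal) {
  n <- sqrt(sum(normal^2))
  if (n == 0) stop_pahemo("Plane normal must be nonzero.")
  normal <- normal / n
  seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(
    normal[2] * u[3] - normal[3] * u[2],
    normal[3] * u[1] - normal[1] * u[3],
    normal[1] * u[2] - normal[2] * u[1]
  )
  structure(list(origin = as.numeric(origin), normal = normal, u = u, v = v),
            class = "analysis_plane")
}

#' @export
print.analysis_plane <- function(x, ...) {
  cat(sprintf("<analysis_plane> origin (%.1f, %.1f, %.1f) mm, normal (%.2f, %.2f, %.2f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

# Regular in-plane sampling grid: points (mm, n x 3), in-plane coordinates
# and the area element (mm^2).
plane_grid <- function(plane, half_extent_mm, spacing_mm) {
  g <- seq(-half_extent_mm, half_extent_mm, by = spacing_mm)
  uv <- as.matrix(expand.grid(a = g, b = g, KEEP.OUT.ATTRS = FALSE))
  pts <- matrix(plane$origin, nrow(uv), 3, byrow = TRUE) +
    uv[, 1] %o% plane$u + uv[, 2] %o% plane$v
  list(points = pts, uv = uv, area_mm2 = spacing_mm^2)
}

# Continuous (1-based) voxel indices of world points (mm).
world_to_index <- function(points_mm, origin_mm, spacing_mm) {
  sweep(sweep(points_mm, 2, origin_mm), 2, spacing_mm, `/`) + 1
}

# Vectorised trilinear interpolation of a 3D array at continuous 1-based
# voxel indices (n x 3).  Points outside the volume return `fill`.
trilinear <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  out <- rep(fill, nrow(idx))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (!any(ok)) return(out)
  p <- idx[ok, , drop = FALSE]
  i0 <- pmin(floor(p), matrix(d - 1L, nrow(p), 3, byrow = TRUE))
  f <- p - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    acc <- acc + w * arr[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out[ok] <- acc
  out
}

# Nearest-neighbour lookup of a 3D array at continuous indices.
nearest_voxel <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  i <- round(idx)
  out <- rep(fill, nrow(idx))
  ok <- i[, 1] >= 1 & i[, 1] <= d[1] & i[, 2] >= 1 & i[, 2] <= d[2] &
    i[, 3] >= 1 & i[, 3] <= d[3]
  out[ok] <- arr[i[ok, , drop = FALSE]]
  out
}
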