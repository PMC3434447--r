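#' Regular 3D scalar grid
#'
#' The lattice container used for MLP and EP fields and for the OpenDX
#' payload: an origin (position of node `[1,1,1]`, in Angstrom), per-axis
#' spacing (Angstrom per cell) and node counts, plus a `counts`-shaped array
#' of values. MLP values are dimensionless; EP values are in kT/e unless
#' labeled otherwise (see [load_ep_grid()]).
#'
#' @param origin numeric length-3, Angstrom.
#' @param spacing numeric length-3 (or scalar, recycled), Angstrom per cell,
#'   all positive.
#' @param counts integer length-3 node counts, each at least 2.
#' @param values numeric array of dimension `counts` (a vector of matching
#'   length is reshaped).
#' @return an object of class `scalar_grid`.
#' @export
scalar_grid <- function(origin, spacing, counts, values) {
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(as.numeric(spacing), 3L)
  spacing <- as.numeric(spacing)
  counts <- as.integer(counts)
  if (length(origin) != 3L || length(spacing) != 3L || length(counts) != 3L)
    stopf("scalar_grid: origin, spacing and counts must have length 3")
  if (any(!is.finite(origin))) stopf("scalar_grid: non-finite origin")
  if (any(spacing <= 0)) stopf("scalar_grid: spacing must be > 0")
  if (any(counts < 2L)) stopf("scalar_grid: counts must be >= 2 on each axis")
  if (length(values) != prod(counts))
    stopf("scalar_grid: values length %d != product of counts %d",
          length(values), prod(counts))
  values <- array(as.numeric(values), dim = counts)
  structure(list(origin = origin, spacing = spacing, counts = counts,
                 values = values),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("scalar_grid: %d x %d x %d nodes, spacing %.3g/%.3g/%.3g A\n",
              x$counts[1], x$counts[2], x$counts[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) A, value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# upper corner of the grid box (position of the last node)
grid_upper <- function(grid) grid$origin + (grid$counts - 1L) * grid$spacing

# grid geometry covering a set of points with symmetric padding
grid_geometry_for <- function(points, spacing, padding) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  lo <- apply(points, 2, min) - padding
  hi <- apply(points, 2, max) + padding
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(origin = lo, spacing = spacing, counts = counts)
}

# Trilinear interpolation of one or more node-value arrays at arbitrary
# points. `arrays` is a list of counts-shaped arrays sharing the grid
# geometry; returns an n x length(arrays) matrix.
trilinear <- function(geom, arrays, points, context = "point") {
  pts <- matrix(as.numeric(points), ncol = 3L)
  n <- geom$counts
  u <- sweep(sweep(pts, 2, geom$origin, "-"), 2, geom$spacing, "/")
  tol <- 1e-9
  bad <- which(u[, 1] < -tol | u[, 2] < -tol | u[, 3] < -tol |
               u[, 1] > n[1] - 1 + tol | u[, 2] > n[2] - 1 + tol |
               u[, 3] > n[3] - 1 + tol)
  if (length(bad))
    stopf("trilinear interpolation: %s %d at (%.3f, %.3f, %.3f) lies outside the grid box",
          context, bad[1], pts[bad[1], 1], pts[bad[1], 2], pts[bad[1], 3])
  u <- pmin(pmax(u, 0), matrix(rep(n - 1, each = nrow(u)), ncol = 3L))
  i0 <- pmin(floor(u), matrix(rep(n - 2, each = nrow(u)), ncol = 3L))
  f <- u - i0
  i0 <- i0 + 1  # 1-based lower corner
  sx <- 1L; sy <- n[1]; sz <- n[1] * n[2]
  base <- (i0[, 1] - 1) * sx + (i0[, 2] - 1) * sy + (i0[, 3] - 1) * sz + 1
  out <- matrix(0, nrow(u), length(arrays))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- base + dx * sx + dy * sy + dz * sz
    for (k in seq_along(arrays)) out[, k] <- out[, k] + w * arrays[[k]][idx]
  }
  out
}

#' Interpolate a scalar grid at arbitrary points
#'
#' Trilinear interpolation: the weighted average of the 8 lattice nodes
#' enclosing each query point. Exact at grid nodes and for affine fields.
#' Points outside the grid box raise an error (no extrapolation).
#'
#' @param grid a [scalar_grid()].
#' @param points n x 3 matrix (or length-3 vector) of positions, Angstrom.
#' @return numeric vector of interpolated values.
#' @export
grid_interpolate <- function(grid, points) {
  drop(trilinear(grid, list(grid$values), points))
}

#' Gradient of a scalar grid
#'
#' Converts an EP (or any scalar) grid into a grid of gradient vectors:
#' central differences over 2*spacing at interior nodes, one-sided
#' differences at boundary nodes. The gradient of a constant grid is zero,
#' and central differencing is exact for quadratic fields at interior nodes.
#'
#' @param grid a [scalar_grid()] with at least 2 nodes per axis (3 or more
#'   for any interior central differences to exist).
#' @return an object of class `vector_grid` with components `vx`, `vy`, `vz`
#'   (field units per Angstrom) on the same lattice.
#' @export
gradient_grid <- function(grid) {
  stopifnot(inherits(grid, "scalar_grid"))
  n <- grid$counts
  if (any(n < 2L)) stopf("gradient_grid: needs at least 2 nodes per axis")
  v <- grid$values
  h <- grid$spacing
  d_axis <- function(axis) {
    nk <- n[axis]
    g <- array(0, dim = n)
    idx <- function(k) switch(axis,
      `1` = v[k, , , drop = FALSE],
      `2` = v[, k, , drop = FALSE],
      `3` = v[, , k, drop = FALSE])
    put <- function(g, k, val) {
      if (axis == 1L) g[k, , ] <- val
      else if (axis == 2L) g[, k, ] <- val
      else g[, , k] <- val
      g
    }
    if (nk >= 3L)
      g <- put(g, 2:(nk - 1), (idx(3:nk) - idx(1:(nk - 2))) / (2 * h[axis]))
    g <- put(g, 1L, (idx(2L) - idx(1L)) / h[axis])
    g <- put(g, nk, (idx(nk) - idx(nk - 1L)) / h[axis])
    g
  }
  structure(list(origin = grid$origin, spacing = grid$spacing, counts = n,
                 vx = d_axis(1L), vy = d_axis(2L), vz = d_axis(3L)),
            class = "vector_grid")
}

#' Interpolate a vector grid at arbitrary points
#'
#' @param grid a `vector_grid` from [gradient_grid()].
#' @param points n x 3 matrix or length-3 vector, Angstrom.
#' @return n x 3 matrix of interpolated vectors.
#' @export
vector_grid_interpolate <- function(grid, points) {
  trilinear(grid, list(grid$vx, grid$vy, grid$vz), points)
}
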