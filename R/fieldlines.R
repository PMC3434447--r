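# Electrostatic field lines: EP on the surface, a gradient grid, EP-weighted
# Monte Carlo seed selection on mesh faces, and bidirectional fixed-step
# integration along the normalized gradient with three termination
# conditions (grid boundary, mesh intersection, low field).

#' Seed-selection controls
#'
#' The two user controls of the line-selection stage plus the RNG seed:
#' `minimum_potential` is the absolute surface EP below which no line starts
#' (same units as the EP grid, kT/e for the built-in solver), and
#' `line_density` scales how many lines are drawn per unit of integrated
#' surface potential (lines per eV/Angstrom^2; the kT/e-to-eV conversion is
#' applied at this interface at the parameter temperature).
#'
#' @param minimum_potential threshold on the face |EP| (>= 0).
#' @param line_density lines per eV/Angstrom^2 (>= 0).
#' @param rng_seed integer seed making the Monte Carlo draw reproducible.
#' @return an object of class `seed_controls`.
#' @export
seed_controls <- function(minimum_potential = 0, line_density = 5,
                          rng_seed = 1L) {
  if (!is_number(minimum_potential) || minimum_potential < 0)
    stopf("seed_controls: minimum_potential must be >= 0 (interpreted on |EP|)")
  if (!is_number(line_density) || line_density < 0)
    stopf("seed_controls: line_density must be >= 0")
  structure(list(minimum_potential = minimum_potential,
                 line_density = line_density,
                 rng_seed = as.integer(rng_seed)),
            class = "seed_controls")
}

#' Monte Carlo selection of field-line seed points
#'
#' Candidate faces are those whose |EP| (mean of the three vertex values)
#' meets `minimum_potential`. The number of seeds is
#' `N = round(line_density * sum |EP_eV| * area)` over candidates (rounding
#' half away from zero), and faces are drawn with replacement with
#' probability proportional to `|EP| * area`, so more lines rise from the
#' more electrically active areas and the total line count is proportional
#' to the global surface potential. Each seed is jittered uniformly within
#' its face. Deterministic for a fixed `rng_seed`; the caller's RNG stream
#' is untouched.
#'
#' @param mesh a [triangle_mesh()] with an `ep` channel.
#' @param controls a [seed_controls()].
#' @param temperature K, for the kT/e-to-eV conversion.
#' @return data.frame with columns `face`, `x`, `y`, `z`, `ep` (0 rows when
#'   nothing qualifies).
#' @export
select_seeds <- function(mesh, controls = seed_controls(), temperature = 298.15) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(controls, "seed_controls"))
  ep <- mesh$channels$ep
  if (is.null(ep)) stopf("select_seeds: mesh has no 'ep' channel")
  face_ep <- (ep[mesh$triangles[, 1]] + ep[mesh$triangles[, 2]] +
              ep[mesh$triangles[, 3]]) / 3
  area <- mesh_face_areas(mesh)
  w <- abs(face_ep) * area
  cand <- which(abs(face_ep) >= controls$minimum_potential & w > 0)
  empty <- data.frame(face = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), ep = numeric(0))
  if (!length(cand)) return(empty)
  total_eV <- sum(w[cand]) * kT_electronvolts(temperature)
  n_seeds <- as.integer(round_half_away(controls$line_density * total_eV))
  if (n_seeds <= 0L) return(empty)
  with_seed(controls$rng_seed, {
    faces <- cand[sample.int(length(cand), n_seeds, replace = TRUE,
                             prob = w[cand])]
    r1 <- sqrt(stats::runif(n_seeds))
    r2 <- stats::runif(n_seeds)
    a <- mesh$vertices[mesh$triangles[faces, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$triangles[faces, 2], , drop = FALSE]
    c_ <- mesh$vertices[mesh$triangles[faces, 3], , drop = FALSE]
    p <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
    data.frame(face = faces, x = p[, 1], y = p[, 2], z = p[, 3],
               ep = face_ep[faces])
  })
}

# --- mesh-intersection acceleration: uniform spatial hash of triangles ----

build_triangle_hash <- function(mesh, cell = NULL) {
  if (nrow(mesh$triangles) == 0L) return(NULL)
  v1 <- tri_corner(mesh, 1L); v2 <- tri_corner(mesh, 2L); v3 <- tri_corner(mesh, 3L)
  lo <- pmin(v1, pmin(v2, v3)); hi <- pmax(v1, pmax(v2, v3))
  if (is.null(cell)) {
    elen <- sqrt(rowSums((v2 - v1)^2))
    cell <- max(2 * stats::median(elen), 1e-6)
  }
  org <- apply(lo, 2, min)
  cl <- floor(sweep(lo, 2, org, "-") / cell)
  ch <- floor(sweep(hi, 2, org, "-") / cell)
  keys <- integer(0); ids <- integer(0)
  dims <- apply(ch, 2, max) + 2L
  lin <- function(cx, cy, cz) cx + dims[1] * (cy + dims[2] * cz) + 1
  ks <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    gx <- cl[i, 1]:ch[i, 1]; gy <- cl[i, 2]:ch[i, 2]; gz <- cl[i, 3]:ch[i, 3]
    g <- expand.grid(gx, gy, gz)
    ks[[i]] <- lin(g[, 1], g[, 2], g[, 3])
  }
  ids <- rep.int(seq_len(nrow(cl)), lengths(ks))
  keys <- unlist(ks, use.names = FALSE)
  list(map = split(ids, keys), org = org, cell = cell, dims = dims,
       v1 = v1, v2 = v2, v3 = v3)
}

# first intersection parameter t in (tmin, 1] of segment p -> q with the
# hashed mesh; returns NULL or list(t, point). `exclude` drops one face id
# (the seed's own face) from the test.
segment_mesh_hit <- function(p, q, hash, tmin = 1e-9, exclude = NA_integer_) {
  if (is.null(hash)) return(NULL)
  lo <- floor((pmin(p, q) - hash$org) / hash$cell)
  hi <- floor((pmax(p, q) - hash$org) / hash$cell)
  lo <- pmax(lo, 0); hi <- pmin(hi, hash$dims - 1L)
  if (any(hi < lo)) return(NULL)
  g <- expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
  keys <- g[, 1] + hash$dims[1] * (g[, 2] + hash$dims[2] * g[, 3]) + 1
  cand <- unique(unlist(hash$map[as.character(keys)], use.names = FALSE))
  if (!is.na(exclude)) cand <- cand[cand != exclude]
  if (!length(cand)) return(NULL)
  d <- q - p
  tt <- ray_triangle_t(p, d, hash$v1[cand, , drop = FALSE],
                       hash$v2[cand, , drop = FALSE],
                       hash$v3[cand, , drop = FALSE])
  tt[tt <= tmin | tt > 1] <- Inf
  if (!any(is.finite(tt))) return(NULL)
  tbest <- min(tt)
  list(t = tbest, point = p + tbest * d)
}

# fast trilinear interpolation of the three gradient components at one
# point (the tracing inner loop; assumes the point is inside the box)
grad_at <- function(grad, p) {
  n <- grad$counts
  u <- (p - grad$origin) / grad$spacing
  u <- pmin(pmax(u, 0), n - 1)
  i0 <- pmin(floor(u), n - 2)
  f <- u - i0
  sx <- 1L; sy <- n[1]; sz <- n[1] * n[2]
  base <- i0[1] * sx + i0[2] * sy + i0[3] * sz + 1
  idx <- base + c(0, sx, sy, sx + sy, sz, sx + sz, sy + sz, sx + sy + sz)
  w <- c((1 - f[1]) * (1 - f[2]) * (1 - f[3]), f[1] * (1 - f[2]) * (1 - f[3]),
         (1 - f[1]) * f[2] * (1 - f[3]), f[1] * f[2] * (1 - f[3]),
         (1 - f[1]) * (1 - f[2]) * f[3], f[1] * (1 - f[2]) * f[3],
         (1 - f[1]) * f[2] * f[3], f[1] * f[2] * f[3])
  c(sum(w * grad$vx[idx]), sum(w * grad$vy[idx]), sum(w * grad$vz[idx]))
}

# clip segment p -> q to the grid box; returns list(point, clipped)
clip_to_box <- function(p, q, lo, hi) {
  d <- q - p
  tmax <- 1
  for (a in 1:3) {
    if (d[a] > 0 && q[a] > hi[a]) tmax <- min(tmax, (hi[a] - p[a]) / d[a])
    if (d[a] < 0 && q[a] < lo[a]) tmax <- min(tmax, (lo[a] - p[a]) / d[a])
  }
  list(point = p + tmax * d, clipped = tmax < 1)
}

#' Trace one field line through a gradient grid
#'
#' Fixed-step Euler integration along the normalized, trilinearly
#' interpolated gradient, in both directions from the seed; the two half
#' traces are concatenated and oriented positive-to-negative (interpolated
#' EP at the first point >= at the last point). Each half stops when the
#' grid boundary is reached (the final point is clipped onto the box), when
#' the segment intersects the mesh (the intersection point ends the line),
#' when the gradient magnitude falls below `low_field_threshold`, or at
#' `max_points`. The stored `termination` is the stopping condition of the
#' negative (downstream) end.
#'
#' @param seed length-3 position inside the grid box.
#' @param grad a `vector_grid` from [gradient_grid()].
#' @param ep the source [scalar_grid()] (used to orient the line).
#' @param mesh optional [triangle_mesh()] for the intersection test
#'   (`NULL` disables it).
#' @param step step length, Angstrom (default half the smallest grid
#'   spacing).
#' @param low_field_threshold gradient magnitude (field units/Angstrom)
#'   below which the field counts as vanished.
#' @param max_points cap on points per line.
#' @return an object of class `field_line`: list with `points` (n x 3
#'   matrix), `seed_index`, `seed_ep`, `termination` (one of
#'   `"grid_boundary"`, `"mesh_intersection"`, `"low_field"`,
#'   `"max_points"`).
#' @export
trace_line <- function(seed, grad, ep, mesh = NULL, step = NULL,
                       low_field_threshold = 1e-4, max_points = 2000L) {
  stopifnot(inherits(grad, "vector_grid"), inherits(ep, "scalar_grid"))
  seed <- as.numeric(seed)
  step <- step %||% (0.5 * min(grad$spacing))
  if (!is_number(step) || step <= 0) stopf("trace_line: step must be > 0")
  lo <- grad$origin; hi <- grid_upper(grad)
  tol <- 1e-9
  if (any(seed < lo - tol) || any(seed > hi + tol))
    stopf("trace_line: seed (%.3f, %.3f, %.3f) lies outside the grid box",
          seed[1], seed[2], seed[3])
  seed <- pmin(pmax(seed, lo), hi)
  hash <- if (is.null(mesh)) NULL
          else if (inherits(mesh, "triangle_mesh")) build_triangle_hash(mesh)
          else mesh  # prebuilt hash
  half <- function(sgn) {
    pts <- vector("list", 64L); npts <- 0L
    p <- seed
    term <- "low_field"
    repeat {
      if (npts >= max_points) { term <- "max_points"; break }
      g <- grad_at(grad, p)
      gn <- sqrt(sum(g^2))
      if (!is.finite(gn) || gn < low_field_threshold) { term <- "low_field"; break }
      q <- p + sgn * step * g / gn
      cl <- clip_to_box(p, q, lo, hi)
      q <- cl$point
      if (!is.null(hash)) {
        hit <- segment_mesh_hit(p, q, hash)
        if (!is.null(hit)) {
          npts <- npts + 1L; pts[[npts]] <- hit$point
          term <- "mesh_intersection"; break
        }
      }
      npts <- npts + 1L; pts[[npts]] <- q
      if (cl$clipped) { term <- "grid_boundary"; break }
      p <- q
    }
    list(points = if (npts) do.call(rbind, pts[seq_len(npts)]) else matrix(0, 0, 3),
         termination = term)
  }
  up <- half(+1)   # toward more positive potential
  down <- half(-1) # toward more negative potential
  pts <- rbind(up$points[rev(seq_len(nrow(up$points))), , drop = FALSE],
               matrix(seed, 1, 3), down$points)
  term <- down$termination
  ep_ends <- grid_interpolate(ep, pts[c(1L, nrow(pts)), , drop = FALSE])
  if (ep_ends[1] < ep_ends[2]) {
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    term <- up$termination
  }
  structure(list(points = pts, seed_index = NA_integer_,
                 seed_ep = grid_interpolate(ep, matrix(seed, 1, 3)),
                 termination = term),
            class = "field_line")
}

#' Field-line bundle
#'
#' @param lines list of `field_line` objects.
#' @param header named list of metadata (seed count, thresholds used).
#' @return an object of class `field_line_file`.
#' @export
field_line_file <- function(lines = list(), header = list()) {
  for (ln in lines) {
    if (!inherits(ln, "field_line") || nrow(ln$points) < 1L)
      stopf("field_line_file: every line must be a field_line with >= 1 point")
  }
  structure(list(lines = lines, header = header), class = "field_line_file")
}

#' @export
print.field_line_file <- function(x, ...) {
  np <- vapply(x$lines, function(l) nrow(l$points), integer(1))
  cat(sprintf("field_line_file: %d lines (%d points total)\n",
              length(x$lines), sum(np)))
  invisible(x)
}

#' Compute the field lines of an EP grid around a surface
#'
#' The full multi-step computation: EP is sampled onto the mesh vertices
#' (trilinear), the gradient grid is built, seeds are drawn by EP-weighted
#' Monte Carlo on the surface ([select_seeds()]), each seed is lifted half
#' a step along its face's outward normal so a line does not instantly
#' re-intersect its source face, and a line is traced per seed
#' ([trace_line()]).
#'
#' @param mesh a [triangle_mesh()] (an existing `ep` channel is recomputed
#'   from `ep_grid` for consistency).
#' @param ep_grid a [scalar_grid()] of EP values; `minimum_potential` in
#'   `controls` is interpreted in this grid's units.
#' @param controls a [seed_controls()].
#' @param step,low_field_threshold,max_points tracing parameters, see
#'   [trace_line()].
#' @param temperature K, for the line-density unit conversion.
#' @return a [field_line_file()]; its header records the controls and
#'   tracing parameters used.
#' @export
compute_field_lines <- function(mesh, ep_grid, controls = seed_controls(),
                                step = NULL, low_field_threshold = 1e-4,
                                max_points = 2000L, temperature = 298.15) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(ep_grid, "scalar_grid"))
  step <- step %||% (0.5 * min(ep_grid$spacing))
  mesh <- sample_grid_at_vertices(ep_grid, mesh, "ep")
  grad <- gradient_grid(ep_grid)
  seeds <- select_seeds(mesh, controls, temperature = temperature)
  header <- list(seed_count = nrow(seeds),
                 minimum_potential = controls$minimum_potential,
                 line_density = controls$line_density,
                 rng_seed = controls$rng_seed,
                 step = step, low_field_threshold = low_field_threshold)
  if (nrow(seeds) == 0L) return(field_line_file(list(), header))
  normals <- mesh_face_normals(mesh)
  hash <- build_triangle_hash(mesh)
  lo <- ep_grid$origin; hi <- grid_upper(ep_grid)
  lines <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    p0 <- c(seeds$x[i], seeds$y[i], seeds$z[i])
    lifted <- p0 + 0.5 * step * normals[seeds$face[i], ]
    if (any(lifted < lo) || any(lifted > hi)) lifted <- p0
    ln <- trace_line(lifted, grad, ep_grid, mesh = hash, step = step,
                     low_field_threshold = low_field_threshold,
                     max_points = max_points)
    ln$seed_index <- seeds$face[i]
    ln$seed_ep <- seeds$ep[i]
    lines[[i]] <- ln
  }
  field_line_file(lines, header)
}
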