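#' Triangle mesh with per-vertex scalar channels
#'
#' A molecular-surface mesh: vertex positions (Angstrom), triangles as
#' 1-based vertex index triples, and named per-vertex scalar channels
#' (`ep`, `mlp`, `gray`, `specular`, `roughness`, `noise_amplitude`).
#'
#' @param vertices n x 3 numeric matrix.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param channels named list of length-n numeric vectors.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, channels = list()) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  nv <- nrow(vertices)
  if (nrow(triangles) > 0L &&
      (min(triangles) < 1L || max(triangles) > nv))
    stopf("triangle_mesh: triangle index out of range (vertex count %d)", nv)
  for (nm in names(channels)) {
    if (length(channels[[nm]]) != nv)
      stopf("triangle_mesh: channel '%s' has length %d but the mesh has %d vertices",
            nm, length(channels[[nm]]), nv)
  }
  structure(list(vertices = vertices, triangles = triangles,
                 channels = channels),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  if (length(x$channels))
    cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Attach a per-vertex channel to a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param name channel name.
#' @param values numeric vector, one value per vertex.
#' @return the mesh with the channel set.
#' @export
set_channel <- function(mesh, name, values) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (length(values) != nrow(mesh$vertices))
    stopf("set_channel: channel '%s' length %d != vertex count %d",
          name, length(values), nrow(mesh$vertices))
  mesh$channels[[name]] <- as.numeric(values)
  mesh
}

tri_corner <- function(mesh, k) mesh$vertices[mesh$triangles[, k], , drop = FALSE]

#' Per-face areas, unit normals and centroids
#'
#' Areas from the cross product; normals follow the right-hand rule on the
#' stored vertex order (outward for meshes built by [build_surface()]).
#'
#' @param mesh a [triangle_mesh()].
#' @return `mesh_face_areas`: numeric vector; `mesh_face_normals`: m x 3
#'   matrix of unit vectors; `mesh_face_centroids`: m x 3 matrix.
#' @export
mesh_face_areas <- function(mesh) {
  a <- tri_corner(mesh, 1L); b <- tri_corner(mesh, 2L); c_ <- tri_corner(mesh, 3L)
  0.5 * sqrt(rowSums(cross3(b - a, c_ - a)^2))
}

#' @rdname mesh_face_areas
#' @export
mesh_face_normals <- function(mesh) {
  a <- tri_corner(mesh, 1L); b <- tri_corner(mesh, 2L); c_ <- tri_corner(mesh, 3L)
  n <- cross3(b - a, c_ - a)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname mesh_face_areas
#' @export
mesh_face_centroids <- function(mesh) {
  (tri_corner(mesh, 1L) + tri_corner(mesh, 2L) + tri_corner(mesh, 3L)) / 3
}

# undirected edges (sorted vertex pairs), one row per triangle edge
mesh_edge_list <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Is a mesh watertight?
#'
#' Watertight (closed) means every undirected edge is shared by exactly two
#' triangles.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(FALSE)
  e <- mesh_edge_list(mesh)
  key <- (e[, 1] - 1) * (nrow(mesh$vertices) + 1) + e[, 2]
  all(tabulate(match(key, unique(key))) == 2L)
}

#' Mesh quality summary
#'
#' Reports the quantities against which surface quality is judged: triangle
#' count, total/mean area and the coefficient of variation of triangle areas
#' (a uniformity measure), mean edge length, watertightness and the Euler
#' characteristic V - E + F (2 for a single closed genus-0 surface).
#'
#' @param mesh a [triangle_mesh()].
#' @return a list with elements `n_vertices`, `n_triangles`, `n_edges`,
#'   `area_total`, `area_mean`, `area_cv`, `mean_edge_length`, `watertight`,
#'   `euler_characteristic`.
#' @export
mesh_statistics <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  areas <- mesh_face_areas(mesh)
  e <- mesh_edge_list(mesh)
  key <- (e[, 1] - 1) * (nrow(mesh$vertices) + 1) + e[, 2]
  uniq <- !duplicated(key)
  elen <- sqrt(rowSums((mesh$vertices[e[uniq, 1], , drop = FALSE] -
                        mesh$vertices[e[uniq, 2], , drop = FALSE])^2))
  list(n_vertices = nrow(mesh$vertices),
       n_triangles = nrow(mesh$triangles),
       n_edges = sum(uniq),
       area_total = sum(areas),
       area_mean = mean(areas),
       area_cv = if (length(areas)) stats::sd(areas) / mean(areas) else NA_real_,
       mean_edge_length = mean(elen),
       watertight = is_watertight(mesh),
       euler_characteristic = nrow(mesh$vertices) - sum(uniq) + nrow(mesh$triangles))
}

# Moller-Trumbore ray/triangle intersection parameters for one ray against
# a set of triangles; returns the vector of ray parameters t (Inf = miss).
ray_triangle_t <- function(orig, dir, v1, v2, v3) {
  eps <- 1e-12
  e1 <- v2 - v1; e2 <- v3 - v1
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  tv <- sweep(-v1, 2, orig, "+")
  u <- rowSums(tv * pv) / det
  qv <- cross3(tv, e1)
  v <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
  tt <- rowSums(e2 * qv) / det
  bary_eps <- 1e-9
  miss <- abs(det) < eps | u < -bary_eps | v < -bary_eps | u + v > 1 + bary_eps |
          !is.finite(tt)
  tt[miss] <- Inf
  tt
}

#' Point-in-mesh test
#'
#' Ray-casting parity test against a closed mesh: a point is inside when a
#' ray from it crosses the surface an odd number of times.
#'
#' @param points n x 3 matrix (or length-3 vector).
#' @param mesh a closed [triangle_mesh()].
#' @return logical vector.
#' @export
point_in_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3L)
  # fixed irrational-ish direction to dodge edge/vertex grazing
  dir <- c(0.5633673867912350, 0.4312344523412347, 0.7043123412345219)
  dir <- dir / sqrt(sum(dir^2))
  v1 <- tri_corner(mesh, 1L); v2 <- tri_corner(mesh, 2L); v3 <- tri_corner(mesh, 3L)
  vapply(seq_len(nrow(points)), function(i) {
    tt <- ray_triangle_t(points[i, ], dir, v1, v2, v3)
    sum(tt > 1e-9 & is.finite(tt)) %% 2L == 1L
  }, logical(1))
}

# connected components over shared vertices; returns per-triangle component id
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tr <- mesh$triangles
  for (r in seq_len(nrow(tr))) {
    a <- find(tr[r, 1]); b <- find(tr[r, 2]); c_ <- find(tr[r, 3])
    parent[b] <- a; parent[c_] <- a
  }
  roots <- vapply(tr[, 1], find, integer(1))
  match(roots, unique(roots))
}

# extract the sub-mesh of a triangle subset, re-indexing vertices
mesh_subset <- function(mesh, tri_keep) {
  tr <- mesh$triangles[tri_keep, , drop = FALSE]
  vid <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(mesh$vertices)); remap[vid] <- seq_along(vid)
  ch <- lapply(mesh$channels, function(v) v[vid])
  triangle_mesh(mesh$vertices[vid, , drop = FALSE],
                matrix(remap[tr], ncol = 3L), ch)
}

# light vertex-averaged (Laplacian) smoothing
smooth_mesh <- function(mesh, iterations = 2L, lambda = 0.5) {
  if (iterations <= 0L || nrow(mesh$triangles) == 0L) return(mesh)
  e <- mesh_edge_list(mesh)
  key <- (e[, 1] - 1) * (nrow(mesh$vertices) + 1) + e[, 2]
  e <- e[!duplicated(key), , drop = FALSE]
  src <- c(e[, 1], e[, 2]); dst <- c(e[, 2], e[, 1])
  deg <- tabulate(src, nbins = nrow(mesh$vertices))
  if (any(deg == 0L)) return(mesh)  # isolated vertices: leave untouched
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    nbsum <- rowsum(v[dst, , drop = FALSE], src, reorder = TRUE)
    # rowsum drops absent indices; all vertices appear in edges for a valid mesh
    v <- v + lambda * (nbsum / deg - v)
  }
  mesh$vertices <- v
  mesh
}
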