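# Gaussian-density molecular surface.
#
# The density around the atoms is sum_i exp(-k * (d_i / R_i)^2) with
# R_i = radius_i + probe; the surface is the iso = exp(-k) level set, so a
# lone atom's surface sits exactly at distance R_i from its center, and
# nearby atoms' densities merge smoothly (the same topology-merging behavior
# as a solvent-excluded surface, without re-entrant geometry). The level set
# is polygonized by marching tetrahedra (each lattice cube split into six
# tetrahedra sharing the main diagonal, which makes the triangulation
# watertight by construction), then lightly vertex-average smoothed.

# default fallback van der Waals radii (Angstrom) by element, used when a
# plain PDB (no per-atom radii) is meshed
.element_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                    P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                    FE = 1.80, ZN = 1.39, MG = 1.73, CA = 1.74, "NA" = 2.27,
                    K = 2.75, X = 1.70)

element_radius <- function(element) {
  r <- .element_radii[toupper(element)]
  r[is.na(r)] <- .element_radii[["X"]]
  unname(r)
}

# accumulate the Gaussian density of each atom onto the lattice (local
# support: contributions beyond cutoff_mult * R_i are dropped)
gaussian_density <- function(centers, R, geom, k, cutoff_mult = 3) {
  n <- geom$counts
  vals <- array(0, dim = n)
  ax <- lapply(1:3, function(a) geom$origin[a] + (seq_len(n[a]) - 1L) * geom$spacing[a])
  for (i in seq_len(nrow(centers))) {
    cut <- cutoff_mult * R[i]
    rng <- lapply(1:3, function(a) {
      which(ax[[a]] >= centers[i, a] - cut & ax[[a]] <= centers[i, a] + cut)
    })
    if (any(lengths(rng) == 0L)) next
    dx2 <- (ax[[1]][rng[[1]]] - centers[i, 1])^2
    dy2 <- (ax[[2]][rng[[2]]] - centers[i, 2])^2
    dz2 <- (ax[[3]][rng[[3]]] - centers[i, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      vals[rng[[1]], rng[[2]], rng[[3]]] + exp(-k * d2 / R[i]^2)
  }
  vals
}

# Polygonize the iso level set of a scalar_grid by marching tetrahedra.
# Triangles are consistently oriented with outward normals (away from the
# region where values > iso).
marching_tetrahedra <- function(grid, iso) {
  v <- grid$values
  n <- grid$counts
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  eps <- 1e-9 * max(1, diff(range(v)))
  v[v == iso] <- iso + eps
  inside <- v > iso
  sl <- function(dx, dy, dz)
    inside[(1 + dx):(nx - 1 + dx), (1 + dy):(ny - 1 + dy), (1 + dz):(nz - 1 + dz),
           drop = FALSE]
  s <- sl(0,0,0) + sl(1,0,0) + sl(1,1,0) + sl(0,1,0) +
       sl(0,0,1) + sl(1,0,1) + sl(1,1,1) + sl(0,1,1)
  cc <- which(s > 0L & s < 8L)
  if (!length(cc)) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  ci <- arrayInd(cc, c(nx - 1L, ny - 1L, nz - 1L))
  off <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
               c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  nid <- function(ix, iy, iz) ix + (iy - 1) * nx + (iz - 1) * nx * ny
  corner <- matrix(0, nrow(ci), 8L)
  for (k in 1:8)
    corner[, k] <- nid(ci[, 1] + off[k, 1], ci[, 2] + off[k, 2], ci[, 3] + off[k, 3])
  # six tetrahedra per cube, all sharing the main diagonal corner1-corner7,
  # so the face diagonals agree between neighboring cubes
  tets <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7), c(1,8,5,7),
                c(1,5,6,7), c(1,6,2,7))
  tet_nodes <- do.call(rbind, lapply(1:6, function(t) corner[, tets[t, ], drop = FALSE]))
  ins <- matrix(inside[tet_nodes], nrow(tet_nodes), 4L)
  code <- as.integer(ins %*% c(1L, 2L, 4L, 8L))
  keep <- code > 0L & code < 15L
  tet_nodes <- tet_nodes[keep, , drop = FALSE]
  code <- code[keep]
  if (!nrow(tet_nodes)) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  # case table: triangles as triples of (inside-slot, outside-slot) edges
  cases <- lapply(1:14, function(cd) {
    m <- bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0L
    S <- which(m); O <- which(!m)
    tris <- if (length(S) == 1L) {
      list(rbind(c(S, O[1]), c(S, O[2]), c(S, O[3])))
    } else if (length(S) == 3L) {
      list(rbind(c(S[1], O), c(S[2], O), c(S[3], O)))
    } else {
      list(rbind(c(S[1], O[1]), c(S[1], O[2]), c(S[2], O[2])),
           rbind(c(S[1], O[1]), c(S[2], O[2]), c(S[2], O[1])))
    }
    list(tris = tris, anchor = S[1])
  })
  A <- list(); B <- list(); AN <- list()
  for (cd in 1:14) {
    rows <- which(code == cd)
    if (!length(rows)) next
    tc <- tet_nodes[rows, , drop = FALSE]
    for (tr in cases[[cd]]$tris) {
      A[[length(A) + 1L]] <- cbind(tc[, tr[1, 1]], tc[, tr[2, 1]], tc[, tr[3, 1]])
      B[[length(B) + 1L]] <- cbind(tc[, tr[1, 2]], tc[, tr[2, 2]], tc[, tr[3, 2]])
      AN[[length(AN) + 1L]] <- tc[, cases[[cd]]$anchor]
    }
  }
  A <- do.call(rbind, A); B <- do.call(rbind, B)
  anchor <- do.call(c, AN)
  ntri <- nrow(A)
  lo <- pmin(A, B); hi <- pmax(A, B)
  key <- (as.vector(lo) - 1) * prod(n) + as.vector(hi)  # < 2^53 for any sane grid
  first <- !duplicated(key)
  ukey <- key[first]
  u_lo <- as.vector(lo)[first]; u_hi <- as.vector(hi)[first]
  vid <- match(key, ukey)
  tri <- matrix(vid, ntri, 3L)
  pos_of <- function(id) {
    id0 <- id - 1
    cbind(grid$origin[1] + (id0 %% nx) * grid$spacing[1],
          grid$origin[2] + ((id0 %/% nx) %% ny) * grid$spacing[2],
          grid$origin[3] + (id0 %/% (nx * ny)) * grid$spacing[3])
  }
  p_lo <- pos_of(u_lo); p_hi <- pos_of(u_hi)
  tpar <- (iso - v[u_lo]) / (v[u_hi] - v[u_lo])
  verts <- p_lo + tpar * (p_hi - p_lo)
  # orient each triangle so its normal points away from its inside corner
  p1 <- verts[tri[, 1], , drop = FALSE]
  p2 <- verts[tri[, 2], , drop = FALSE]
  p3 <- verts[tri[, 3], , drop = FALSE]
  nrm <- cross3(p2 - p1, p3 - p1)
  cen <- (p1 + p2 + p3) / 3
  flip <- rowSums(nrm * (cen - pos_of(anchor))) < 0
  tmp <- tri[flip, 2L]; tri[flip, 2L] <- tri[flip, 3L]; tri[flip, 3L] <- tmp
  triangle_mesh(verts, tri)
}

#' Build a molecular-surface mesh from a structure
#'
#' Generates a closed, watertight triangle mesh of the molecular surface as
#' the level set of a smooth Gaussian density over the atoms (see the top of
#' this file): a lone atom's surface sits at `radius + probe` from its
#' center, and overlapping atoms merge into one closed surface. The mean
#' triangle-edge length tracks the voxel size, so `voxel = 1` Angstrom
#' yields the ~1 Angstrom edges that match the default potential-grid
#' spacing.
#'
#' @param structure a [structure3d()]; atoms need radii (PQR) or get a
#'   fallback radius by element.
#' @param voxel lattice spacing for the polygonizer, Angstrom (> 0, and not
#'   larger than the smallest atom radius).
#' @param probe probe radius added to every atom radius, Angstrom
#'   (default 1.4, water).
#' @param iso density iso-level; the default `exp(-k)` places a lone atom's
#'   surface exactly at `radius + probe`.
#' @param k Gaussian sharpness (default `log(2)`).
#' @param smooth_iterations vertex-averaging smoothing passes (default 2).
#' @param drop_enclosed drop connected components that lie inside another
#'   component (internal cavity surfaces); off by default.
#' @return a [triangle_mesh()] with outward-oriented triangles.
#' @export
build_surface <- function(structure, voxel = 1.0, probe = 1.4,
                          iso = NULL, k = log(2), smooth_iterations = 2L,
                          drop_enclosed = FALSE) {
  stopifnot(inherits(structure, "structure3d"))
  if (!is_number(voxel) || voxel <= 0) stopf("build_surface: voxel must be > 0")
  if (!is_number(probe) || probe < 0) stopf("build_surface: probe must be >= 0")
  r <- structure$atoms$radius
  if (any(is.na(r))) r[is.na(r)] <- element_radius(structure$atoms$element[is.na(r)])
  if (voxel > min(r))
    stopf("build_surface: voxel %.3g A exceeds the smallest atom radius %.3g A (resolution too coarse)",
          voxel, min(r))
  iso <- iso %||% exp(-k)
  centers <- atom_coords(structure)
  R <- r + probe
  pad <- max(R) + 3 * voxel
  geom <- grid_geometry_for(centers, voxel, pad)
  dens <- gaussian_density(centers, R, geom, k)
  grid <- scalar_grid(geom$origin, geom$spacing, geom$counts, dens)
  mesh <- marching_tetrahedra(grid, iso)
  if (nrow(mesh$triangles) == 0L)
    stopf("build_surface: empty isosurface (voxel too coarse for the structure?)")
  mesh <- smooth_mesh(mesh, iterations = smooth_iterations)
  if (drop_enclosed) mesh <- drop_enclosed_components(mesh)
  mesh
}

# remove components nested inside an odd number of other components
drop_enclosed_components <- function(mesh) {
  comp <- mesh_components(mesh)
  ncomp <- max(comp)
  if (ncomp <= 1L) return(mesh)
  keep <- rep(TRUE, ncomp)
  for (cmp in seq_len(ncomp)) {
    other <- mesh_subset(mesh, comp != cmp)
    probe_pt <- mesh$vertices[mesh$triangles[which(comp == cmp)[1], 1], ]
    if (point_in_mesh(probe_pt, other)) keep[cmp] <- FALSE
  }
  mesh_subset(mesh, keep[comp])
}
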