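# Shared in-code fixtures (no files are stored; everything is generated).

atom_coords_helper <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

clamp_helper <- function(x, lo = -3, hi = 1) pmin(pmax(x, lo), hi)

# regular tetrahedron: four congruent equilateral faces, outward-oriented
regular_tetra_mesh <- function(mlp = NULL) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tr <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  ch <- if (is.null(mlp)) list() else list(mlp = mlp)
  triangle_mesh(v, tr, ch)
}

# two well-separated unit right triangles with a per-vertex ep channel
two_patch_mesh <- function(ep_a, ep_b) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(100, 0, 0), c(101, 0, 0), c(100, 1, 0))
  tr <- rbind(c(1, 2, 3), c(4, 5, 6))
  triangle_mesh(v, tr, list(ep = c(rep(ep_a, 3), rep(ep_b, 3))))
}

# single-atom structure at the origin
one_atom_structure <- function(charge = 1, radius = 1.5, f = 1) {
  structure3d(data.frame(serial = 1L, name = "C1", element = "C",
                         residue_name = "FIX", residue_id = 1L, chain = "A",
                         x = 0, y = 0, z = 0, charge = charge,
                         radius = radius, f = f))
}

# random small structure with symbolic f values and charges
random_structure <- function(n, seed, span = 5) {
  set.seed(seed)
  pos <- matrix(stats::runif(3 * n, -span, span), ncol = 3)
  structure3d(data.frame(serial = seq_len(n), name = paste0("C", seq_len(n)),
                         element = "C", residue_name = "FIX",
                         residue_id = seq_len(n), chain = "A",
                         x = pos[, 1], y = pos[, 2], z = pos[, 3],
                         charge = stats::runif(n, -1, 1),
                         radius = stats::runif(n, 1, 2),
                         f = sample(c(-1, -0.5, 0.5, 1), n, replace = TRUE)))
}

# scalar grid sampled from a function f(x, y, z)
grid_from_function <- function(fun, origin = c(0, 0, 0), spacing = 1,
                               counts = c(6L, 6L, 6L)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(counts[a]) - 1L) * spacing[a])
  vals <- array(0, dim = counts)
  for (k in seq_len(counts[3])) for (j in seq_len(counts[2]))
    vals[, j, k] <- fun(ax[[1]], ax[[2]][j], ax[[3]][k])
  scalar_grid(origin, spacing, counts, vals)
}

# random field-line file for round-trip tests
random_field_line_file <- function(n_lines, seed = 1) {
  set.seed(seed)
  lines <- lapply(seq_len(n_lines), function(i) {
    np <- sample(1:12, 1)
    structure(list(points = matrix(stats::runif(3 * np, -50, 50), ncol = 3),
                   seed_index = NA_integer_,
                   seed_ep = stats::runif(1, -5, 5),
                   termination = sample(c("grid_boundary", "mesh_intersection",
                                          "low_field"), 1)),
              class = "field_line")
  })
  field_line_file(lines, header = list(minimum_potential = 0.25,
                                       line_density = 2, rng_seed = 7L,
                                       seed_count = n_lines))
}
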