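# Mapping grid scalars onto the surface mesh and deriving material
# channels. The visual code: hydrophobic (high MLP) areas render
# smooth-shiny, hydrophilic (low MLP) areas rough-dull, so gray drives
# specularity directly and surface noise amplitude / roughness inversely.

#' Sample a grid onto mesh vertices
#'
#' Trilinear interpolation of the 8 enclosing lattice nodes at every vertex
#' (exact at nodes and for affine fields); the result is stored as a named
#' per-vertex channel. Vertices outside the grid box raise an error naming
#' the vertex - there is no silent extrapolation, so potential grids must
#' be built with enough padding to cover the surface.
#'
#' @param grid a [scalar_grid()].
#' @param mesh a [triangle_mesh()].
#' @param channel_name name under which to store the sampled values
#'   (e.g. `"mlp"`, `"ep"`).
#' @return the mesh with the channel added.
#' @export
sample_grid_at_vertices <- function(grid, mesh, channel_name) {
  stopifnot(inherits(grid, "scalar_grid"), inherits(mesh, "triangle_mesh"))
  vals <- drop(trilinear(grid, list(grid$values), mesh$vertices,
                         context = "vertex"))
  set_channel(mesh, channel_name, vals)
}

#' Gray-map parameters
#'
#' The MLP-to-gray transfer curve: piecewise linear through the knots
#' (in_low, 0), (in_mid, 0.5), (in_high, 1) - by default MLP -3 maps to
#' black, 0 to mid-gray and +1 to white, covering the typical working range
#' of protein surface MLP. A single linear map cannot send both [-3,1] onto
#' [0,1] and 0 onto 0.5; the two-segment map satisfies both. `contrast`
#' scales about mid-gray and `brightness` shifts, after which the output is
#' re-clamped to [0,1]:
#' `out = clamp((g - 0.5) * contrast + 0.5 + brightness, 0, 1)`.
#'
#' @param contrast multiplicative contrast about 0.5 (default 1).
#' @param brightness additive shift (default 0).
#' @param in_low,in_mid,in_high MLP knots (must increase).
#' @return an object of class `gray_map_params`.
#' @export
gray_map_params <- function(contrast = 1, brightness = 0,
                            in_low = -3, in_mid = 0, in_high = 1) {
  if (!(in_low < in_mid && in_mid < in_high))
    stopf("gray_map_params: knots must satisfy in_low < in_mid < in_high")
  if (!is_number(contrast) || !is_number(brightness))
    stopf("gray_map_params: contrast and brightness must be finite scalars")
  structure(list(in_low = in_low, in_mid = in_mid, in_high = in_high,
                 out_low = 0, out_mid = 0.5, out_high = 1,
                 contrast = contrast, brightness = brightness),
            class = "gray_map_params")
}

#' Convert MLP values to gray levels
#'
#' Piecewise-linear map `[in_low, in_mid] -> [0, 0.5]`,
#' `[in_mid, in_high] -> [0.5, 1]`, clamping out-of-range inputs to the
#' endpoints, then contrast/brightness (see [gray_map_params()]). Total and
#' monotone nondecreasing in MLP.
#'
#' @param mlp numeric vector of MLP values.
#' @param params a [gray_map_params()].
#' @return gray levels in [0, 1].
#' @export
mlp_to_gray <- function(mlp, params = gray_map_params()) {
  stopifnot(inherits(params, "gray_map_params"))
  x <- clamp(mlp, params$in_low, params$in_high)
  g <- ifelse(x <= params$in_mid,
              params$out_mid * (x - params$in_low) / (params$in_mid - params$in_low),
              params$out_mid +
                (params$out_high - params$out_mid) * (x - params$in_mid) /
                (params$in_high - params$in_mid))
  clamp((g - 0.5) * params$contrast + 0.5 + params$brightness, 0, 1)
}

#' Derive material channels from gray
#'
#' Encodes the smooth-shiny/rough-dull visual code as data for any
#' renderer: `specular = gray` (white, hydrophobic areas are reflective),
#' `roughness = 1 - gray` and `noise_amplitude = 1 - gray` (strong surface
#' noise over black, hydrophilic areas; none on white). Deterministic; the
#' noise itself is realized downstream (see [noise_preview()]).
#'
#' @param gray numeric vector in [0, 1].
#' @return list with `specular`, `roughness`, `noise_amplitude`.
#' @export
gray_to_material_channels <- function(gray) {
  if (any(gray < -1e-12 | gray > 1 + 1e-12))
    stopf("gray_to_material_channels: gray values must lie in [0, 1]")
  gray <- clamp(gray, 0, 1)
  list(specular = gray, roughness = 1 - gray, noise_amplitude = 1 - gray)
}

#' Attach gray and material channels to a mesh
#'
#' Convenience composition: requires an `mlp` channel (see
#' [sample_grid_at_vertices()]), adds `gray`, `specular`, `roughness` and
#' `noise_amplitude`.
#'
#' @param mesh a [triangle_mesh()] with an `mlp` channel.
#' @param params a [gray_map_params()].
#' @return the mesh with four channels added.
#' @export
add_material_channels <- function(mesh, params = gray_map_params()) {
  if (is.null(mesh$channels$mlp))
    stopf("add_material_channels: mesh has no 'mlp' channel")
  gray <- mlp_to_gray(mesh$channels$mlp, params)
  mat <- gray_to_material_channels(gray)
  mesh <- set_channel(mesh, "gray", gray)
  mesh <- set_channel(mesh, "specular", mat$specular)
  mesh <- set_channel(mesh, "roughness", mat$roughness)
  set_channel(mesh, "noise_amplitude", mat$noise_amplitude)
}

#' Seeded per-vertex noise preview
#'
#' Realizes the surface noise as data (for preview, not rendering):
#' Gaussian draws scaled by the `noise_amplitude` channel, deterministic
#' for a fixed seed.
#'
#' @param mesh a mesh with a `noise_amplitude` channel.
#' @param rng_seed integer seed.
#' @return numeric vector of noise values, one per vertex.
#' @export
noise_preview <- function(mesh, rng_seed = 1L) {
  amp <- mesh$channels$noise_amplitude
  if (is.null(amp)) stopf("noise_preview: mesh has no 'noise_amplitude' channel")
  with_seed(rng_seed, stats::rnorm(length(amp)) * amp)
}
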