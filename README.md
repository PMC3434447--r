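# surfscape

Proteins interact with their surroundings through surface properties that
plain structure viewers encode as arbitrary color ramps: hydropathy and
electrostatics. `surfscape` computes both as *data* that any renderer (or
analysis) can consume, for a single structure or for every conformation of
a moving protein:

- **MLP** — the molecular lipophilic potential, an atom-level fragment sum
  `MLP(r) = Σᵢ fᵢ · k(|r − rᵢ|)` with a pluggable distance kernel
  (exponential `e^(−d/2)` by default; `e^(−d)` and hyperbolic variants are
  provided), evaluated on a regular grid and mapped per-vertex onto a
  molecular surface. MLP drives a piecewise-linear gray map
  (−3 → 0, 0 → 0.5, +1 → 1) and the derived material channels
  `specular = gray`, `roughness = noise_amplitude = 1 − gray`, encoding
  the smooth-shiny (hydrophobic) versus rough-dull (hydrophilic) visual
  code.
- **EP** — the electrostatic potential in kT/e. The faithful path imports
  a Poisson–Boltzmann grid in OpenDX format; the built-in solver is a
  uniform-dielectric screened-Coulomb (Debye–Hückel) approximation
  `φ(r) = l_B Σᵢ qᵢ e^(−κ|r−rᵢ|)/|r−rᵢ|` from PQR partial charges
  (defaults: 0.150 mol/L NaCl, solvent ε 78.54, 298.15 K). EP is redrawn
  as field lines: seeds are drawn on the surface by EP-weighted Monte
  Carlo sampling, each line follows the potential gradient in both
  directions with small fixed steps, and stops at the grid boundary, on
  mesh intersection, or where the field vanishes. Lines are oriented
  positive → negative and carry a particle schedule (one emission per line
  every 5 frames, 20-frame lifetime, 25 fps).

Surfaces are generated internally as watertight Gaussian-density
isosurfaces polygonized by marching tetrahedra (meshes can also be
imported as OBJ). Everything is deterministic under a single RNG seed,
including the Monte Carlo stages.

Supported formats: PDB (multi-model for frame sequences), PQR, OpenDX
scalar grids, Wavefront OBJ (per-vertex MLP stored in the texture-V
field), an ASCII field-line format, and columnar text for channels and
particle schedules.

## Worked example

A two-atom ±1 e "dipole" fixture through the whole pipeline:

```r
library(surfscape)

s    <- make_fixture("dipole")          # +1 e and -1 e, 6 A apart
mesh <- build_surface(s, voxel = 1)     # Gaussian surface, marching tetrahedra
mesh_statistics(mesh)[c("watertight", "euler_characteristic", "mean_edge_length")]
#> watertight: TRUE | Euler characteristic: 2 | mean edge: 0.54 A

mlp  <- compute_mlp_grid(s)             # 1 A default spacing
ep   <- compute_ep_grid(s)              # screened Coulomb, kT/e
ep
#> scalar_grid: 17 x 11 x 11 nodes, spacing 1/1/1 A
#>   origin (-8.000, -5.000, -5.000) A, value range [-69.9, 69.9]

mesh <- sample_grid_at_vertices(mlp, mesh, "mlp")   # trilinear
mesh <- add_material_channels(mesh)     # gray / specular / roughness / noise

lines <- compute_field_lines(mesh, ep, seed_controls(rng_seed = 1))
lines
#> field_line_file: 28 lines (242 points total)
table(vapply(lines$lines, function(l) l$termination, character(1)))
#>     grid_boundary mesh_intersection
#>                11                17

steady_state_time(animation_params())   # particle system fills up at
#> [1] 0.6                              # frame 15 = 0.6 s

nrow(schedule(lines, animation_params(), frame = 15)) / length(lines$lines)
#> [1] 4                                # live particles per line at steady state
```

The 28 lines rise preferentially from the two charged lobes (seed counts
are proportional to |EP| × area per face), each runs from its positive
toward its negative end, and 4 particles per line are alive once the
system reaches steady state.

`run_frame()` writes the five per-frame artifacts (`surface.obj`,
`mlp.dx`, `ep.dx`, `lines.txt`, `schedule.tsv`) plus a channel sidecar
and the resolved config; `run_sequence()` does this per model of a
multi-model file (or per file of a directory) with a manifest. The same
pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/surfscape.R make-fixture dipole --out fixtures
Rscript inst/scripts/surfscape.R run fixtures/dipole.pqr --out out --rng-seed 1
```

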