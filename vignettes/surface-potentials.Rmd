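---
title: "Surface lipophilic and electrostatic potentials: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface lipophilic and electrostatic potentials: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfscape)
```

`surfscape` turns a protein conformation (or a sequence of them) into
renderer-agnostic surface data: a watertight triangle mesh carrying
lipophilicity-derived material channels, plus electrostatic field lines
with particle schedules. This vignette documents the models, every
tunable that matters, the numerical choices, and what the synthetic test
fixtures do and do not establish about real data.

## The molecular lipophilic potential

The MLP is an atom-based fragment sum

$$\mathrm{MLP}(\mathbf r) \;=\; \sum_i f_i \, k(\lVert \mathbf r - \mathbf r_i\rVert),$$

where $f_i$ is the lipophilic fragment value of atom $i$ (a Broto-style
atom-level decomposition of octanol/water partition contributions;
positive = hydrophobic) and $k$ a decaying distance kernel. Atom-based
fragment sums resolve sub-residue detail that residue-level hydropathy
scales (e.g. Kyte–Doolittle) cannot: surface patches change smoothly as
side chains rotate, which is what makes the representation useful on
moving proteins.

**Kernel.** The default kernel is exponential, $k(d) = e^{-d/2}$. The
exact exponent convention in the literature is ambiguous (reported forms
differ between $d/2$ and $d^2$), so the kernel is a pluggable object
(`mlp_formula()`): swapping the decay law is a one-line change and the
alternatives (`fauchere` $e^{-d}$, `dubost` $100/(1+d)$, `brasseur`
$e^{-d/2}$) are provided as labeled variants, not validated science.

**Fragment values.** The shipped table
(`inst/extdata/mlp_fragments.tsv`) is a synthetic, rule-based set —
aliphatic carbon ≈ +0.45, aromatic ≈ +0.31, terminal methyls +0.63,
polar N/O between −0.40 and −0.85, sulfur +0.60, hydrogens +0.10 via
element fallback — covering the heavy atoms of the 20 standard amino
acids with element-level fallback for everything else (nucleic acids and
sugars resolve through the fallback). Published fragment sets are not
redistributed here; the file documents its provenance and
`read_lipophilic_library(path)` swaps in any table with the same three
columns. Test fixtures deliberately use symbolic $f$ values (±1, ±0.5)
so that numerical tests are independent of this table.

**Grid.** Default spacing 1 Å (`default_spacing()`): comparable to the
mean triangle edge of the default surface mesh, so the field and the
geometry resolve the same detail. Contributions beyond 12 Å are cut off;
with the default kernel the truncated term is below $e^{-6} \approx
0.0025$ of its peak, and the cutoff is configurable (`cutoff = Inf`
disables it, which is what the oracle tests use).

## From MLP to material channels

Surface values are obtained per vertex by trilinear interpolation of the
8 enclosing grid nodes (`sample_grid_at_vertices()`): exact at nodes and
for affine fields, and the grids are built with enough padding that a
vertex outside the grid is an error, never an extrapolation.

The gray map (`mlp_to_gray()`) must send the working range $[-3, 1]$
onto $[0, 1]$ *and* MLP 0 to mid-gray 0.5. No single linear map does
both, so the map is piecewise linear with knots $(-3, 0)$, $(0, 0.5)$,
$(1, 1)$, clamping outside the range. Contrast and brightness act
afterwards as $\mathrm{clamp}((g - 0.5)c + 0.5 + b)$ — the standard
slider form, chosen because only the existence of the two controls is
fixed, not their algebra.

Material channels are pure functions of gray: `specular = gray`,
`roughness = 1 - gray`, `noise_amplitude = 1 - gray`. Bright
(hydrophobic) surface renders shiny and smooth; dark (hydrophilic)
surface rough and noisy. The package exports the noise *amplitude* as
data; rasterizing noise into textures and bump maps is a renderer
concern and out of scope (a seeded `noise_preview()` exists for quick
checks). The exact noise spectrum a renderer applies is not recoverable
from data this package produces, and is not modeled.

## The electrostatic potential

The reference treatment of protein electrostatics is a
Poisson–Boltzmann solve with a dielectric boundary; `surfscape` imports
such grids (OpenDX, `load_ep_grid()`, unit tagged "as-labeled" because
DX files do not declare units). The built-in solver is deliberately
simpler — a uniform-dielectric screened-Coulomb (Debye–Hückel) sum

$$\phi(\mathbf r) = l_B \sum_i \frac{q_i\, e^{-\kappa \lVert \mathbf r-\mathbf r_i\rVert}}{\lVert \mathbf r-\mathbf r_i\rVert} \quad [kT/e],$$

with $l_B \approx 7.14$ Å the Bjerrum length in water at 298.15 K and
$\kappa \approx 0.127$ Å⁻¹ at 0.150 mol/L. It keeps the package
self-contained and desk-testable against a closed form; the field-line
machinery downstream is agnostic to the grid's provenance. Defaults
(0.150 mol/L NaCl, solute ε 2, solvent ε 78.54) follow standard
continuum-electrostatics practice; the solute dielectric is recorded but
unused by the built-in solver, which has no dielectric boundary — the
single largest physical approximation in the package. Grid nodes within
0.1 Å of an atom are clamped to the value at 0.1 Å so the singularity
never reaches the lattice.

## Field lines

The gradient grid uses central differences at interior nodes (exact for
quadratics) and one-sided differences on the boundary.

**Seeding.** Faces whose $|EP|$ (mean of vertex values) passes
`minimum_potential` are candidates; seeds are drawn with replacement
with probability $\propto |EP| \cdot \mathrm{area}$, and the seed count
is $N = \mathrm{round}(\rho \sum |EP_{\mathrm{eV}}| \cdot
\mathrm{area})$ with `line_density` $\rho$ in lines per eV/Å² (kT/e →
eV conversion at the configured temperature; rounding half away from
zero). This makes line count proportional to the global surface
potential and line placement proportional to local activity. Faces are
the sampling granularity (the finest consistent choice); seeds are
jittered uniformly within their face. Defaults (`minimum_potential = 0`,
`line_density = 5`) were chosen once from the surface-potential scale of
the dipole fixture to give a few dozen lines; both are user controls in
every interface. Seeding is on the surface with a half-step outward
offset (below), not in the volume — a documented choice, since either
reading is defensible.

**Integration.** Fixed-step Euler on the *normalized* gradient, default
step = half the smallest grid spacing. Normalization prevents step
blow-up near charges and makes the step a length in Å; an RK2 upgrade
would be a drop-in (the integrator is one local function). Each seed is
traced both ways and the halves concatenated, oriented so interpolated
EP at the first point ≥ at the last (positive → negative, matching the
physics convention for field lines). Termination, recorded per line:
the grid boundary (the final point is clipped exactly onto the box), a
segment–triangle mesh intersection (uniform spatial hash of triangles;
the intersection point ends the line), gradient magnitude below
`low_field_threshold` (default 1e-4 field-units/Å, user-overridable), or
a `max_points` cap. Seeds are lifted half a step along the outward face
normal before tracing; the mesh test then runs on *every* step,
including the first — a first step that dives back through the seed's
own face is a genuine, immediate termination (this is exactly what
happens to the downstream half of a line seeded on a negatively charged
patch).

**Degenerate inputs.** A neutral structure yields an identically zero
field, zero candidate weight and zero lines. A vanished field at the
seed yields a single-point line terminated `low_field`. Ties in the
weighted draw are resolved by the seeded generator, never by platform
iteration order; all Monte Carlo stages restore the caller's RNG stream.

## Particle schedules

Field lines are emitters at their positive ends. With 0-based frames and
first emission at frame 0, a particle is born every `emission_period`
frames (default 5 = 0.2 s at 25 fps) and lives `lifetime` frames
(default 20 = 0.8 s), its curve parameter $t = \mathrm{age} /
\mathrm{lifetime}$ advancing at constant parametric speed (the speed law
along the curve is not otherwise constrained; constant-parameter is the
simplest defensible choice, and one particle per emission event is
assumed). The live count per line reaches its steady maximum
$\lceil \mathrm{lifetime}/\mathrm{period} \rceil = 4$ at frame 15 =
0.6 s — `steady_state_time()` finds this by brute-force simulation
rather than closed form, so the schedule logic is what is being
exercised. The 0-based convention is what reconciles a 1-based
"sixteenth frame" with 0.6 s. In single-conformation loop mode emission
stops after frame 250 and the system drains over one more lifetime.

## Surfaces

No marching-cubes implementation is available among this package's
dependencies, so polygonization is implemented here as marching
tetrahedra: each lattice cube is split into six tetrahedra sharing the
main diagonal, which makes face diagonals agree between neighboring
cubes and the resulting triangulation watertight by construction.
Surface vertices lie on lattice edges (linear interpolation of the
density), triangles are oriented outward, and exact-iso node values are
nudged by 1e-9 of the value range so no zero-area triangle can arise.

The density is a Gaussian sum $\sum_i \exp(-k\, (d_i/R_i)^2)$ with $R_i
= r_i + \mathrm{probe}$ (probe default 1.4 Å, water) and $k = \ln 2$,
polygonized at iso $= e^{-k}$ so a lone atom's surface sits exactly at
$R_i$; meshes of merging atoms fuse with the same topology-merging
behavior as a solvent-excluded surface, though the geometry is smoother
than a true Connolly surface in crevices (an accepted stand-in; exact
SES is a non-goal). Two light vertex-averaging passes (λ = 0.5) remove
lattice anisotropy; at the default voxel the induced shrinkage is far
below the 5% area tolerance the tests enforce. A single atom meshed at
voxel 0.25 Å reproduces the analytic sphere area to under 1%. Internal
cavity surfaces are kept by default; `drop_enclosed = TRUE` removes
components nested inside another component by a point-in-mesh parity
test. The default voxel 1.0 Å matches the ~1 Å mean-edge target that
pairs with the default potential-grid spacing.

## Determinism and reproducibility

One master seed drives everything: per frame, the seed-selection RNG is
re-derived as `rng_seed + frame_index`, so frames are independent (any
model order permutation permutes outputs identically) yet a full run is
byte-deterministic — the suite asserts identical bytes for line and
schedule files across repeated runs. Every run writes its resolved
configuration as YAML next to the outputs; reading it back
(`read_pipeline_config()`) reproduces the run bit-identically.

## Problem sizes and what the tests show

All tests run on synthetic fixtures: point-set "molecules" of 1–20 atoms
(monopole, dipole, quadrupole, amphipathic rod, mini-helix), grids up to
about 21³, meshes of a few thousand triangles. These sizes exercise
every code path — topology merging, both termination-rich tracing
regimes, the Monte Carlo seeding statistics at n = 10,000 — while each
oracle (closed-form Debye–Hückel, analytic sphere area, brute-force
triple loops, binomial sampling bounds) stays independently computable.

What they do *not* establish: fixtures have no conformational strain, no
real charge distributions (PQR charge assignment is upstream and out of
scope), no dielectric boundary physics, and protein-scale grids are
larger by two orders of magnitude. The monopole radiality checks are
asserted outside ~3 grid cells of the charge, where the lattice actually
resolves the 1/r field; inside that core the discrete field is dominated
by the singularity clamp. Passing tests therefore validate the
machinery and its documented numerics, not the biophysical accuracy of
the screened-Coulomb approximation on real proteins — for that, import
an externally solved Poisson–Boltzmann grid.

## Known limitations

- The built-in EP solver has no dielectric boundary and no ion
  exclusion layer; magnitudes near the surface differ from a
  Poisson–Boltzmann solve (direction fields, which drive the lines, are
  affected less).
- Euler integration with a fixed step can ping-pong across a point
  sink instead of converging onto it; such lines end at `max_points`.
  In practice sinks are enclosed by mesh, and lines terminate on it
  first.
- The shipped fragment table is illustrative; quantitative MLP work
  should substitute a published set.
- Exact solvent-excluded surfaces, mmCIF input, compressed files, UV
  unwrapping/texture baking and any rendering are out of scope.
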