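# Electrostatic potential (EP) grids.
#
# The faithful path is importing an externally solved Poisson-Boltzmann
# grid (load_ep_grid on an APBS-style .dx). The built-in solver is a
# uniform-dielectric screened-Coulomb (Debye-Huckel) approximation:
#
#   phi(r) [kT/e] = l_B * sum_i q_i * exp(-kappa |r - r_i|) / |r - r_i|
#
# with l_B the Bjerrum length in the solvent dielectric and kappa the
# inverse Debye length from the ionic strength. There is no dielectric
# boundary: solute_dielectric is accepted (and recorded) but unused.

.phys <- list(
  e = 1.602176634e-19,        # C
  kB = 1.380649e-23,          # J/K
  eps0 = 8.8541878128e-12,    # F/m
  NA_ = 6.02214076e23)        # 1/mol

#' Electrostatic parameters
#'
#' Defaults follow standard continuum-electrostatics practice for proteins
#' in physiological saline: 0.150 mol/L NaCl, solute dielectric 2, solvent
#' (water) dielectric 78.54, 298.15 K.
#'
#' @param ionic_strength mol/L of 1:1 salt.
#' @param solute_dielectric dimensionless (recorded; unused by the built-in
#'   screened-Coulomb solver, which has no dielectric boundary).
#' @param solvent_dielectric dimensionless.
#' @param temperature K.
#' @param spacing grid spacing, Angstrom.
#' @param padding grid margin around the structure, Angstrom.
#' @return an object of class `ep_parameters`.
#' @export
ep_parameters <- function(ionic_strength = 0.150, solute_dielectric = 2,
                          solvent_dielectric = 78.54, temperature = 298.15,
                          spacing = 1.0, padding = 5.0) {
  vals <- c(ionic_strength = ionic_strength, solute_dielectric = solute_dielectric,
            solvent_dielectric = solvent_dielectric, temperature = temperature,
            spacing = spacing, padding = padding)
  if (any(!is.finite(vals)) || any(vals[-1] <= 0) || ionic_strength < 0)
    stopf("ep_parameters: all parameters must be positive (ionic_strength >= 0)")
  structure(as.list(vals), class = "ep_parameters")
}

#' Debye screening constant
#'
#' `kappa = sqrt(2 * 1000 * NA * I * e^2 / (eps0 * eps_s * kB * T))`,
#' converted to 1/Angstrom. About 0.127 1/A at 0.150 mol/L and 298.15 K in
#' water.
#'
#' @param params an [ep_parameters()].
#' @return kappa in 1/Angstrom.
#' @export
debye_kappa <- function(params = ep_parameters()) {
  n <- 1000 * .phys$NA_ * params$ionic_strength  # ions per m^3 per species
  k2 <- 2 * n * .phys$e^2 /
    (.phys$eps0 * params$solvent_dielectric * .phys$kB * params$temperature)
  sqrt(k2) * 1e-10
}

#' Bjerrum length in the solvent dielectric
#'
#' `l_B = e^2 / (4 pi eps0 eps_s kB T)` in Angstrom (about 7.14 A in water
#' at 298.15 K): the prefactor that makes the screened-Coulomb sum come out
#' in kT/e for charges in elementary-charge units and distances in Angstrom.
#'
#' @param params an [ep_parameters()].
#' @return length in Angstrom.
#' @export
bjerrum_length <- function(params = ep_parameters()) {
  .phys$e^2 / (4 * pi * .phys$eps0 * params$solvent_dielectric *
               .phys$kB * params$temperature) * 1e10
}

#' Thermal voltage kT/e
#'
#' Conversion factor between the internal kT/e potential unit and volts
#' (equivalently eV per elementary charge): about 0.02569 V at 298.15 K.
#'
#' @param temperature K.
#' @return kT/e in volts.
#' @export
kT_electronvolts <- function(temperature = 298.15) {
  .phys$kB * temperature / .phys$e
}

#' Net charge of a structure
#'
#' @param structure a [structure3d()] with charges (PQR input).
#' @return sum of partial charges, elementary charges.
#' @export
net_charge <- function(structure) {
  stopifnot(inherits(structure, "structure3d"))
  q <- structure$atoms$charge
  if (length(q) == 0L) stopf("net_charge: empty atom selection")
  if (any(is.na(q)))
    stopf("net_charge: atoms lack charges; supply a PQR file")
  sum(q)
}

#' Compute a screened-Coulomb EP grid
#'
#' Evaluates the Debye-Huckel potential (see the file header) in kT/e on a
#' lattice covering the structure plus padding. Grid nodes closer than
#' 0.1 Angstrom to an atom are clamped to the value at 0.1 Angstrom so the
#' Coulomb singularity never reaches the grid.
#'
#' @param structure a [structure3d()] whose atoms all carry charges.
#' @param params an [ep_parameters()].
#' @param geometry optional explicit grid geometry (`origin`, `spacing`,
#'   `counts`) overriding the bounding-box layout.
#' @return a [scalar_grid()] of EP values in kT/e.
#' @export
compute_ep_grid <- function(structure, params = ep_parameters(), geometry = NULL) {
  stopifnot(inherits(structure, "structure3d"), inherits(params, "ep_parameters"))
  q <- structure$atoms$charge
  if (any(is.na(q)))
    stopf("compute_ep_grid: atoms lack charges; supply PQR input (or load an external .dx with load_ep_grid)")
  centers <- atom_coords(structure)
  geom <- geometry %||% grid_geometry_for(centers, params$spacing, params$padding)
  if (length(geom$spacing) == 1L) geom$spacing <- rep(geom$spacing, 3L)
  n <- geom$counts
  kap <- debye_kappa(params)
  lB <- bjerrum_length(params)
  ax <- lapply(1:3, function(a) geom$origin[a] + (seq_len(n[a]) - 1L) * geom$spacing[a])
  vals <- array(0, dim = n)
  for (i in seq_len(nrow(centers))) {
    if (q[i] == 0) next
    d2 <- outer(outer((ax[[1]] - centers[i, 1])^2,
                      (ax[[2]] - centers[i, 2])^2, "+"),
                (ax[[3]] - centers[i, 3])^2, "+")
    d <- pmax(sqrt(d2), 0.1)  # singularity clamp
    vals <- vals + lB * q[i] * exp(-kap * d) / d
  }
  scalar_grid(geom$origin, geom$spacing, n, vals)
}

#' Load an externally computed EP grid
#'
#' Delegates to [read_dx()]; the potential unit of an external grid is
#' whatever its producer wrote, so the grid is tagged with a `units`
#' attribute `"as-labeled"` rather than converted.
#'
#' @param path path to an OpenDX file.
#' @return a [scalar_grid()] with `attr(, "units") == "as-labeled"`.
#' @export
load_ep_grid <- function(path) {
  grid <- read_dx(path)
  attr(grid, "units") <- "as-labeled"
  grid
}
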