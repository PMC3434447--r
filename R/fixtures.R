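# Synthetic test molecules: small point sets with charges, radii and
# symbolic lipophilic fragment values (+-1, +-0.5 rather than library
# values, so MLP tests are fragment-library independent). They stand in
# for real protein inputs at desk scale; no download is ever required.

fixture_atoms <- function(pos, charge, f, radius = 1.5) {
  n <- nrow(pos)
  data.frame(serial = seq_len(n),
             name = paste0("C", seq_len(n)),
             element = "C",
             residue_name = "FIX",
             residue_id = seq_len(n),
             chain = "A",
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             charge = charge, radius = radius, f = f,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic fixture molecule
#'
#' Kinds: `monopole` (one +1 e atom), `dipole` (+1/-1 e, 6 Angstrom apart,
#' net charge 0), `quadrupole` (alternating charges on a square),
#' `amphipathic_rod` (two parallel atom rows, one face with f = +1, the
#' other f = -1, exercising the MLP gray contrast; alternating small
#' charges summing to 0) and `mini_helix` (atoms on a helix with seeded
#' small charges adjusted to the declared net charge). Deterministic for a
#' fixed `rng_seed`, including the PQR bytes written when `dir` is given.
#'
#' @param kind fixture kind.
#' @param n_atoms atom count (rod and helix kinds; defaults 20 and 12).
#' @param rng_seed integer seed.
#' @param dir if non-NULL, also write `<dir>/<kind>.pqr`.
#' @param net_charge declared net charge (helix kind), elementary charges.
#' @return a [structure3d()] whose atom table includes the `f` column; when
#'   written, the path is attached as attribute `"pqr_path"`.
#' @export
make_fixture <- function(kind = c("monopole", "dipole", "quadrupole",
                                  "amphipathic_rod", "mini_helix"),
                         n_atoms = NULL, rng_seed = 1L, dir = NULL,
                         net_charge = 0) {
  kind <- match.arg(kind)
  atoms <- switch(kind,
    monopole = fixture_atoms(matrix(0, 1, 3), charge = 1, f = 1),
    dipole = fixture_atoms(rbind(c(-3, 0, 0), c(3, 0, 0)),
                           charge = c(1, -1), f = c(1, -1)),
    quadrupole = fixture_atoms(rbind(c(-3, -3, 0), c(3, -3, 0),
                                     c(3, 3, 0), c(-3, 3, 0)),
                               charge = c(1, -1, 1, -1), f = c(1, -1, 1, -1)),
    amphipathic_rod = {
      n <- n_atoms %||% 20L
      if (n %% 2L != 0L) stopf("make_fixture: amphipathic_rod needs an even atom count")
      half <- n %/% 2L
      xs <- seq(0, by = 1.8, length.out = half)
      pos <- rbind(cbind(xs, 1.5, 0), cbind(xs, -1.5, 0))
      q <- rep(c(0.1, -0.1), length.out = n)
      if (n %% 4L != 0L) q <- q - sum(q) / n  # keep the declared net charge 0
      fixture_atoms(pos, charge = q, f = rep(c(1, -1), each = half))
    },
    mini_helix = {
      n <- n_atoms %||% 12L
      th <- (seq_len(n) - 1L) * 100 * pi / 180
      pos <- cbind(2.3 * cos(th), 2.3 * sin(th), (seq_len(n) - 1L) * 1.5)
      q <- with_seed(rng_seed, round(stats::runif(n, -0.5, 0.5), 4))
      q[n] <- round(net_charge - sum(q[-n]), 4)
      fixture_atoms(pos, charge = q, f = rep(c(0.5, -0.5), length.out = n))
    })
  s <- structure3d(atoms)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    path <- file.path(dir, paste0(kind, ".pqr"))
    write_structure(s, path)
    attr(s, "pqr_path") <- path
  }
  s
}

#' Closed-form screened-Coulomb grid for a single charge at the origin
#'
#' Independent oracle for the EP stage and the field-line radiality checks:
#' evaluates `l_B * q * exp(-kappa d) / max(d, 0.1)` (kT/e) directly on the
#' requested lattice.
#'
#' @param q charge, elementary charges.
#' @param params an [ep_parameters()].
#' @param geometry list with `origin`, `spacing`, `counts`.
#' @return a [scalar_grid()].
#' @export
analytic_monopole_grid <- function(q, params = ep_parameters(), geometry) {
  if (length(geometry$spacing) == 1L) geometry$spacing <- rep(geometry$spacing, 3L)
  n <- geometry$counts
  kap <- debye_kappa(params)
  lB <- bjerrum_length(params)
  ax <- lapply(1:3, function(a)
    geometry$origin[a] + (seq_len(n[a]) - 1L) * geometry$spacing[a])
  d <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  vals <- lB * q * exp(-kap * pmax(d, 0.1)) / pmax(d, 0.1)
  scalar_grid(geometry$origin, geometry$spacing, n, vals)
}
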