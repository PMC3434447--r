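# Molecular lipophilic potential (MLP) on a regular grid.
#
# MLP(r) = sum_i f_i * kernel(|r - r_i|), where f_i is the atomic lipophilic
# fragment value of atom i (Broto-style atom-level decomposition of
# octanol/water partition contributions) and the kernel is a decaying
# distance function. Positive MLP = hydrophobic, negative = hydrophilic;
# surface values on proteins typically fall between -3 and 1.

#' Default MLP grid spacing
#'
#' 1 Angstrom: comparable to the mean triangle-edge length of the default
#' surface mesh, and a good compromise between field resolution and cost.
#'
#' @return 1.0 (Angstrom).
#' @export
default_spacing <- function() 1.0

#' MLP distance kernels
#'
#' Named, pluggable distance-decay kernels: `testa` uses exponential decay
#' `exp(-d/2)` (Broto fragment values with an exponential distance
#' function); `fauchere` uses `exp(-d)`; `dubost` the hyperbolic
#' `100/(1+d)`; `brasseur` shares the `exp(-d/2)` decay (its native
#' fragment set is unified into the single shipped library). All kernels
#' are finite at d = 0 and vanish as d grows; the `testa` kernel has
#' kernel(0) = 1.
#'
#' @param name one of `"testa"`, `"fauchere"`, `"dubost"`, `"brasseur"`.
#' @return an object of class `mlp_formula` with fields `name` and
#'   `kernel` (a vectorized function of distance in Angstrom).
#' @export
mlp_formula <- function(name = c("testa", "fauchere", "dubost", "brasseur")) {
  name <- match.arg(name)
  kernel <- switch(name,
    testa = function(d) exp(-d / 2),
    fauchere = function(d) exp(-d),
    dubost = function(d) 100 / (1 + d),
    brasseur = function(d) exp(-d / 2))
  structure(list(name = name, kernel = kernel), class = "mlp_formula")
}

#' Load a lipophilic fragment library
#'
#' Reads a columnar text table mapping `(residue, atom)` to a fragment
#' value `f`, with element-level fallback rows (residue `*`, atom = element
#' symbol). The shipped table (`inst/extdata/mlp_fragments.tsv`) is a
#' rule-based synthetic set covering the heavy atoms of the 20 standard
#' amino acids plus element fallbacks (hydrogens included); it is data, not
#' validated science, and can be swapped for any table in the same format.
#'
#' @param path table path; default the packaged table.
#' @return an object of class `lipophilic_library`.
#' @export
read_lipophilic_library <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mlp_fragments.tsv",
                                package = "surfscape", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("residue", "atom", "f") %in% names(tab)))
    stopf("read_lipophilic_library: %s must have columns residue, atom, f", path)
  env <- new.env(parent = emptyenv(), size = nrow(tab) * 2L)
  spec <- tab$residue != "*"
  for (i in which(spec))
    assign(paste0(tab$residue[i], "|", tab$atom[i]), tab$f[i], envir = env)
  fallback <- tab$f[!spec]
  names(fallback) <- toupper(tab$atom[!spec])
  structure(list(env = env, fallback = fallback, path = path),
            class = "lipophilic_library")
}

#' Look up per-atom fragment values
#'
#' Resolution order: exact `(residue, atom name)` entry, then element
#' fallback; an atom matching neither raises an error naming the residue
#' and atom.
#'
#' @param library a [read_lipophilic_library()] object.
#' @param structure a [structure3d()].
#' @return numeric vector of f values, one per atom.
#' @export
lipophilic_values <- function(library, structure) {
  stopifnot(inherits(library, "lipophilic_library"))
  a <- structure$atoms
  vapply(seq_len(nrow(a)), function(i) {
    key <- paste0(a$residue_name[i], "|", a$name[i])
    if (exists(key, envir = library$env, inherits = FALSE))
      return(get(key, envir = library$env))
    el <- toupper(a$element[i])
    if (el %in% names(library$fallback)) return(library$fallback[[el]])
    stopf("lipophilic_values: no fragment value for atom '%s' of residue '%s' (element %s)",
          a$name[i], a$residue_name[i], a$element[i])
  }, numeric(1))
}

#' Compute the MLP on a regular grid
#'
#' Evaluates `MLP(r) = sum_i f_i * kernel(|r - r_i|)` on a lattice covering
#' the structure's bounding box plus `padding` on all sides. Contributions
#' beyond `cutoff` (default 12 Angstrom, where the testa kernel is below
#' e^-6 of its peak) are dropped, keeping the cost proportional to the
#' molecule size.
#'
#' @param structure a [structure3d()]; if its atom table has an `f` column,
#'   those fragment values are used directly (library-independent fixtures),
#'   otherwise they are resolved through `library`.
#' @param library a [read_lipophilic_library()]; defaults to the packaged
#'   table.
#' @param formula an [mlp_formula()] (default `"testa"`).
#' @param spacing grid spacing, Angstrom (default [default_spacing()]).
#' @param padding margin around the atom bounding box, Angstrom.
#' @param cutoff distance cutoff, Angstrom (`Inf` disables it).
#' @param geometry optional explicit grid geometry (list with `origin`,
#'   `spacing`, `counts`), overriding the bounding-box layout.
#' @return a [scalar_grid()] of dimensionless MLP values.
#' @export
compute_mlp_grid <- function(structure, library = NULL,
                             formula = mlp_formula("testa"),
                             spacing = default_spacing(), padding = 5,
                             cutoff = 12, geometry = NULL) {
  stopifnot(inherits(structure, "structure3d"), inherits(formula, "mlp_formula"))
  if (!is_number(spacing) || spacing <= 0)
    stopf("compute_mlp_grid: spacing must be > 0")
  if (!is_number(padding) || padding < 0)
    stopf("compute_mlp_grid: padding must be >= 0")
  f <- structure$atoms$f
  if (is.null(f)) {
    library <- library %||% read_lipophilic_library()
    f <- lipophilic_values(library, structure)
  }
  centers <- atom_coords(structure)
  geom <- geometry %||% grid_geometry_for(centers, spacing, padding)
  if (length(geom$spacing) == 1L) geom$spacing <- rep(geom$spacing, 3L)
  n <- geom$counts
  vals <- array(0, dim = n)
  ax <- lapply(1:3, function(a) geom$origin[a] + (seq_len(n[a]) - 1L) * geom$spacing[a])
  for (i in seq_len(nrow(centers))) {
    rng <- if (is.finite(cutoff)) {
      lapply(1:3, function(a)
        which(ax[[a]] >= centers[i, a] - cutoff & ax[[a]] <= centers[i, a] + cutoff))
    } else lapply(1:3, function(a) seq_len(n[a]))
    if (any(lengths(rng) == 0L)) next
    d2 <- outer(outer((ax[[1]][rng[[1]]] - centers[i, 1])^2,
                      (ax[[2]][rng[[2]]] - centers[i, 2])^2, "+"),
                (ax[[3]][rng[[3]]] - centers[i, 3])^2, "+")
    contrib <- f[i] * formula$kernel(sqrt(d2))
    if (is.finite(cutoff)) contrib[d2 > cutoff^2] <- 0
    vals[rng[[1]], rng[[2]], rng[[3]]] <- vals[rng[[1]], rng[[2]], rng[[3]]] + contrib
  }
  if (any(!is.finite(vals))) stopf("compute_mlp_grid: non-finite grid values")
  scalar_grid(geom$origin, geom$spacing, n, vals)
}
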