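#' Read an OpenDX regular scalar grid
#'
#' Supports the "regular positions, regular connections" dialect used by
#' Poisson-Boltzmann solvers and MLP tools: a header defining the grid
#' origin, the per-axis deltas and the number of points on each axis,
#' followed by the data values with the last (z) axis varying fastest.
#' Non-diagonal delta rows (a sheared lattice) are rejected.
#'
#' @param path path to a `.dx` file.
#' @return a [scalar_grid()].
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stopf("read_dx: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]
  gp <- grep("class gridpositions counts", lines, fixed = TRUE)
  if (!length(gp)) stopf("read_dx: %s: missing 'gridpositions counts' header (unsupported dialect)", path)
  tk <- toks(lines[gp[1]])
  counts <- suppressWarnings(as.integer(tk[(length(tk) - 2L):length(tk)]))
  if (any(is.na(counts))) stopf("read_dx: %s: malformed counts header", path)
  oi <- grep("^\\s*origin\\b", lines)
  if (!length(oi)) stopf("read_dx: %s: missing origin", path)
  origin <- as.numeric(toks(lines[oi[1]])[2:4])
  di <- grep("^\\s*delta\\b", lines)
  if (length(di) < 3L) stopf("read_dx: %s: expected 3 delta rows", path)
  deltas <- t(vapply(lines[di[1:3]], function(l) as.numeric(toks(l)[2:4]),
                     numeric(3)))
  offdiag <- deltas; diag(offdiag) <- 0
  if (any(abs(offdiag) > 0))
    stopf("read_dx: %s: non-diagonal delta matrix (sheared grids are unsupported)", path)
  spacing <- diag(deltas)
  ai <- grep("class array", lines, fixed = TRUE)
  if (!length(ai)) stopf("read_dx: %s: missing data array object", path)
  nitems <- prod(counts)
  body <- lines[(ai[1] + 1L):length(lines)]
  body <- body[!grepl("^\\s*(attribute|object|component|end)\\b", body)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "[[:space:]]+"),
                                             use.names = FALSE)))
  vals <- vals[!is.na(vals)]
  if (length(vals) < nitems)
    stopf("read_dx: %s: expected %d values, found %d", path, nitems, length(vals))
  vals <- vals[seq_len(nitems)]
  # OpenDX stores z fastest; R arrays store the first index fastest
  arr <- aperm(array(vals, dim = rev(counts)), c(3L, 2L, 1L))
  scalar_grid(origin, spacing, counts, arr)
}

#' Write a scalar grid as an OpenDX file
#'
#' Inverse of [read_dx()]: full-precision round-trip on origin, spacing,
#' counts and values, with the OpenDX value ordering (last axis fastest).
#'
#' @param grid a [scalar_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "scalar_grid"))
  n <- grid$counts
  vals <- as.vector(aperm(grid$values, c(3L, 2L, 1L)))  # z fastest
  ntot <- length(vals)
  pad <- c(vals, rep(NA_real_, (3L - ntot %% 3L) %% 3L))
  rows <- matrix(sprintf("%.17g", pad), nrow = 3L)
  txt <- apply(rows, 2, function(r) paste(r[r != "NA"], collapse = " "))
  hdr <- c(
    "# OpenDX scalar grid written by surfscape",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.17g %.17g %.17g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.17g 0.0 0.0", grid$spacing[1]),
    sprintf("delta 0.0 %.17g 0.0", grid$spacing[2]),
    sprintf("delta 0.0 0.0 %.17g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", ntot))
  ftr <- c('attribute "dep" string "positions"',
           'object "regular positions regular connections" class field',
           'component "positions" value 1',
           'component "connections" value 2',
           'component "data" value 3')
  writeLines(c(hdr, txt, ftr), path)
  invisible(path)
}
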