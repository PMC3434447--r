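#' Atomic structure container
#'
#' One conformation (frame) of a molecule: an ordered atom table plus a frame
#' index. Atom fields follow the PDB/PQR column semantics; in PQR files the
#' occupancy and temperature-factor columns carry per-atom partial charge
#' (elementary charges) and radius (Angstrom) instead. Plain-PDB atoms get
#' `charge = NA` and `radius = NA` (not 0), so charge-dependent stages fail
#' loudly rather than silently computing a zero field. An optional `f` column
#' holds per-atom lipophilic fragment values (used by fixtures and honored by
#' [compute_mlp_grid()] in place of a library lookup).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `residue_id`, `chain`, `x`, `y`, `z` and optionally
#'   `charge`, `radius`, `f`.
#' @param frame_index integer >= 0.
#' @param source_path origin file, for messages.
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(atoms, frame_index = 0L, source_path = NA_character_) {
  req <- c("serial", "name", "element", "residue_name", "residue_id",
           "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stopf("structure3d: missing atom columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(atoms) < 1L) stopf("structure3d: at least one atom required")
  if (anyDuplicated(atoms$serial))
    stopf("structure3d: duplicate atom serials within a frame")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stopf("structure3d: non-finite atom coordinates")
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  r <- atoms$radius[!is.na(atoms$radius)]
  if (any(r <= 0)) stopf("structure3d: atom radii must be > 0")
  structure(list(atoms = atoms, frame_index = as.integer(frame_index),
                 source_path = source_path),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms (frame %d)%s\n", nrow(x$atoms),
              x$frame_index,
              if (is.na(x$source_path)) "" else paste0(" from ", x$source_path)))
  cat(sprintf("  charges: %s, radii: %s\n",
              if (all(is.na(x$atoms$charge))) "absent" else "present",
              if (all(is.na(x$atoms$radius))) "absent" else "present"))
  invisible(x)
}

atom_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# derive the element symbol from a PDB atom name ("1HB " -> H, " CA " -> C)
element_from_name <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  ifelse(nchar(s) == 0L, "X", toupper(substr(s, 1L, 1L)))
}

# split file lines into per-model line-index ranges; models are parsed
# lazily so a corrupt model only fails its own frame
model_line_ranges <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(seq_along(lines)))
  ends <- grep("^ENDMDL", lines)
  lapply(seq_along(starts), function(k) {
    e <- ends[ends > starts[k]]
    e <- if (length(e)) e[1] else length(lines) + 1L
    seq(starts[k] + 1L, e - 1L)
  })
}

#' Number of models in a PDB/PQR file
#'
#' @param path file path.
#' @return integer count (1 for files without MODEL records).
#' @export
count_models <- function(path) {
  length(model_line_ranges(readLines(path, warn = FALSE)))
}

parse_pdb_atoms <- function(lines, line_numbers, path) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[sel]; line_numbers <- line_numbers[sel]
  if (!length(lines)) stopf("%s: no ATOM/HETATM records in requested model", path)
  num <- function(txt, ln, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("%s: parse error at line %d: bad %s field '%s'",
            path, ln[bad[1]], what, txt[bad[1]])
    v
  }
  short <- which(nchar(lines) < 54L)
  if (length(short))
    stopf("%s: parse error at line %d: ATOM record shorter than 54 columns",
          path, line_numbers[short[1]])
  fld <- function(a, b) trimws(substr(lines, a, b))
  elem <- fld(77, 78)
  name <- fld(13, 16)
  elem <- ifelse(elem == "", element_from_name(name), toupper(elem))
  data.frame(
    serial = as.integer(num(fld(7, 11), line_numbers, "serial")),
    name = name,
    element = elem,
    residue_name = fld(18, 20),
    residue_id = as.integer(num(fld(23, 26), line_numbers, "residue id")),
    chain = fld(22, 22),
    x = num(fld(31, 38), line_numbers, "x"),
    y = num(fld(39, 46), line_numbers, "y"),
    z = num(fld(47, 54), line_numbers, "z"),
    charge = NA_real_,
    radius = NA_real_,
    stringsAsFactors = FALSE)
}

# PQR is whitespace-tokenized (PDB2PQR widens columns on overflow):
# ATOM serial name resname [chain] resid x y z charge radius
parse_pqr_atoms <- function(lines, line_numbers, path) {
  sel <- grepl("^(ATOM|HETATM)", lines)
  lines <- lines[sel]; line_numbers <- line_numbers[sel]
  if (!length(lines)) stopf("%s: no ATOM/HETATM records in requested model", path)
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!length(tok) %in% c(10L, 11L))
      stopf("%s: parse error at line %d: expected 10 or 11 fields, got %d",
            path, line_numbers[i], length(tok))
    has_chain <- length(tok) == 11L
    numtok <- suppressWarnings(as.numeric(tok[(length(tok) - 5L):length(tok)]))
    if (any(!is.finite(numtok)))
      stopf("%s: parse error at line %d: non-numeric coordinate/charge/radius",
            path, line_numbers[i])
    data.frame(
      serial = as.integer(tok[2]),
      name = tok[3],
      element = element_from_name(tok[3]),
      residue_name = tok[4],
      residue_id = as.integer(numtok[1]),
      chain = if (has_chain) tok[5] else "",
      x = numtok[2], y = numtok[3], z = numtok[4],
      charge = numtok[5], radius = numtok[6],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a structure from a PDB or PQR file
#'
#' The extension selects the dialect: `.pdb` is parsed fixed-width, `.pqr`
#' whitespace-tokenized with the last two fields of each ATOM record read as
#' partial charge (e) and radius (Angstrom). For multi-model files, model
#' `k` (0-based `frame`) is returned; models are parsed independently, so a
#' malformed model does not prevent reading the others.
#'
#' @param path file path ending in `.pdb` or `.pqr`.
#' @param frame 0-based model index (default 0).
#' @return a [structure3d()].
#' @export
read_structure <- function(path, frame = 0L) {
  if (!file.exists(path)) stopf("read_structure: no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("pdb", "pqr"))
    stopf("read_structure: unrecognized extension '.%s' (expected .pdb or .pqr)", ext)
  lines <- readLines(path, warn = FALSE)
  ranges <- model_line_ranges(lines)
  frame <- as.integer(frame)
  if (frame < 0L || frame >= length(ranges))
    stopf("read_structure: model %d not present in %s (%d model%s)",
          frame, path, length(ranges), if (length(ranges) == 1L) "" else "s")
  idx <- ranges[[frame + 1L]]
  atoms <- if (ext == "pqr") parse_pqr_atoms(lines[idx], idx, path)
           else parse_pdb_atoms(lines[idx], idx, path)
  structure3d(atoms, frame_index = frame, source_path = path)
}

format_pqr_atom <- function(a) {
  sprintf("ATOM  %5d %-4s %-4s%1s %4d    %8.3f %8.3f %8.3f %8.4f %7.4f",
          a$serial, a$name, a$residue_name,
          ifelse(a$chain == "", " ", a$chain), a$residue_id,
          a$x, a$y, a$z, a$charge, a$radius)
}

format_pdb_atom <- function(a) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial, a$name, a$residue_name,
          ifelse(a$chain == "", " ", a$chain), a$residue_id,
          a$x, a$y, a$z, 1, 0, a$element)
}

#' Write structures to a PDB or PQR file
#'
#' A single structure is written as a plain file; a list of structures as a
#' multi-model file (MODEL/ENDMDL), one model per animation frame.
#'
#' @param structures a [structure3d()] or list of them.
#' @param path output path; the extension (`.pdb`/`.pqr`) selects the format.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structures, path) {
  if (inherits(structures, "structure3d")) structures <- list(structures)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("pdb", "pqr"))
    stopf("write_structure: unrecognized extension '.%s'", ext)
  fmt <- if (ext == "pqr") format_pqr_atom else format_pdb_atom
  out <- character(0)
  multi <- length(structures) > 1L
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    if (ext == "pqr" && any(is.na(s$atoms$charge) | is.na(s$atoms$radius)))
      stopf("write_structure: PQR output needs charge and radius on every atom")
    if (multi) out <- c(out, sprintf("MODEL %8d", k))
    out <- c(out, vapply(seq_len(nrow(s$atoms)),
                         function(i) fmt(s$atoms[i, ]), character(1)))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
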