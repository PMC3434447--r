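# Wavefront OBJ interchange, with the per-vertex MLP channel carried in
# the texture coordinates: one "vt" record per vertex with U = 0 and V =
# the raw MLP value, and faces referencing matching vertex/texture indices.

#' Write a mesh as OBJ with the MLP channel in texture coordinates
#'
#' @param mesh a [triangle_mesh()] with an `mlp` channel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj_with_mlp <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) == 0L)
    stopf("write_obj_with_mlp: refusing to write an empty mesh")
  mlp <- mesh$channels$mlp
  if (is.null(mlp))
    stopf("write_obj_with_mlp: mesh has no 'mlp' channel")
  v <- mesh$vertices
  out <- c("# OBJ written by surfscape; vt V carries the per-vertex MLP value",
           sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
           sprintf("vt 0.000000 %.6f", mlp),
           sprintf("f %d/%d %d/%d %d/%d",
                   mesh$triangles[, 1], mesh$triangles[, 1],
                   mesh$triangles[, 2], mesh$triangles[, 2],
                   mesh$triangles[, 3], mesh$triangles[, 3]))
  writeLines(out, path)
  invisible(path)
}

#' Read an OBJ mesh
#'
#' Parses `v`, `vt` and triangular `f` records (polygonal faces are
#' fan-triangulated). When one texture coordinate exists per vertex and
#' faces pair each vertex with its own texture index, the V coordinates are
#' recovered as the `mlp` channel.
#'
#' @param path OBJ file path.
#' @return a [triangle_mesh()].
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stopf("read_obj: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  tk <- strsplit(trimws(lines), "[[:space:]]+")
  tag <- vapply(tk, function(t) if (length(t)) t[1] else "", character(1))
  vs <- tk[tag == "v"]
  vts <- tk[tag == "vt"]
  fs <- tk[tag == "f"]
  if (!length(vs)) stopf("read_obj: %s contains no vertices", path)
  verts <- t(vapply(vs, function(t) as.numeric(t[2:4]), numeric(3)))
  tris <- list()
  for (t in fs) {
    idx <- vapply(strsplit(t[-1], "/"), function(p) as.integer(p[1]), integer(1))
    if (anyNA(idx)) stopf("read_obj: %s: malformed face record '%s'",
                          path, paste(t, collapse = " "))
    for (k in seq_len(length(idx) - 2L))
      tris[[length(tris) + 1L]] <- c(idx[1], idx[k + 1L], idx[k + 2L])
  }
  tris <- if (length(tris)) do.call(rbind, tris) else matrix(0L, 0, 3)
  channels <- list()
  if (length(vts) == nrow(verts)) {
    vvals <- vapply(vts, function(t) as.numeric(t[3]), numeric(1))
    channels$mlp <- unname(vvals)
  }
  triangle_mesh(verts, tris, channels)
}

#' Write/read per-vertex channels as a sidecar table
#'
#' Columnar text keyed by vertex index, carrying every channel attached to
#' the mesh (ep, gray, specular, roughness, noise_amplitude, ...); the OBJ
#' itself only carries MLP.
#'
#' @param mesh a [triangle_mesh()] with at least one channel.
#' @param path output path (TSV).
#' @return `path` invisibly; `read_vertex_channels` returns a data.frame.
#' @export
write_vertex_channels <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!length(mesh$channels))
    stopf("write_vertex_channels: mesh has no channels")
  df <- data.frame(vertex = seq_len(nrow(mesh$vertices)))
  for (nm in names(mesh$channels)) df[[nm]] <- sprintf("%.6f", mesh$channels[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertex_channels
#' @export
read_vertex_channels <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
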