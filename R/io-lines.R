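# ASCII field-line file. The layout (this package's own; the producing
# stage only fixes "sequences of points in a text file") is:
#
#   # surfscape field lines
#   nlines <N>
#   min_potential <value>
#   line_density <value>
#   rng_seed <int>
#   line <npoints> <seed_ep> <termination>
#   <x> <y> <z>          (npoints rows, %.6f)
#   ...
#
# The header records the thresholds used, for reproducibility.

#' Write field lines to an ASCII file
#'
#' @param flf a [field_line_file()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_lines <- function(flf, path) {
  stopifnot(inherits(flf, "field_line_file"))
  h <- flf$header
  out <- c("# surfscape field lines",
           sprintf("nlines %d", length(flf$lines)),
           sprintf("min_potential %.6f", h$minimum_potential %||% 0),
           sprintf("line_density %.6f", h$line_density %||% 0),
           sprintf("rng_seed %d", as.integer(h$rng_seed %||% 0L)))
  for (ln in flf$lines) {
    out <- c(out,
             sprintf("line %d %.6f %s", nrow(ln$points), ln$seed_ep,
                     ln$termination),
             sprintf("%.6f %.6f %.6f",
                     ln$points[, 1], ln$points[, 2], ln$points[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read field lines from an ASCII file
#'
#' Round-trips [write_field_lines()] output to 1e-6 Angstrom. A truncated
#' or malformed block raises a parse error naming the block index.
#'
#' @param path file path.
#' @return a [field_line_file()].
#' @export
read_field_lines <- function(path) {
  if (!file.exists(path)) stopf("read_field_lines: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- function(key, idx = 1L) {
    hit <- grep(paste0("^", key, "\\b"), lines)
    if (!length(hit)) stopf("read_field_lines: %s: missing header field '%s'", path, key)
    strsplit(trimws(lines[hit[1]]), "[[:space:]]+")[[1]][-1]
  }
  nl <- as.integer(kv("nlines"))
  header <- list(minimum_potential = as.numeric(kv("min_potential")),
                 line_density = as.numeric(kv("line_density")),
                 rng_seed = as.integer(kv("rng_seed")),
                 seed_count = nl)
  pos <- grep("^line\\b", lines)
  if (length(pos) != nl)
    stopf("read_field_lines: %s: header declares %d lines but %d blocks found",
          path, nl, length(pos))
  out <- vector("list", nl)
  for (b in seq_len(nl)) {
    tok <- strsplit(trimws(lines[pos[b]]), "[[:space:]]+")[[1]]
    np <- suppressWarnings(as.integer(tok[2]))
    if (is.na(np) || np < 1L || length(tok) < 4L)
      stopf("read_field_lines: %s: malformed header of block %d", path, b)
    rows <- lines[(pos[b] + 1L):(pos[b] + np)]
    end_ok <- pos[b] + np <= length(lines) &&
      (b == nl || pos[b] + np < pos[b + 1L])
    vals <- suppressWarnings(
      as.numeric(unlist(strsplit(trimws(rows), "[[:space:]]+"), use.names = FALSE)))
    if (!end_ok || length(vals) != 3L * np || anyNA(vals))
      stopf("read_field_lines: %s: truncated or malformed block %d", path, b)
    out[[b]] <- structure(list(points = matrix(vals, ncol = 3L, byrow = TRUE),
                               seed_index = NA_integer_,
                               seed_ep = as.numeric(tok[3]),
                               termination = tok[4]),
                          class = "field_line")
  }
  field_line_file(out, header)
}
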