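# Per-frame orchestration for still and moving proteins. Moving proteins
# cannot reuse one mesh (topology changes between conformations), so every
# frame gets a fresh surface, MLP, EP, field lines and particle schedule;
# frames are processed independently and indexed outputs plus a manifest
# are written.

#' Pipeline configuration
#'
#' All stage parameters in one serializable object; every run writes its
#' resolved configuration (YAML) next to the outputs, and that file alone
#' reproduces the run.
#'
#' @param out_dir output directory.
#' @param formula MLP formula name (see [mlp_formula()]).
#' @param mlp_spacing,mlp_padding,mlp_cutoff MLP grid layout, Angstrom.
#' @param library_path fragment-library path (`NULL` = packaged table).
#' @param voxel,probe,smooth_iterations,drop_enclosed surface parameters,
#'   see [build_surface()].
#' @param ep an [ep_parameters()].
#' @param ep_dx path to an externally solved EP grid (`NULL` = built-in
#'   screened-Coulomb solver; requires PQR charges).
#' @param gray a [gray_map_params()].
#' @param seeds a [seed_controls()]; its `rng_seed` is re-derived per frame
#'   from `rng_seed + frame_index` so frames are independent yet
#'   reproducible.
#' @param step,low_field_threshold,max_points tracing parameters.
#' @param animation an [animation_params()].
#' @param rng_seed master seed.
#' @param fail_fast abort a sequence on the first failing frame.
#' @param verbose log one line per stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = ".", formula = "testa",
                            mlp_spacing = default_spacing(), mlp_padding = 5,
                            mlp_cutoff = 12, library_path = NULL,
                            voxel = 1.0, probe = 1.4, smooth_iterations = 2L,
                            drop_enclosed = FALSE,
                            ep = ep_parameters(), ep_dx = NULL,
                            gray = gray_map_params(),
                            seeds = seed_controls(),
                            step = NULL, low_field_threshold = 1e-4,
                            max_points = 2000L,
                            animation = animation_params(),
                            rng_seed = 1L, fail_fast = FALSE, verbose = TRUE) {
  structure(list(out_dir = out_dir, formula = formula,
                 mlp_spacing = mlp_spacing, mlp_padding = mlp_padding,
                 mlp_cutoff = mlp_cutoff, library_path = library_path,
                 voxel = voxel, probe = probe,
                 smooth_iterations = smooth_iterations,
                 drop_enclosed = drop_enclosed,
                 ep = ep, ep_dx = ep_dx, gray = gray, seeds = seeds,
                 step = step, low_field_threshold = low_field_threshold,
                 max_points = max_points, animation = animation,
                 rng_seed = as.integer(rng_seed), fail_fast = fail_fast,
                 verbose = verbose),
            class = "pipeline_config")
}

config_as_plain_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), config_as_plain_list) else x
}

#' Write the resolved configuration next to the outputs
#'
#' @param config a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(config, path) {
  yaml::write_yaml(config_as_plain_list(config), path)
  invisible(path)
}

#' Read a configuration file back into a pipeline_config
#'
#' @param path YAML path written by [write_resolved_config()].
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    out_dir = y$out_dir, formula = y$formula, mlp_spacing = y$mlp_spacing,
    mlp_padding = y$mlp_padding, mlp_cutoff = y$mlp_cutoff,
    library_path = y$library_path, voxel = y$voxel, probe = y$probe,
    smooth_iterations = y$smooth_iterations, drop_enclosed = y$drop_enclosed,
    ep = do.call(ep_parameters, y$ep), ep_dx = y$ep_dx,
    gray = do.call(gray_map_params,
                   y$gray[c("contrast", "brightness", "in_low", "in_mid", "in_high")]),
    seeds = do.call(seed_controls, y$seeds),
    step = y$step, low_field_threshold = y$low_field_threshold,
    max_points = y$max_points,
    animation = do.call(animation_params, y$animation),
    rng_seed = y$rng_seed, fail_fast = y$fail_fast, verbose = y$verbose)
}

pipe_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Run the full pipeline on one conformation
#'
#' Stages: surface mesh, MLP grid, MLP/gray/material channels, EP grid
#' (built-in screened Coulomb, or an imported .dx), field lines, particle
#' schedule. Writes five per-frame artifacts - `surface.obj` (MLP in
#' texture coordinates), `mlp.dx`, `ep.dx`, `lines.txt`, `schedule.tsv` -
#' plus a `channels.tsv` sidecar and the resolved config. Deterministic
#' given the config's `rng_seed`. A stage failure aborts the frame with a
#' stage-named message.
#'
#' @param structure a [structure3d()].
#' @param config a [pipeline_config()].
#' @param frame_index 0-based index used in file names and in the per-frame
#'   seed derivation.
#' @return invisibly, a list with the artifact `paths` and the in-memory
#'   `mesh`, `mlp_grid`, `ep_grid`, `lines`.
#' @export
run_frame <- function(structure, config = pipeline_config(),
                      frame_index = structure$frame_index) {
  stopifnot(inherits(structure, "structure3d"), inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stopf("[%s] %s", name, conditionMessage(e)))
    pipe_log(config, "frame %d | %-12s %.2fs", frame_index, name,
             proc.time()[["elapsed"]] - t0)
    r
  }
  pre <- function(name) file.path(config$out_dir,
                                  sprintf("frame_%03d_%s", frame_index, name))
  mesh <- stage("surface", build_surface(
    structure, voxel = config$voxel, probe = config$probe,
    smooth_iterations = config$smooth_iterations,
    drop_enclosed = config$drop_enclosed))
  lib <- if (is.null(structure$atoms$f))
    read_lipophilic_library(config$library_path) else NULL
  mlp_grid <- stage("mlp_grid", compute_mlp_grid(
    structure, library = lib, formula = mlp_formula(config$formula),
    spacing = config$mlp_spacing, padding = config$mlp_padding,
    cutoff = config$mlp_cutoff))
  mesh <- stage("mlp_map", {
    m <- sample_grid_at_vertices(mlp_grid, mesh, "mlp")
    add_material_channels(m, config$gray)
  })
  ep_grid <- stage("ep_grid", {
    if (!is.null(config$ep_dx)) load_ep_grid(config$ep_dx)
    else compute_ep_grid(structure, config$ep)
  })
  mesh <- stage("ep_map", sample_grid_at_vertices(ep_grid, mesh, "ep"))
  lines <- stage("field_lines", {
    ctl <- config$seeds
    ctl$rng_seed <- config$rng_seed + as.integer(frame_index)
    compute_field_lines(mesh, ep_grid, ctl, step = config$step,
                        low_field_threshold = config$low_field_threshold,
                        max_points = config$max_points,
                        temperature = config$ep$temperature)
  })
  paths <- list(obj = pre("surface.obj"), channels = pre("channels.tsv"),
                mlp_dx = pre("mlp.dx"), ep_dx = pre("ep.dx"),
                lines = pre("lines.txt"), schedule = pre("schedule.tsv"),
                config = file.path(config$out_dir, "config.yaml"))
  stage("write", {
    write_obj_with_mlp(mesh, paths$obj)
    write_vertex_channels(mesh, paths$channels)
    write_dx(mlp_grid, paths$mlp_dx)
    write_dx(ep_grid, paths$ep_dx)
    write_field_lines(lines, paths$lines)
    write_particle_schedule(lines, config$animation, paths$schedule)
    write_resolved_config(config, paths$config)
  })
  invisible(list(paths = paths, mesh = mesh, mlp_grid = mlp_grid,
                 ep_grid = ep_grid, lines = lines))
}

# natural sort: file10 after file2
natural_sort <- function(x) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", basename(x))))
  x[order(is.na(num), num, x)]
}

sequence_frames <- function(path) {
  if (dir.exists(path)) {
    files <- natural_sort(list.files(path, pattern = "\\.(pdb|pqr)$",
                                     full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stopf("run_sequence: no .pdb/.pqr files in %s", path)
    lapply(seq_along(files), function(k)
      function() {
        s <- read_structure(files[k], frame = 0L)
        s$frame_index <- k - 1L
        s
      })
  } else {
    nm <- count_models(path)
    lapply(seq_len(nm) - 1L, function(k) function() read_structure(path, frame = k))
  }
}

#' Run the pipeline over a frame sequence
#'
#' Accepts a multi-model PDB/PQR (one model per animation frame) or a
#' directory of numbered single-frame files (natural-sort order). Every
#' frame is processed independently with a fresh mesh, MLP, EP and lines;
#' a failing frame is recorded in the manifest and the remaining frames
#' continue (unless the config sets `fail_fast`).
#'
#' @param path multi-model structure file or frame directory.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with per-frame results, the `manifest`
#'   data.frame and its `manifest_path`.
#' @export
run_sequence <- function(path, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  loaders <- sequence_frames(path)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  results <- vector("list", length(loaders))
  manifest <- data.frame(frame = seq_along(loaders) - 1L,
                         status = NA_character_, message = "",
                         stringsAsFactors = FALSE)
  for (k in seq_along(loaders)) {
    frame_id <- k - 1L
    res <- tryCatch({
      s <- loaders[[k]]()
      out <- run_frame(s, config, frame_index = frame_id)
      manifest$status[k] <- "ok"
      out
    }, error = function(e) {
      if (isTRUE(config$fail_fast)) stop(e)
      manifest$status[k] <<- "failed"
      manifest$message[k] <<- conditionMessage(e)
      pipe_log(config, "frame %d | FAILED: %s", frame_id, conditionMessage(e))
      NULL
    })
    results[[k]] <- res
  }
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(frames = results, manifest = manifest,
                 manifest_path = manifest_path))
}
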