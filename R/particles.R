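# Particle animation schedule along field lines. Every line's most
# positive end is a particle emitter; particles travel toward the negative
# end at constant parametric speed. Frames are 0-based with the first
# emission at frame 0, which reconciles a 1-based "sixteenth frame" with
# 0-based frame 15 = 0.6 s at 25 fps.

#' Animation timing parameters
#'
#' Defaults encode the standard timing: 25 frames per second, a particle
#' emitted on every line every 5 frames (0.2 s) with a lifetime of 20
#' frames (0.8 s); in single-conformation loop mode lines emit for 250
#' frames.
#'
#' @param fps frames per second (positive integer).
#' @param emission_period frames between emissions (positive integer).
#' @param lifetime particle lifetime in frames (>= 1).
#' @param loop_emission_span last frame at which emission happens in loop
#'   mode.
#' @return an object of class `animation_params`.
#' @export
animation_params <- function(fps = 25L, emission_period = 5L, lifetime = 20L,
                             loop_emission_span = 250L) {
  v <- c(fps = fps, emission_period = emission_period, lifetime = lifetime,
         loop_emission_span = loop_emission_span)
  if (any(v != round(v)) || any(v <= 0))
    stopf("animation_params: all parameters must be positive integers")
  structure(lapply(as.list(v), as.integer), class = "animation_params")
}

#' Convert a frame count to seconds
#'
#' @param frames number of frames.
#' @param fps frames per second (> 0).
#' @return seconds (`frames / fps`).
#' @export
frames_to_seconds <- function(frames, fps = 25) {
  if (!is_number(fps) || fps <= 0) stopf("frames_to_seconds: fps must be > 0")
  frames / fps
}

n_lines_of <- function(lines) {
  if (inherits(lines, "field_line_file")) length(lines$lines)
  else if (is.numeric(lines) && length(lines) == 1L) as.integer(lines)
  else stopf("expected a field_line_file or a line count")
}

#' Live particles at a given frame
#'
#' Per line, particles are born at frames 0, p, 2p, ... (p the emission
#' period), up to `loop_emission_span`; a particle born at frame b is live
#' for frames [b, b + lifetime) and its curve parameter is
#' `t = age / lifetime` (t = 0 at the positive end, constant parametric
#' speed). Once reached, the steady-state live count per line is
#' `ceiling(lifetime / period)` at emission frames.
#'
#' @param lines a [field_line_file()] or an integer line count.
#' @param params an [animation_params()].
#' @param frame 0-based frame index (>= 0).
#' @return data.frame with columns `line_id`, `birth_frame`, `age`, `t`
#'   (one row per live particle).
#' @export
schedule <- function(lines, params = animation_params(), frame) {
  stopifnot(inherits(params, "animation_params"))
  if (frame < 0 || frame != round(frame)) stopf("schedule: frame must be an integer >= 0")
  n <- n_lines_of(lines)
  last <- min(frame, params$loop_emission_span)
  births <- seq(0L, last, by = params$emission_period)
  births <- births[births > frame - params$lifetime]
  if (!length(births) || n == 0L)
    return(data.frame(line_id = integer(0), birth_frame = integer(0),
                      age = integer(0), t = numeric(0)))
  g <- expand.grid(birth_frame = births, line_id = seq_len(n))
  age <- frame - g$birth_frame
  data.frame(line_id = g$line_id, birth_frame = g$birth_frame, age = age,
             t = age / params$lifetime)[order(g$line_id, g$birth_frame), ]
}

#' Time to particle-system steady state
#'
#' Brute-force simulates the per-line live-particle count frame by frame
#' and returns the elapsed time (seconds, 0-based frames) at which it first
#' reaches its long-run maximum `ceiling(lifetime / emission_period)`. With
#' the defaults (period 5, lifetime 20, 25 fps) this is frame 15 = 0.6 s.
#'
#' @param params an [animation_params()].
#' @return seconds.
#' @export
steady_state_time <- function(params = animation_params()) {
  stopifnot(inherits(params, "animation_params"))
  target <- ceiling(params$lifetime / params$emission_period)
  f <- 0L
  repeat {
    live <- nrow(schedule(1L, params, f))
    if (live >= target) return(frames_to_seconds(f, params$fps))
    f <- f + 1L
    if (f > params$lifetime + params$emission_period * (target + 1L))
      stopf("steady_state_time: steady state not reached (inconsistent parameters)")
  }
}

#' Write a particle schedule file
#'
#' Columnar text (frame, line_id, t, age), one row per live particle per
#' frame, covering frames `0 .. loop_emission_span + lifetime` by default
#' (after which loop-mode particles are all dead).
#'
#' @param lines a [field_line_file()] or integer line count.
#' @param params an [animation_params()].
#' @param path output path (TSV).
#' @param frames frame indices to include.
#' @return `path`, invisibly.
#' @export
write_particle_schedule <- function(lines, params = animation_params(), path,
                                    frames = NULL) {
  frames <- frames %||% seq(0L, params$loop_emission_span + params$lifetime)
  rows <- lapply(frames, function(f) {
    s <- schedule(lines, params, f)
    if (nrow(s)) cbind(frame = f, s[, c("line_id", "t", "age")]) else NULL
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(frame = integer(0), line_id = integer(0),
                                    t = numeric(0), age = integer(0))
  df$t <- sprintf("%.6f", df$t)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
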