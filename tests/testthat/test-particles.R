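test_that("frame timing converts as frames/fps", {
  expect_equal(frames_to_seconds(5, 25), 0.2)
  expect_equal(frames_to_seconds(20, 25), 0.8)
  expect_equal(frames_to_seconds(0, 25), 0)
  expect_error(frames_to_seconds(5, 0), "fps")
})

test_that("live particles enumerate births within the lifetime window", {
  p <- animation_params()
  s15 <- schedule(1L, p, frame = 15)
  expect_equal(nrow(s15), 4L)                   # births 0, 5, 10, 15
  expect_equal(sort(s15$birth_frame), c(0, 5, 10, 15))
  expect_equal(s15$t, s15$age / 20)
  s0 <- schedule(1L, p, frame = 0)
  expect_equal(nrow(s0), 1L)
  expect_equal(s0$t, 0)
  # expired singleton: lifetime 1, period 5, frame 3
  p2 <- animation_params(lifetime = 1, emission_period = 5)
  expect_equal(nrow(schedule(1L, p2, frame = 3)), 0L)
  expect_error(animation_params(lifetime = 0), "positive")
  # particles vanish exactly at age = lifetime (half-open interval)
  p3 <- animation_params(emission_period = 100, lifetime = 20)
  expect_equal(nrow(schedule(1L, p3, frame = 19)), 1L)
  expect_equal(nrow(schedule(1L, p3, frame = 20)), 0L)
})

test_that("steady state is reached at the brute-force simulated frame", {
  expect_equal(steady_state_time(animation_params()), 0.6)
  expect_equal(steady_state_time(animation_params(emission_period = 20,
                                                  lifetime = 20)), 0)
  expect_equal(steady_state_time(animation_params(fps = 10, emission_period = 2,
                                                  lifetime = 6)), 0.4)
})

test_that("live counts are periodic and bounded after steady state", {
  for (p in list(animation_params(),
                 animation_params(emission_period = 3, lifetime = 7),
                 animation_params(emission_period = 4, lifetime = 4))) {
    cmax <- ceiling(p$lifetime / p$emission_period)
    counts <- vapply(0:80, function(f) nrow(schedule(1L, p, f)), integer(1))
    expect_lte(max(counts), cmax)
    steady_from <- which(counts == cmax)[1]
    post <- counts[steady_from:81]
    lag <- p$emission_period
    expect_identical(post[seq_len(length(post) - lag)],
                     post[(lag + 1):length(post)])
  }
})

test_that("loop mode stops emitting after the span and drains", {
  p <- animation_params(loop_emission_span = 10)
  s12 <- schedule(1L, p, frame = 12)
  expect_true(all(s12$birth_frame <= 10))
  expect_equal(nrow(schedule(1L, p, frame = 10 + p$lifetime)), 0L)
  expect_gt(nrow(schedule(1L, p, frame = 10 + p$lifetime - 1)), 0L)
})

test_that("schedules scale with the line count and export as columns", {
  flf <- random_field_line_file(3, seed = 2)
  p <- animation_params()
  s <- schedule(flf, p, frame = 7)
  expect_equal(nrow(s), 3L * 2L)                # births 0 and 5 per line
  path <- withr::local_tempfile(fileext = ".tsv")
  write_particle_schedule(flf, p, path, frames = 0:20)
  df <- utils::read.table(path, header = TRUE)
  expect_identical(names(df), c("frame", "line_id", "t", "age"))
  expect_true(all(df$t >= 0 & df$t < 1))
  expect_equal(nrow(df[df$frame == 15, ]), 12L) # 4 live per line
})
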