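test_that("accel surrogate reproduces static tilt angles", {
  n <- 40
  t <- (seq_len(n) - 1) / 30
  flat <- synced_session(insole_stream(t, rep(0, n), rep(1, n), rep(1, n),
                                       rep(1, n), ax = rep(0, n),
                                       ay = rep(0, n), az = rep(1, n)))
  expect_lt(max(abs(pitch_trace(flat, "accel_surrogate")$pitch)), 1e-6)
  tilted <- synced_session(insole_stream(t, rep(0, n), rep(1, n), rep(1, n),
                                         rep(1, n), ax = rep(0, n),
                                         ay = rep(0.5, n),
                                         az = rep(sqrt(3) / 2, n)))
  expect_lt(max(abs(pitch_trace(tilted, "accel_surrogate")$pitch - 30)), 1e-6)
})

test_that("surrogate pitch plateau matches the programmed peak on noiseless data", {
  gs <- generate_session(noiseless_params())
  pt <- pitch_trace(gs$session, "accel_surrogate")
  tr <- gs$truth$events
  t <- pt$time
  hold <- t > tr$t_rise_end[2] + 0.3 & t < tr$t_drop_start[2] - 0.3
  expect_lt(max(abs(pt$pitch[hold] - 25)), 0.5)
})

test_that("pitch_trace respects the requested source", {
  gs <- generate_session(noiseless_params())
  expect_identical(attr(pitch_trace(gs$session), "source"), "orientation")
  bare <- synced_session(gs$session$insole)
  expect_identical(attr(pitch_trace(bare), "source"), "accel_surrogate")
  expect_error(pitch_trace(bare, "orientation"), class = "hr_config_error")
})

test_that("no events are detected in idle-only or too-short traces", {
  t <- (0:299) / 30
  zero <- structure(data.frame(time = t, pitch = rep(0, 300)),
                    class = c("pitch_trace", "data.frame"))
  expect_equal(nrow(detect_events(zero)), 0)
  # a 0.2 s supra-threshold blip fails the minimum-duration filter
  blip <- zero
  blip$pitch[100:106] <- 20
  expect_equal(nrow(detect_events(blip)), 0)
  short <- structure(data.frame(time = (0:9) / 30, pitch = rep(0, 10)),
                     class = c("pitch_trace", "data.frame"))
  expect_warning(out <- detect_events(short), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("noiseless default session yields exactly five events bracketing ground truth", {
  gs <- generate_session(noiseless_params())
  pt <- pitch_trace(gs$session)
  ev <- detect_events(pt)
  tr <- gs$truth$events
  expect_equal(nrow(ev), 5)
  # windows contain the true corners (inflated by at most taper + 1 sample)
  slack <- 0.2 / 2 + 1 / 30 + 1e-9
  expect_true(all(ev$t_start >= tr$t_start - slack &
                    ev$t_start <= tr$t_start + 1 / 30))
  expect_true(all(ev$t_end <= tr$t_end + slack &
                    ev$t_end >= tr$t_end - 1 / 30))
})

test_that("refined boundaries recover ground truth within one sample on noiseless data", {
  gs <- generate_session(noiseless_params())
  ev <- segment_session(gs$session)
  tr <- gs$truth$events
  for (col in c("t_start", "t_rise_end", "t_drop_start", "t_end")) {
    expect_lt(max(abs(ev[[col]] - tr[[col]])), 1 / 30)
  }
  expect_true(all(ev$valid))
})

test_that("default noisy session keeps mean boundary error within two samples", {
  gs <- generate_session(synthesis_params(seed = 21, muscles = NULL,
                                          include_gridcop = FALSE))
  ev <- segment_session(gs$session)
  tr <- gs$truth$events
  expect_equal(nrow(ev), 5)
  err <- abs(as.matrix(ev[, c("t_start", "t_rise_end", "t_drop_start", "t_end")]) -
               as.matrix(tr[, c("t_start", "t_rise_end", "t_drop_start", "t_end")]))
  expect_lt(mean(err), 2 / 30)
})

test_that("phase boundaries on linear trapezoids match the analytic corners", {
  tr <- linear_trapezoid_trace(3, rise = 1, hold = 3, drop = 1)
  ev <- detect_events(tr)
  ph <- detect_phases(tr, c(ev$t_start[1], ev$t_end[1]))
  corners <- attr(tr, "corners")
  got <- c(ph$t_start, ph$t_rise_end, ph$t_drop_start, ph$t_end)
  expect_lt(max(abs(got - corners)), 1 / 30)
  expect_equal(c(ph$rise_s, ph$hold_s, ph$drop_s), c(1, 3, 1),
               tolerance = 1 / 30)
})

test_that("corner recovery holds across a grid of phase durations", {
  for (rise in c(0.6, 1, 1.8)) {
    for (hold in c(0.8, 2, 3.5)) {
      for (drop in c(0.6, 1.2, 2)) {
        tr <- linear_trapezoid_trace(4, rise, hold, drop)
        ev <- detect_events(tr)
        expect_equal(nrow(ev), 1)
        ph <- detect_phases(tr, c(ev$t_start[1], ev$t_end[1]))
        got <- c(ph$t_start, ph$t_rise_end, ph$t_drop_start, ph$t_end)
        expect_lt(max(abs(got - attr(tr, "corners"))), 1 / 30)
      }
    }
  }
})

test_that("phases partition each event with no overlap", {
  gs <- generate_session(synthesis_params(seed = 3, muscles = NULL,
                                          include_gridcop = FALSE))
  ev <- segment_session(gs$session)
  expect_true(all(ev$t_start < ev$t_rise_end))
  expect_true(all(ev$t_rise_end <= ev$t_drop_start))
  expect_true(all(ev$t_drop_start < ev$t_end))
  expect_equal(ev$rise_s + ev$hold_s + ev$drop_s, ev$t_end - ev$t_start)
})

test_that("event counts are stable under moderate pitch noise", {
  # 100 seeded replicates, zero-mean noise SD 0.5 deg on the pitch
  counts <- vapply(1:100, function(seed) {
    gs <- generate_session(synthesis_params(
      seed = seed, muscles = NULL, include_gridcop = FALSE,
      noise_sd = list(pitch = 0.5, roll = 0.3, accel = 0.02, force = 1.5)))
    nrow(segment_session(gs$session))
  }, numeric(1))
  expect_true(all(counts == 5))
})

test_that("a triangle with no plateau yields a tiny but ordered hold", {
  tr <- linear_trapezoid_trace(3, rise = 1, hold = 1 / 60, drop = 1)
  ev <- detect_events(tr)
  ph <- detect_phases(tr, c(ev$t_start[1], ev$t_end[1]))
  expect_true(ph$valid)
  expect_gte(ph$hold_s, 0)
  expect_lt(ph$hold_s, 0.5)
})

test_that("a near-flat event is reported with invalid phases", {
  t <- (0:599) / 30
  # slow drift above threshold but with gradient below 3 deg/s
  p <- 8 * sin(pi * pmin(pmax((t - 4) / 12, 0), 1))
  tr <- structure(data.frame(time = t, pitch = p),
                  class = c("pitch_trace", "data.frame"))
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1)
  expect_warning(ph <- detect_phases(tr, c(ev$t_start[1], ev$t_end[1])),
                 "invalid")
  expect_false(ph$valid)
})

test_that("sessions without events segment to an empty table", {
  n <- 300
  t <- (seq_len(n) - 1) / 30
  idle <- synced_session(
    insole_stream(t, rep(1, n), rep(100, n), rep(100, n), rep(250, n),
                  ax = rep(0, n), ay = rep(0, n), az = rep(1, n)),
    orientation_stream(t, rep(0.5, n), rep(0, n)))
  expect_equal(nrow(segment_session(idle)), 0)
})
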