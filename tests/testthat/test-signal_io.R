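test_that("stream constructors validate their invariants", {
  expect_s3_class(
    insole_stream((0:2) / 30, c(1, 1, 1), c(30, 30, 30), c(10, 10, 10),
                  c(5, 5, 5), 0:2 * 0, 0:2 * 0, rep(1, 3)),
    "insole_stream")
  expect_error(
    insole_stream(c(0, 1 / 30, 1 / 30), rep(1, 3), rep(1, 3), rep(1, 3),
                  rep(1, 3), rep(0, 3), rep(0, 3), rep(1, 3)),
    class = "hr_data_error")
  expect_error(
    insole_stream((0:1) / 30, c(-1, 0), c(1, 1), c(1, 1), c(1, 1),
                  c(0, 0), c(0, 0), c(1, 1)),
    class = "hr_data_error")
  expect_error(orientation_stream(0:1, c(0, 95), c(0, 0)),
               class = "hr_data_error")
  expect_error(gridcop_stream(0:1, c(0, 120), width_mm = 100),
               class = "hr_data_error")
})

test_that("read_stream reports missing columns and non-monotone time", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,F1,F2", "0,1,2"), path)
  expect_error(read_stream(path, "insole"), "F3", class = "hr_format_error")
  writeLines(c("time,pitch,roll", "0,0,0", "0.033,1,0", "0.033,2,0"), path)
  expect_error(read_stream(path, "orientation"), "index 3",
               class = "hr_data_error")
})

test_that("a minimal well-formed insole file reads at the nominal rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,F1,F2,F3,F4,ax,ay,az",
               "0,1,30,10,200,0,0,1",
               sprintf("%.10f,1,31,10,199,0,0,1", 1 / 30),
               sprintf("%.10f,1,32,11,198,0,0,1", 2 / 30)), path)
  s <- read_stream(path, "insole")
  expect_equal(nrow(s), 3)
  expect_equal(stream_rate(s), 30)
  expect_equal(s$F2, c(30, 31, 32))
})

test_that("write/read round-trip is the identity for all four kinds", {
  withr::local_seed(11)
  dir <- withr::local_tempdir()
  streams <- list(
    insole = random_insole_stream(40),
    orientation = orientation_stream((0:39) / 30,
                                     pitch = runif(40, -20, 40),
                                     roll = runif(40, -15, 15)),
    emg = emg_stream((0:199) / 2000,
                     list(PL = rnorm(200), GM = rnorm(200)),
                     rate_hz = 2000),
    gridcop = gridcop_stream((0:39) / 50, runif(40, 0, 100),
                             width_mm = 100)
  )
  for (kind in names(streams)) {
    p <- file.path(dir, paste0(kind, ".csv"))
    write_stream(streams[[kind]], p)
    back <- read_stream(p, kind)
    for (ch in stream_channels(streams[[kind]])) {
      expect_equal(back[[ch]], streams[[kind]][[ch]], tolerance = 1e-9)
    }
    expect_equal(back$time, streams[[kind]]$time, tolerance = 1e-9)
    expect_equal(stream_rate(back), stream_rate(streams[[kind]]))
  }
})

test_that("written files contain the literal values and a header", {
  dir <- withr::local_tempdir()
  s <- insole_stream(0, F1 = 1, F2 = 30, F3 = 10, F4 = 5,
                     ax = 0, ay = 0, az = 1)
  p <- file.path(dir, "one.csv")
  write_stream(s, p)
  lines <- readLines(p)
  expect_true(any(grepl("^time,F1,F2,F3,F4,ax,ay,az$", lines)))
  expect_true(any(grepl("^0,1,30,10,5,0,0,1$", lines)))

  # empty stream -> header-only payload
  e <- emg_stream(numeric(0), data.frame(PL = numeric(0)))
  pe <- file.path(dir, "empty.csv")
  write_stream(e, pe)
  body <- grep("^#", readLines(pe), value = TRUE, invert = TRUE)
  expect_equal(body, "time,PL")
})

test_that("resample preserves constants and linear signals exactly", {
  t <- (0:29) / 30
  s <- orientation_stream(t, pitch = rep(7, 30), roll = t * 10)
  r <- resample(s, 60)
  expect_equal(stream_rate(r), 60)
  expect_true(all(abs(r$pitch - 7) < 1e-9))
  expect_true(all(abs(r$roll - r$time * 10) < 1e-9))
  expect_equal(r$time[1], t[1])
  expect_equal(r$time[nrow(r)], t[30])
})

test_that("resample at the original rate returns the original samples", {
  withr::local_seed(5)
  s <- random_insole_stream(50)
  r <- resample(s, 30)
  expect_equal(nrow(r), nrow(s))
  for (ch in c("time", stream_channels(s))) {
    expect_true(max(abs(r[[ch]] - s[[ch]])) < 1e-9)
  }
})

test_that("resampled sine tracks the analytic signal for f well below Nyquist", {
  t <- seq(0, 5, by = 1 / 30)
  f <- 2
  s <- orientation_stream(t, pitch = 10 * sin(2 * pi * f * t),
                          roll = rep(0, length(t)))
  r <- resample(s, 90)
  rms <- sqrt(mean((r$pitch - 10 * sin(2 * pi * f * r$time))^2))
  # linear interpolation error bound ~ A*(pi*f*dt)^2/2
  expect_lt(rms, 10 * (pi * f / 30)^2 / 2)
  expect_error(resample(orientation_stream(0, 0, 0), 60),
               class = "hr_data_error")
})

test_that("synchronize recovers a constructed lag via cross-correlation", {
  gs <- generate_session(synthesis_params(seed = 31, muscles = NULL,
                                          include_gridcop = FALSE))
  ins <- gs$session$insole
  ori <- gs$session$orientation
  shifted <- orientation_stream(ori$time + 0.5, ori$pitch, ori$roll)
  syn <- synchronize(ins, orientation = shifted, method = "cross-correlation")
  expect_lt(abs(syn$meta$applied_lag_s - 0.5), 1 / 30 + 1e-9)
  # aligned pitch should again match the insole-clock pitch
  err <- abs(syn$orientation$pitch - ori$pitch[seq_len(nrow(syn$orientation))])
  expect_lt(median(err), 0.5)
})

test_that("synchronize of already-aligned streams applies zero lag and is idempotent", {
  gs <- generate_session(synthesis_params(seed = 32, muscles = c("PL")))
  s <- gs$session
  syn1 <- synchronize(s$insole, s$orientation, s$emg, s$gridcop,
                      method = "cross-correlation")
  expect_equal(syn1$meta$applied_lag_s, 0)
  syn2 <- synchronize(syn1$insole, syn1$orientation, syn1$emg, syn1$gridcop,
                      method = "shared-clock")
  expect_equal(syn2$insole$time, syn1$insole$time)
  expect_equal(syn2$orientation$pitch, syn1$orientation$pitch)
  expect_equal(nrow(syn2$emg), nrow(syn1$emg))
})

test_that("disjoint time ranges raise an alignment error; flat signals fall back", {
  a <- random_insole_stream(60)
  b <- orientation_stream(10 + (0:59) / 30, rnorm(60), rnorm(60))
  expect_error(synchronize(a, b), class = "hr_alignment_error")
  flat <- orientation_stream((0:59) / 30, rep(0, 60), rep(0, 60))
  expect_warning(syn <- synchronize(a, flat, method = "cross-correlation"),
                 "flat")
  expect_equal(syn$meta$applied_lag_s, 0)
})
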