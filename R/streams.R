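# signal_io: sensor stream containers, delimited-text I/O, resampling and
# synchronisation onto a common master clock.

STREAM_KINDS <- c("insole", "orientation", "emg", "gridcop")

stream_required_cols <- function(kind) {
  switch(kind,
    insole      = c("time", "F1", "F2", "F3", "F4", "ax", "ay", "az"),
    orientation = c("time", "pitch", "roll"),
    emg         = "time",
    gridcop     = c("time", "cop_x"),
    hr_error("hr_parameter_error", "unknown stream kind '%s'", kind)
  )
}

new_stream <- function(df, kind, rate_hz, extra = list()) {
  structure(df,
            class = c(paste0(kind, "_stream"), "sensor_stream", "data.frame"),
            kind = kind, rate_hz = rate_hz, meta = extra)
}

#' Sensor stream constructors
#'
#' Build validated sensor streams, the time-series containers used across
#' the package. All streams share a `time` column in seconds (strictly
#' increasing); remaining columns depend on the kind:
#'
#' * **insole** — `F1,F2,F3,F4`: force per FSR channel in device units
#'   (F1 = toe, F2 = under the 1st metatarsal head, i.e. medial forefoot,
#'   F3 = under the 4th metatarsal head, i.e. lateral forefoot, F4 = heel)
#'   and `ax,ay,az`: acceleration in g (x medio-lateral, y along-foot,
#'   z vertical). Nominal rate 30 Hz.
#' * **orientation** — `pitch`, `roll` in degrees. Pitch 0 = flat foot,
#'   positive = heel up; roll positive = eversion, negative = inversion.
#' * **emg** — one or more named raw EMG channels in mV at their own
#'   (typically much higher) sampling rate.
#' * **gridcop** — `cop_x`: medial-axis centre-of-pressure coordinate in mm
#'   within an insole of width `width_mm` (from a grid-pressure insole).
#'
#' @param time numeric vector of sample times, seconds, strictly increasing.
#' @param F1,F2,F3,F4 FSR force channels, device units, non-negative.
#' @param ax,ay,az accelerometer channels, g.
#' @param pitch,roll orientation angles, degrees, within +/-90.
#' @param channels named list or data.frame of raw EMG channels, mV.
#' @param cop_x medial COP coordinate, mm, within `[0, width_mm]`.
#' @param width_mm insole width, mm.
#' @param rate_hz nominal sampling rate in Hz.
#' @return A data frame of class `<kind>_stream`/`sensor_stream` with
#'   attributes `kind`, `rate_hz` and `meta`.
#' @examples
#' s <- insole_stream(time = (0:2) / 30,
#'                    F1 = c(5, 5, 5), F2 = c(30, 31, 32),
#'                    F3 = c(10, 10, 11), F4 = c(200, 198, 197),
#'                    ax = c(0, 0, 0), ay = c(0, 0, 0), az = c(1, 1, 1))
#' stream_kind(s)
#' @export
insole_stream <- function(time, F1, F2, F3, F4, ax, ay, az, rate_hz = 30) {
  df <- data.frame(time = as.numeric(time), F1 = F1, F2 = F2, F3 = F3,
                   F4 = F4, ax = ax, ay = ay, az = az)
  validate_stream(new_stream(df, "insole", rate_hz))
}

#' @rdname insole_stream
#' @export
orientation_stream <- function(time, pitch, roll, rate_hz = 30) {
  df <- data.frame(time = as.numeric(time), pitch = pitch, roll = roll)
  validate_stream(new_stream(df, "orientation", rate_hz))
}

#' @rdname insole_stream
#' @export
emg_stream <- function(time, channels, rate_hz = 2000) {
  channels <- as.data.frame(channels)
  hr_assert(ncol(channels) >= 1 && !is.null(names(channels)),
            "hr_parameter_error", "emg_stream() needs >= 1 named channel")
  df <- cbind(data.frame(time = as.numeric(time)), channels)
  validate_stream(new_stream(df, "emg", rate_hz))
}

#' @rdname insole_stream
#' @export
gridcop_stream <- function(time, cop_x, width_mm, rate_hz = 50) {
  df <- data.frame(time = as.numeric(time), cop_x = as.numeric(cop_x))
  validate_stream(new_stream(df, "gridcop", rate_hz,
                             extra = list(width_mm = as.numeric(width_mm))))
}

#' @rdname insole_stream
#' @param stream a sensor stream.
#' @export
stream_kind <- function(stream) attr(stream, "kind")

#' @rdname insole_stream
#' @export
stream_rate <- function(stream) attr(stream, "rate_hz")

#' @rdname insole_stream
#' @export
stream_channels <- function(stream) setdiff(names(stream), "time")

validate_stream <- function(stream) {
  kind <- stream_kind(stream)
  t <- stream$time
  hr_assert(length(t) == 0 || all(is.finite(t)), "hr_data_error",
            "%s stream: non-finite time values", kind)
  if (length(t) > 1 && !is_strictly_increasing(t)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    hr_error("hr_data_error",
             "%s stream: time not strictly increasing at index %d", kind, bad)
  }
  nc <- vapply(stream, length, integer(1))
  hr_assert(length(unique(nc)) <= 1, "hr_data_error",
            "%s stream: channels of unequal length", kind)
  if (kind == "insole") {
    for (f in c("F1", "F2", "F3", "F4")) {
      hr_assert(all(stream[[f]] >= 0, na.rm = TRUE), "hr_data_error",
                "insole stream: negative force in %s", f)
    }
    if (length(t) > 2) {
      md <- median(diff(t))
      if (abs(md - 1 / stream_rate(stream)) > 0.1 / stream_rate(stream)) {
        warning(sprintf(
          "insole stream: median sampling interval %.4fs deviates >10%% from nominal 1/%g s",
          md, stream_rate(stream)))
      }
    }
  } else if (kind == "orientation") {
    hr_assert(all(abs(stream$pitch) <= 90, na.rm = TRUE), "hr_data_error",
              "orientation stream: |pitch| > 90 deg")
    hr_assert(all(abs(stream$roll) <= 90, na.rm = TRUE), "hr_data_error",
              "orientation stream: |roll| > 90 deg")
  } else if (kind == "gridcop") {
    w <- attr(stream, "meta")$width_mm
    hr_assert(is.numeric(w) && length(w) == 1 && w > 0, "hr_parameter_error",
              "gridcop stream: width_mm must be a positive scalar")
    hr_assert(all(stream$cop_x >= 0 & stream$cop_x <= w, na.rm = TRUE),
              "hr_data_error", "gridcop stream: cop_x outside [0, width_mm]")
  }
  stream
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<%s stream> %d samples @ %g Hz, channels: %s\n",
              stream_kind(x), nrow(x), stream_rate(x),
              paste(stream_channels(x), collapse = ", ")))
  if (nrow(x) > 0) {
    cat(sprintf("  time range: [%.3f, %.3f] s\n", x$time[1], x$time[nrow(x)]))
  }
  invisible(x)
}

#' Read and write sensor streams as delimited text
#'
#' Streams are stored as comma-separated text with one header row.
#' Metadata (sampling rate, insole width for grid-COP streams) is carried
#' in leading comment lines of the form `# key=value`. `read_stream()`
#' validates the result: a missing required column is a format error,
#' non-monotone time is a data error naming the first offending row, and
#' rows violating range invariants (negative forces, angles beyond +/-90,
#' COP outside the insole) are dropped with a message reporting the count.
#'
#' `write_stream()` writes numerics with enough digits that
#' `read_stream(write_stream(s))` reproduces `s` to better than 1e-9
#' relative.
#'
#' @param path file path.
#' @param kind one of `"insole"`, `"orientation"`, `"emg"`, `"gridcop"`.
#' @param stream a sensor stream (see [insole_stream()]).
#' @return `read_stream()`: a validated stream; `write_stream()`: `path`,
#'   invisibly.
#' @export
read_stream <- function(path, kind = c("insole", "orientation", "emg", "gridcop")) {
  kind <- match.arg(kind)
  hr_assert(file.exists(path), "hr_io_error", "file not found: %s", path)
  lines <- readLines(path, n = 50L)
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      meta[[key]] <- val
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  req <- stream_required_cols(kind)
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    hr_error("hr_format_error", "%s file %s: missing column(s) %s",
             kind, path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) > 1 && !is_strictly_increasing(df$time)) {
    bad <- which(diff(df$time) <= 0)[1] + 1L
    hr_error("hr_data_error",
             "%s file %s: time not strictly increasing at index %d",
             kind, path, bad)
  }
  rate <- as.numeric(meta$rate_hz %||%
                       switch(kind, insole = 30, orientation = 30,
                              emg = 2000, gridcop = 50))
  keep <- rep(TRUE, nrow(df))
  if (kind == "insole") {
    keep <- keep & rowSums(df[, c("F1", "F2", "F3", "F4"), drop = FALSE] < 0) == 0
  } else if (kind == "orientation") {
    keep <- keep & abs(df$pitch) <= 90 & abs(df$roll) <= 90
  } else if (kind == "gridcop") {
    w <- as.numeric(meta$width_mm %||% NA_real_)
    hr_assert(is.finite(w), "hr_format_error",
              "gridcop file %s: missing '# width_mm=' metadata line", path)
    keep <- keep & df$cop_x >= 0 & df$cop_x <= w
  }
  if (any(!keep)) {
    message(sprintf("read_stream: dropped %d out-of-range row(s) from %s",
                    sum(!keep), path))
    df <- df[keep, , drop = FALSE]
  }
  switch(kind,
    insole = insole_stream(df$time, df$F1, df$F2, df$F3, df$F4,
                           df$ax, df$ay, df$az, rate_hz = rate),
    orientation = orientation_stream(df$time, df$pitch, df$roll,
                                     rate_hz = rate),
    emg = emg_stream(df$time, df[, setdiff(names(df), "time"), drop = FALSE],
                     rate_hz = rate),
    gridcop = gridcop_stream(df$time, df$cop_x,
                             width_mm = as.numeric(meta$width_mm),
                             rate_hz = rate)
  )
}

#' @rdname read_stream
#' @export
write_stream <- function(stream, path) {
  hr_assert(inherits(stream, "sensor_stream"), "hr_parameter_error",
            "write_stream() expects a sensor stream")
  con <- tryCatch(file(path, "w"), error = function(e)
    hr_error("hr_io_error", "cannot open %s for writing: %s",
             path, conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# kind=%s", stream_kind(stream)), con)
  writeLines(sprintf("# rate_hz=%.10g", stream_rate(stream)), con)
  w <- attr(stream, "meta")$width_mm
  if (!is.null(w)) writeLines(sprintf("# width_mm=%.10g", w), con)
  df <- as.data.frame(stream)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.12g", col))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0) {
    writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  }
  invisible(path)
}

#' Resample a stream onto a uniform grid
#'
#' Linear interpolation of every channel onto a uniform grid spanning the
#' original time range (both endpoints preserved). Resampling a uniformly
#' sampled stream at its own rate reproduces it exactly.
#'
#' @param stream a sensor stream of length >= 2.
#' @param target_rate_hz new sampling rate, Hz, > 0.
#' @return A stream of the same kind at `target_rate_hz`.
#' @export
resample <- function(stream, target_rate_hz) {
  hr_assert(inherits(stream, "sensor_stream"), "hr_parameter_error",
            "resample() expects a sensor stream")
  hr_assert(is.numeric(target_rate_hz) && target_rate_hz > 0,
            "hr_parameter_error", "target_rate_hz must be > 0")
  n <- nrow(stream)
  if (n < 2) hr_error("hr_data_error", "resample(): stream length < 2")
  t0 <- stream$time[1]
  t1 <- stream$time[n]
  m <- max(2L, round((t1 - t0) * target_rate_hz) + 1L)
  grid <- seq(t0, t1, length.out = m)
  out <- data.frame(time = grid)
  for (ch in stream_channels(stream)) {
    out[[ch]] <- stats::approx(stream$time, stream[[ch]], xout = grid,
                               rule = 2)$y
  }
  kind <- stream_kind(stream)
  switch(kind,
    insole = insole_stream(out$time, out$F1, out$F2, out$F3, out$F4,
                           out$ax, out$ay, out$az, rate_hz = target_rate_hz),
    orientation = orientation_stream(out$time, out$pitch, out$roll,
                                     rate_hz = target_rate_hz),
    emg = emg_stream(out$time, out[, setdiff(names(out), "time"), drop = FALSE],
                     rate_hz = target_rate_hz),
    gridcop = gridcop_stream(out$time, out$cop_x,
                             width_mm = attr(stream, "meta")$width_mm,
                             rate_hz = target_rate_hz)
  )
}

# Lag (seconds) such that y(t) ~ x(t - lag); positive lag means y trails x.
cross_correlation_lag <- function(t_x, x, t_y, y, dt, max_lag_s = 5) {
  lo <- min(t_x[1], t_y[1])
  hi <- max(t_x[length(t_x)], t_y[length(t_y)])
  grid <- seq(lo, hi, by = dt)
  xi <- stats::approx(t_x, x, xout = grid, rule = 2)$y
  yi <- stats::approx(t_y, y, xout = grid, rule = 2)$y
  if (stats::sd(xi) == 0 || stats::sd(yi) == 0) return(NULL)
  xi <- (xi - mean(xi)) / stats::sd(xi)
  yi <- (yi - mean(yi)) / stats::sd(yi)
  K <- min(length(grid) - 2L, round(max_lag_s / dt))
  lags <- -K:K
  score <- vapply(lags, function(k) {
    if (k >= 0) sum(xi[1:(length(xi) - k)] * yi[(1 + k):length(yi)])
    else        sum(xi[(1 - k):length(xi)] * yi[1:(length(yi) + k)])
  }, numeric(1))
  lags[which.max(score)] * dt
}

#' Synchronize sensor streams into a session
#'
#' Places all streams on the insole's 30 Hz master clock. With
#' `method = "shared-clock"` the streams are assumed to share a time base
#' and are trimmed to their common interval. With
#' `method = "cross-correlation"` the lag maximising the normalized
#' cross-correlation between the insole's pitch surrogate (the along-foot
#' acceleration `ay`) and the orientation stream's pitch is removed from
#' the orientation (and grid-COP) clock before trimming; the applied lag is
#' recorded in the session metadata. Orientation and grid-COP streams are
#' interpolated onto the master grid; EMG keeps its native rate and is
#' trimmed to the master interval (boundaries are mapped across clocks by
#' nearest sample downstream).
#'
#' @param insole an insole stream (the master clock).
#' @param orientation,emg,gridcop optional companion streams.
#' @param method alignment method.
#' @param meta optional named list of session metadata (subject, variant...).
#' @return A `synced_session`: list with elements `insole`, `orientation`,
#'   `emg`, `gridcop` (possibly `NULL`) and `meta` (includes
#'   `applied_lag_s`).
#' @export
synchronize <- function(insole, orientation = NULL, emg = NULL,
                        gridcop = NULL,
                        method = c("shared-clock", "cross-correlation"),
                        meta = list()) {
  method <- match.arg(method)
  hr_assert(stream_kind(insole) == "insole", "hr_parameter_error",
            "synchronize(): first argument must be an insole stream")
  dt <- 1 / stream_rate(insole)
  lag <- 0
  if (method == "cross-correlation") {
    if (is.null(orientation)) {
      warning("cross-correlation synchronization needs an orientation stream; falling back to shared-clock")
    } else {
      lag_est <- cross_correlation_lag(insole$time, insole$ay,
                                       orientation$time, orientation$pitch, dt)
      if (is.null(lag_est)) {
        warning("flat signal under cross-correlation; falling back to shared-clock")
      } else {
        lag <- lag_est
      }
    }
  }
  shift <- function(s) {
    if (is.null(s) || lag == 0) return(s)
    s$time <- s$time - lag
    s
  }
  orientation <- shift(orientation)
  gridcop <- shift(gridcop)
  others <- Filter(Negate(is.null), list(orientation, emg, gridcop))
  t0 <- insole$time[1]
  t1 <- insole$time[nrow(insole)]
  for (s in others) {
    t0 <- max(t0, s$time[1])
    t1 <- min(t1, s$time[nrow(s)])
  }
  if (t1 - t0 < 1) {
    hr_error("hr_alignment_error",
             "streams overlap by %.3f s (< 1 s required)", max(0, t1 - t0))
  }
  keep <- insole$time >= t0 - dt / 2 & insole$time <= t1 + dt / 2
  master <- insole[keep, , drop = FALSE]
  master <- insole_stream(master$time, master$F1, master$F2, master$F3,
                          master$F4, master$ax, master$ay, master$az,
                          rate_hz = stream_rate(insole))
  on_master <- function(s) {
    if (is.null(s)) return(NULL)
    out <- data.frame(time = master$time)
    for (ch in stream_channels(s)) {
      out[[ch]] <- stats::approx(s$time, s[[ch]], xout = master$time,
                                 rule = 2)$y
    }
    if (stream_kind(s) == "orientation") {
      orientation_stream(out$time, out$pitch, out$roll,
                         rate_hz = stream_rate(insole))
    } else {
      gridcop_stream(out$time, out$cop_x,
                     width_mm = attr(s, "meta")$width_mm,
                     rate_hz = stream_rate(insole))
    }
  }
  if (!is.null(emg)) {
    ke <- emg$time >= t0 - dt / 2 & emg$time <= t1 + dt / 2
    emg <- emg_stream(emg$time[ke],
                      as.data.frame(emg)[ke, stream_channels(emg), drop = FALSE],
                      rate_hz = stream_rate(emg))
  }
  meta$applied_lag_s <- lag
  meta$sync_method <- method
  synced_session(master, on_master(orientation), emg, on_master(gridcop),
                 meta = meta)
}

#' Assemble a synchronized session
#'
#' Container for streams already on a shared master clock (as produced by
#' [synchronize()] or [generate_session()]).
#'
#' @param insole insole stream on the master clock.
#' @param orientation,emg,gridcop optional member streams.
#' @param meta named list of metadata.
#' @return An object of class `synced_session`.
#' @export
synced_session <- function(insole, orientation = NULL, emg = NULL,
                           gridcop = NULL, meta = list()) {
  hr_assert(stream_kind(insole) == "insole", "hr_parameter_error",
            "synced_session(): insole stream required")
  dt <- 1 / stream_rate(insole)
  t0 <- insole$time[1]
  t1 <- insole$time[nrow(insole)]
  for (s in Filter(Negate(is.null), list(orientation, emg, gridcop))) {
    hr_assert(abs(s$time[1] - t0) <= dt + 1e-9 &&
                abs(s$time[nrow(s)] - t1) <= dt + 1e-9,
              "hr_alignment_error",
              "member stream does not cover the master interval within one sample")
  }
  structure(list(insole = insole, orientation = orientation, emg = emg,
                 gridcop = gridcop, meta = meta),
            class = "synced_session")
}

#' @export
print.synced_session <- function(x, ...) {
  present <- names(Filter(Negate(is.null),
                          x[c("insole", "orientation", "emg", "gridcop")]))
  cat(sprintf("<synced_session> streams: %s\n", paste(present, collapse = ", ")))
  cat(sprintf("  master: %d samples @ %g Hz over [%.2f, %.2f] s\n",
              nrow(x$insole), stream_rate(x$insole),
              x$insole$time[1], x$insole$time[nrow(x$insole)]))
  if (!is.null(x$meta$variant)) cat(sprintf("  variant: %s\n", x$meta$variant))
  invisible(x)
}
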