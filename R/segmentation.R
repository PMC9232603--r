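# segmentation: heel-raise event detection by pitch thresholding and
# rise/hold/drop phase splitting from the pitch gradient.

#' Segmentation configuration
#'
#' Tunable parameters of the event/phase detector. The pitch threshold
#' only needs to sit well below the heel-raise excursion (~25 deg) and well
#' above idle noise; hysteresis suppresses chatter on noisy crossings. The
#' gradient threshold gates whether a candidate event contains a genuine
#' rise and drop; the phase boundaries themselves are refined to the
#' half-of-peak-gradient crossings (see [detect_phases()]).
#'
#' @param pitch_threshold_deg event opens when pitch exceeds this, degrees.
#' @param hysteresis_deg event closes when pitch falls below
#'   `pitch_threshold_deg - hysteresis_deg`.
#' @param min_event_s events shorter than this are discarded, seconds.
#' @param min_gap_s events separated by less than this are merged, seconds.
#' @param gradient_smooth_window_s moving-average window applied to the
#'   pitch before differentiation, seconds (zero-phase, so boundaries are
#'   not biased in time).
#' @param gradient_threshold_deg_per_s minimum peak |gradient| for a valid
#'   rise/drop, deg/s.
#' @param pitch_source where the pitch comes from: the orientation stream,
#'   the accelerometer surrogate, or `"auto"` (orientation when present).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(pitch_threshold_deg = 5,
                                hysteresis_deg = 2,
                                min_event_s = 1.0,
                                min_gap_s = 1.0,
                                gradient_smooth_window_s = 0.3,
                                gradient_threshold_deg_per_s = 3,
                                pitch_source = c("auto", "orientation",
                                                 "accel_surrogate")) {
  pitch_source <- match.arg(pitch_source)
  hr_assert(pitch_threshold_deg > hysteresis_deg && hysteresis_deg >= 0,
            "hr_parameter_error",
            "need pitch_threshold_deg > hysteresis_deg >= 0")
  hr_assert(gradient_smooth_window_s > 0 && min_event_s > 0 && min_gap_s > 0,
            "hr_parameter_error", "windows and durations must be > 0")
  structure(list(pitch_threshold_deg = pitch_threshold_deg,
                 hysteresis_deg = hysteresis_deg,
                 min_event_s = min_event_s,
                 min_gap_s = min_gap_s,
                 gradient_smooth_window_s = gradient_smooth_window_s,
                 gradient_threshold_deg_per_s = gradient_threshold_deg_per_s,
                 pitch_source = pitch_source),
            class = "segmentation_config")
}

#' Foot pitch trace of a session
#'
#' Returns the foot pitch on the master clock, either passed through from
#' the orientation stream or estimated from the insole accelerometer as
#' `asin(clamp(ay / |a|, -1, 1))` in degrees, low-pass filtered (2nd-order
#' Butterworth, 3 Hz cutoff, zero-phase). The surrogate is valid because
#' during a heel raise the along-foot gravity projection and the pitch
#' reach their extrema together; it is the default when no orientation
#' stream was recorded.
#'
#' @param session a [synced_session()].
#' @param source `"orientation"`, `"accel_surrogate"` or `"auto"`.
#' @return data.frame of class `pitch_trace` with columns `time`, `pitch`
#'   (degrees) and attribute `source`.
#' @export
pitch_trace <- function(session, source = c("auto", "orientation",
                                            "accel_surrogate")) {
  source <- match.arg(source)
  if (source == "auto") {
    source <- if (!is.null(session$orientation)) "orientation"
              else "accel_surrogate"
  }
  if (source == "orientation") {
    if (is.null(session$orientation)) {
      hr_error("hr_config_error",
               "pitch_source = 'orientation' but session has no orientation stream")
    }
    out <- data.frame(time = session$orientation$time,
                      pitch = session$orientation$pitch)
  } else {
    ins <- session$insole
    norm <- sqrt(ins$ax^2 + ins$ay^2 + ins$az^2)
    norm[norm == 0] <- 1
    p <- asin(clamp(ins$ay / norm, -1, 1)) * 180 / pi
    fs <- stream_rate(ins)
    n <- length(p)
    if (n > 12 && fs > 6) {
      bf <- signal::butter(2, 3 / (fs / 2), type = "low")
      # odd-reflection padding to suppress filtfilt edge transients
      npad <- min(n - 1L, as.integer(3 * fs))
      xp <- c(2 * p[1] - p[(npad + 1L):2L], p,
              2 * p[n] - p[(n - 1L):(n - npad)])
      yp <- as.numeric(signal::filtfilt(bf, xp))
      p <- yp[(npad + 1L):(npad + n)]
    }
    out <- data.frame(time = ins$time, pitch = p)
  }
  structure(out, class = c("pitch_trace", "data.frame"), source = source)
}

# State machine over threshold/hysteresis crossings; returns index pairs.
threshold_events <- function(p, thr, thr_close) {
  open <- FALSE
  start <- integer(0); stop_ <- integer(0)
  s <- NA_integer_
  for (i in seq_along(p)) {
    if (!open && p[i] > thr) {
      open <- TRUE; s <- i
    } else if (open && p[i] < thr_close) {
      open <- FALSE
      start <- c(start, s); stop_ <- c(stop_, i)
    }
  }
  if (open) { start <- c(start, s); stop_ <- c(stop_, length(p)) }
  cbind(start = start, stop = stop_)
}

#' Detect heel-raise events from the pitch trace
#'
#' An event opens when the pitch rises above the threshold and closes when
#' it falls below threshold minus hysteresis. Events shorter than
#' `min_event_s` are discarded, events separated by less than `min_gap_s`
#' are merged, and the remaining windows are extended outward to the
#' nearest local pitch minimum so that the rise onset and the drop
#' completion are contained in the window.
#'
#' @param pitch a [pitch_trace()] (or data.frame with `time`, `pitch`).
#' @param cfg a [segmentation_config()].
#' @return data.frame with columns `t_start`, `t_end` (seconds), one row
#'   per event.
#' @export
detect_events <- function(pitch, cfg = segmentation_config()) {
  t <- pitch$time; p <- pitch$pitch
  n <- length(t)
  if (n < 2) return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  dt <- median(diff(t))
  if ((t[n] - t[1]) < cfg$min_event_s) {
    warning("pitch trace shorter than min_event_s; no events")
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  }
  ev <- threshold_events(p, cfg$pitch_threshold_deg,
                         cfg$pitch_threshold_deg - cfg$hysteresis_deg)
  if (nrow(ev) == 0) return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  # merge events separated by less than min_gap_s
  merged <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      gap <- t[ev[i, "start"]] - t[merged[nrow(merged), "stop"]]
      if (gap < cfg$min_gap_s) {
        merged[nrow(merged), "stop"] <- ev[i, "stop"]
      } else {
        merged <- rbind(merged, ev[i, , drop = FALSE])
      }
    }
  }
  dur <- t[merged[, "stop"]] - t[merged[, "start"]]
  merged <- merged[dur >= cfg$min_event_s, , drop = FALSE]
  if (nrow(merged) == 0) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  }
  # extend outward to the nearest local pitch minimum
  for (i in seq_len(nrow(merged))) {
    a <- merged[i, "start"]
    while (a > 1 && p[a - 1] < p[a]) a <- a - 1L
    b <- merged[i, "stop"]
    while (b < n && p[b + 1] < p[b]) b <- b + 1L
    merged[i, "start"] <- a; merged[i, "stop"] <- b
  }
  data.frame(t_start = t[merged[, "start"]], t_end = t[merged[, "stop"]])
}

# First crossing of g below `level`, walking away from peak index ipk in
# direction dir (-1 left, +1 right); linear interpolation between samples.
half_crossing <- function(g, t, ipk, level, dir, bound) {
  i <- ipk
  while (i != bound && g[i + dir] > level) i <- i + dir
  if (i == bound) return(t[bound])
  j <- i + dir
  # interpolate between samples i (above) and j (at/below)
  if (g[i] == g[j]) return(t[j])
  frac <- (g[i] - level) / (g[i] - g[j])
  t[i] + frac * (t[j] - t[i])
}

#' Split a heel-raise event into rise, hold and drop
#'
#' Works on the gradient of the smoothed pitch (moving average of width
#' `gradient_smooth_window_s`, central differences). The rise is located
#' at the largest positive gradient peak, the drop at the largest negative
#' peak after it; each of the four boundaries (rise onset, hold start,
#' drop start, drop end) is then refined to the time where the gradient
#' crosses half of the respective peak value. For any pitch profile whose
#' slope transitions are symmetric about the underlying trapezoid corner —
#' including ideal piecewise-linear trapezoids — the half-peak crossing
#' recovers the corner time exactly, independent of the smoothing width.
#' An event whose peak |gradient| stays below
#' `gradient_threshold_deg_per_s` is reported with `valid = FALSE`.
#'
#' @param pitch a [pitch_trace()].
#' @param event numeric `c(t_start, t_end)` window (from
#'   [detect_events()]).
#' @param cfg a [segmentation_config()].
#' @param event_index ordinal attached to the output row.
#' @return One-row data.frame with `event_index`, `t_start`, `t_rise_end`,
#'   `t_drop_start`, `t_end`, `rise_s`, `hold_s`, `drop_s`, `valid`.
#' @export
detect_phases <- function(pitch, event, cfg = segmentation_config(),
                          event_index = 1L) {
  t <- pitch$time; p <- pitch$pitch
  dt <- median(diff(t))
  win <- max(3L, round(cfg$gradient_smooth_window_s / dt))
  g <- central_gradient(moving_average(p, win), dt)
  pad <- cfg$gradient_smooth_window_s
  i0 <- max(1L, which(t >= event[1] - pad)[1])
  i1 <- min(length(t), tail(which(t <= event[2] + pad), 1))
  idx <- i0:i1
  gi <- g[idx]; ti <- t[idx]
  invalid <- function() {
    warning(sprintf("event %d: no supra-threshold pitch gradient; phases marked invalid",
                    event_index))
    data.frame(event_index = event_index, t_start = event[1],
               t_rise_end = NA_real_, t_drop_start = NA_real_,
               t_end = event[2], rise_s = NA_real_, hold_s = NA_real_,
               drop_s = NA_real_, valid = FALSE)
  }
  ipk_r <- which.max(gi)
  if (!is.finite(gi[ipk_r]) || gi[ipk_r] <= cfg$gradient_threshold_deg_per_s) {
    return(invalid())
  }
  half_r <- gi[ipk_r] / 2
  t_start <- half_crossing(gi, ti, ipk_r, half_r, -1L, 1L)
  t_rise_end <- half_crossing(gi, ti, ipk_r, half_r, +1L, length(gi))
  rest <- ipk_r:length(gi)
  ipk_d <- rest[which.min(gi[rest])]
  if (gi[ipk_d] >= -cfg$gradient_threshold_deg_per_s) {
    # rise with no completed drop (e.g. trace truncated): degenerate drop
    warning(sprintf("event %d: no supra-threshold negative gradient; drop marked degenerate",
                    event_index))
    t_drop_start <- ti[length(ti)]
    t_end <- ti[length(ti)]
  } else {
    half_d <- gi[ipk_d] / 2
    t_drop_start <- half_crossing(-gi, ti, ipk_d, -half_d, -1L, 1L)
    t_end <- half_crossing(-gi, ti, ipk_d, -half_d, +1L, length(gi))
  }
  if (t_rise_end > t_drop_start) {
    mid <- (t_rise_end + t_drop_start) / 2
    t_rise_end <- mid; t_drop_start <- mid
  }
  data.frame(event_index = event_index, t_start = t_start,
             t_rise_end = t_rise_end, t_drop_start = t_drop_start,
             t_end = t_end,
             rise_s = t_rise_end - t_start,
             hold_s = t_drop_start - t_rise_end,
             drop_s = t_end - t_drop_start,
             valid = TRUE)
}

#' Segment a session into heel-raise events with phases
#'
#' Composes [pitch_trace()], [detect_events()] and [detect_phases()] and
#' derives the idle interval preceding each event (from the previous
#' event's drop completion, or from the start of the recording for the
#' first event).
#'
#' @param session a [synced_session()].
#' @param cfg a [segmentation_config()].
#' @return data.frame of class `heel_raise_events`, one row per event,
#'   with the boundary times, phase durations, `preceding_idle_s` and
#'   `valid`; attribute `pitch_source` records which pitch was used.
#' @export
segment_session <- function(session, cfg = segmentation_config()) {
  pt <- pitch_trace(session, cfg$pitch_source)
  ev <- detect_events(pt, cfg)
  if (nrow(ev) == 0) {
    out <- data.frame(event_index = integer(0), t_start = numeric(0),
                      t_rise_end = numeric(0), t_drop_start = numeric(0),
                      t_end = numeric(0), rise_s = numeric(0),
                      hold_s = numeric(0), drop_s = numeric(0),
                      preceding_idle_s = numeric(0), valid = logical(0))
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
      detect_phases(pt, c(ev$t_start[i], ev$t_end[i]), cfg, event_index = i)
    }))
    prev_end <- c(pt$time[1], out$t_end[-nrow(out)])
    out$preceding_idle_s <- out$t_start - prev_end
  }
  structure(out, class = c("heel_raise_events", "data.frame"),
            pitch_source = attr(pt, "source"))
}
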