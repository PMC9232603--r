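# features: EMG waveform length, medial partial pressure, medio-lateral
# centre of pressure, and per-event-phase summary means.

#' EMG waveform length
#'
#' Sliding-window waveform length of a raw EMG trace,
#' `WL(t) = sum_{n = t-N+2}^{t} |x(n) - x(n-1)|`, i.e. the sum of the
#' `N - 1` absolute successive differences in the window ending at sample
#' `t`. A standard activation envelope: it grows with both amplitude and
#' frequency content. The output is window-end aligned (causal); the first
#' `N - 1` samples are `NA`, and the output has the same length as the
#' input.
#'
#' @param x numeric raw EMG trace, mV.
#' @param N window size in samples (>= 2). The conventional default is
#'   0.25 s worth of samples at the EMG rate, see [wl_window()].
#' @return numeric vector of WL values, mV, same length as `x`.
#' @examples
#' waveform_length(rep(c(0, 1), 8), N = 8)   # 7 unit steps per window
#' @export
waveform_length <- function(x, N) {
  hr_assert(is.numeric(N) && length(N) == 1 && N >= 2, "hr_parameter_error",
            "waveform_length(): window N must be >= 2")
  N <- as.integer(N)
  hr_assert(length(x) >= N, "hr_data_error",
            "waveform_length(): trace shorter than window N")
  d <- abs(diff(x))
  cs <- c(0, cumsum(d))
  # window ending at t (1-based t >= N) spans diffs (t-N+1)..(t-1)
  wl <- rep(NA_real_, length(x))
  idx <- N:length(x)
  wl[idx] <- cs[idx] - cs[idx - (N - 1L)]
  wl
}

#' Default waveform-length window
#'
#' @param rate_hz EMG sampling rate, Hz.
#' @param window_s window duration, seconds (default 0.25 s).
#' @return window size in samples (at least 2).
#' @export
wl_window <- function(rate_hz, window_s = 0.25) {
  max(2L, as.integer(round(rate_hz * window_s)))
}

#' Medial partial pressure (MPP)
#'
#' Medial share of the forefoot load,
#' `MPP = 100 * F2 / (F2 + F3)` percent, where `F2` is the force under the
#' 1st metatarsal head (medial) and `F3` under the 4th metatarsal head
#' (lateral). When the combined forefoot load falls to or below `floor`
#' the ratio is meaningless (both sensors unloaded, e.g. mid-swing) and
#' the sample is returned as `NA` rather than risking a division blow-up.
#'
#' @param F2,F3 non-negative force vectors, device units.
#' @param floor low-load floor in the same units; default 1 percent of the
#'   95th percentile of `F2 + F3` over the input.
#' @return percent vector in `[0, 100]` with `NA` at low-load samples.
#' @examples
#' mpp(30, 10)   # 75
#' @export
mpp <- function(F2, F3, floor = NULL) {
  hr_assert(length(F2) == length(F3), "hr_data_error",
            "mpp(): F2 and F3 must have equal length")
  hr_assert(all(F2 >= 0, na.rm = TRUE) && all(F3 >= 0, na.rm = TRUE),
            "hr_data_error", "mpp(): negative force")
  s <- F2 + F3
  if (is.null(floor)) {
    floor <- 0.01 * stats::quantile(s, 0.95, na.rm = TRUE, names = FALSE)
  }
  out <- rep(NA_real_, length(s))
  ok <- !is.na(s) & s > floor
  out[ok] <- 100 * F2[ok] / s[ok]
  out
}

#' Medio-lateral centre of pressure, percent of insole width
#'
#' `ML COP = 100 * (width - cop_x) / width`, with `cop_x` the medial-axis
#' COP coordinate reported by a grid-pressure insole of width `width_mm`.
#' Implemented exactly as defined; note that with `cop_x` a *medial*
#' coordinate the quantity reads as the complementary (lateral-referenced)
#' fraction — the sign convention follows the defining system and is kept
#' verbatim so values are comparable.
#'
#' @param cop_x COP coordinate, mm, within `[0, width_mm]`.
#' @param width_mm insole width, mm.
#' @return percent vector in `[0, 100]`.
#' @export
ml_cop <- function(cop_x, width_mm) {
  hr_assert(is.numeric(width_mm) && all(width_mm > 0), "hr_parameter_error",
            "ml_cop(): width_mm must be > 0")
  hr_assert(all(cop_x >= 0 & cop_x <= width_mm, na.rm = TRUE),
            "hr_data_error", "ml_cop(): cop_x outside [0, width_mm]")
  100 * (width_mm - cop_x) / width_mm
}

#' Centre of pressure from a sensor grid
#'
#' Force-weighted mean sensor coordinate,
#' `sum(x_i F_i) / sum(F_i)`; `NA` when the total force is zero.
#'
#' @param sensor_positions_mm sensor coordinates along the axis, mm.
#' @param forces corresponding non-negative forces.
#' @return COP coordinate, mm (scalar).
#' @export
cop_from_grid <- function(sensor_positions_mm, forces) {
  hr_assert(length(sensor_positions_mm) == length(forces), "hr_data_error",
            "cop_from_grid(): positions and forces must have equal length")
  hr_assert(all(forces >= 0, na.rm = TRUE), "hr_data_error",
            "cop_from_grid(): negative force")
  s <- sum(forces)
  if (!is.finite(s) || s == 0) return(NA_real_)
  sum(sensor_positions_mm * forces) / s
}

phase_bounds <- function(event) {
  data.frame(phase = c("rise", "hold", "drop"),
             a = c(event$t_start, event$t_rise_end, event$t_drop_start),
             b = c(event$t_rise_end, event$t_drop_start, event$t_end))
}

# Nearest-sample index range per phase (the boundary-mapping convention
# between clocks; also immune to float jitter at on-grid corners).
phase_index_ranges <- function(time, event) {
  idx <- nearest_index(time, c(event$t_start, event$t_rise_end,
                               event$t_drop_start, event$t_end))
  list(rise = idx[1]:max(idx[1], idx[2] - 1L),
       hold = idx[2]:max(idx[2], idx[3] - 1L),
       drop = idx[3]:idx[4])
}

#' Per-phase feature means for segmented events
#'
#' For every event x phase (rise/hold/drop), the arithmetic mean of each
#' available per-sample quantity over that phase: MPP (undefined low-load
#' samples excluded; a phase with no defined sample yields `NA`), pitch
#' and roll (when an orientation stream is present), ML COP (when a
#' grid-COP stream is present), and the waveform length of every EMG
#' channel. WL means are computed on the EMG clock over the phase interval
#' mapped by nearest sample, as column `wl_<channel>`.
#'
#' @param session a [synced_session()].
#' @param events a `heel_raise_events` table from [segment_session()].
#' @param wl_N waveform-length window in samples (default 0.25 s at the
#'   EMG rate).
#' @param mpp_floor low-load floor forwarded to [mpp()].
#' @return data.frame of class `phase_features`, one row per event x
#'   phase.
#' @export
phase_features <- function(session, events, wl_N = NULL, mpp_floor = NULL) {
  if (nrow(events) == 0) {
    return(structure(data.frame(event_index = integer(0),
                                phase = character(0)),
                     class = c("phase_features", "data.frame")))
  }
  ins <- session$insole
  t <- ins$time
  mpp_t <- mpp(ins$F2, ins$F3, floor = mpp_floor)
  ori <- session$orientation
  cop_t <- NULL
  if (!is.null(session$gridcop)) {
    cop_t <- ml_cop(session$gridcop$cop_x,
                    attr(session$gridcop, "meta")$width_mm)
  }
  wl <- NULL
  if (!is.null(session$emg)) {
    rate <- stream_rate(session$emg)
    N <- wl_N %||% wl_window(rate)
    wl <- lapply(as.data.frame(session$emg)[stream_channels(session$emg)],
                 waveform_length, N = N)
  }
  rows <- list()
  for (i in seq_len(nrow(events))) {
    evt <- events[i, ]
    if (!isTRUE(evt$valid)) next
    ranges <- phase_index_ranges(t, evt)
    ranges_cop <- if (!is.null(cop_t))
      phase_index_ranges(session$gridcop$time, evt) else NULL
    ranges_emg <- if (!is.null(wl))
      phase_index_ranges(session$emg$time, evt) else NULL
    for (ph in names(ranges)) {
      m <- ranges[[ph]]
      row <- data.frame(event_index = evt$event_index, phase = ph,
                        mean_mpp_pct = if (any(!is.na(mpp_t[m])))
                          mean(mpp_t[m], na.rm = TRUE) else NA_real_,
                        mean_pitch_deg = if (!is.null(ori))
                          mean(ori$pitch[m]) else NA_real_,
                        mean_roll_deg = if (!is.null(ori))
                          mean(ori$roll[m]) else NA_real_,
                        mean_ml_cop_pct = if (!is.null(cop_t))
                          mean(cop_t[ranges_cop[[ph]]]) else NA_real_)
      if (!is.null(wl)) {
        for (ch in names(wl)) {
          v <- wl[[ch]][ranges_emg[[ph]]]
          row[[paste0("wl_", ch)]] <-
            if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("phase_features", "data.frame"))
}
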