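# ensemble: phase-percent time normalisation and across-event mean +/- SD
# aggregation; rise-phase EMG normalisation for between-subject comparison.

#' Phase-percent time normalisation of one event
#'
#' Resamples a channel over one segmented event onto a fixed grid of
#' `points_per_phase` equally spaced fractions of each phase's duration
#' (rise, hold, drop concatenated), so that events of different durations
#' can be averaged point by point as "percent of phase".
#'
#' @param time,values the channel samples (any clock covering the event).
#' @param event one row of a `heel_raise_events` table.
#' @param points_per_phase grid points per phase (default 100).
#' @return numeric vector of length `3 * points_per_phase` with attribute
#'   `phase` labelling each point.
#' @export
normalize_phase_time <- function(time, values, event, points_per_phase = 100) {
  hr_assert(isTRUE(event$valid), "hr_data_error",
            "normalize_phase_time(): event has invalid phases")
  pb <- phase_bounds(event)
  P <- as.integer(points_per_phase)
  hr_assert(P >= 2, "hr_parameter_error", "points_per_phase must be >= 2")
  out <- numeric(0)
  for (k in seq_len(nrow(pb))) {
    grid <- pb$a[k] + seq(0, 1, length.out = P) * (pb$b[k] - pb$a[k])
    inside <- sum(time >= pb$a[k] & time <= pb$b[k])
    if (inside < 2) {
      warning(sprintf("phase '%s' covers < 2 samples; nearest-sample fill",
                      pb$phase[k]))
      i <- nearest_index(time, grid)
      out <- c(out, values[i])
    } else {
      out <- c(out, stats::approx(time, values, xout = grid, rule = 2)$y)
    }
  }
  structure(out, phase = rep(c("rise", "hold", "drop"), each = P))
}

#' Across-event ensemble mean and SD
#'
#' Pointwise arithmetic mean and sample standard deviation over events
#' (rows). With a single event the SD is zero.
#'
#' @param traces matrix with one row per event (e.g. stacked
#'   [normalize_phase_time()] outputs).
#' @return list with numeric vectors `mean` and `sd`.
#' @export
aggregate_traces <- function(traces) {
  traces <- rbind(traces)
  hr_assert(nrow(traces) >= 1, "hr_data_error",
            "aggregate_traces(): need >= 1 event")
  m <- colMeans(traces)
  s <- if (nrow(traces) == 1) rep(0, ncol(traces))
       else apply(traces, 2, stats::sd)
  list(mean = as.numeric(m), sd = as.numeric(s))
}

#' Phase-normalized ensemble of a channel over all events
#'
#' Convenience wrapper: normalises a channel for every valid event of a
#' session and aggregates the ensemble.
#'
#' @param time,values the channel samples.
#' @param events `heel_raise_events` table.
#' @param channel channel name carried into the result.
#' @param points_per_phase grid points per phase.
#' @return Object of class `phase_normalized_trace`: list with `channel`,
#'   `points_per_phase`, `traces` (event x point matrix), `mean`, `sd`
#'   and `phase` labels.
#' @export
ensemble_trace <- function(time, values, events, channel = "channel",
                           points_per_phase = 100) {
  events <- events[events$valid, , drop = FALSE]
  hr_assert(nrow(events) >= 1, "hr_data_error",
            "ensemble_trace(): no valid events")
  traces <- t(vapply(seq_len(nrow(events)), function(i) {
    as.numeric(normalize_phase_time(time, values, events[i, ],
                                    points_per_phase))
  }, numeric(3 * points_per_phase)))
  agg <- aggregate_traces(traces)
  structure(list(channel = channel, points_per_phase = points_per_phase,
                 traces = traces, mean = agg$mean, sd = agg$sd,
                 phase = rep(c("rise", "hold", "drop"),
                             each = points_per_phase)),
            class = "phase_normalized_trace")
}

#' @export
print.phase_normalized_trace <- function(x, ...) {
  cat(sprintf("<phase_normalized_trace> '%s': %d events x %d points (%d/phase)\n",
              x$channel, nrow(x$traces), ncol(x$traces), x$points_per_phase))
  invisible(x)
}

#' @export
plot.phase_normalized_trace <- function(x, ...) {
  P <- x$points_per_phase
  pct <- rep(seq(0, 100, length.out = P), 3)
  xx <- seq_along(x$mean)
  graphics::plot(xx, x$mean, type = "n",
                 ylim = range(c(x$mean - x$sd, x$mean + x$sd)),
                 xlab = "phase percent (rise | hold | drop)",
                 ylab = x$channel, xaxt = "n", ...)
  graphics::polygon(c(xx, rev(xx)),
                    c(x$mean + x$sd, rev(x$mean - x$sd)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(xx, x$mean, col = "steelblue", lwd = 2)
  graphics::abline(v = c(P, 2 * P) + 0.5, lty = 2, col = "grey50")
  graphics::axis(1, at = c(1, P, 2 * P, 3 * P),
                 labels = c("0%", "100/0%", "100/0%", "100%"))
  invisible(x)
}

#' Normalise EMG waveform-length features to the rise phase
#'
#' Raw EMG magnitudes are not comparable between subjects (electrode
#' placement, tissue impedance), so each subject x muscle value is divided
#' by that subject's mean rise-phase WL for the muscle. By default the
#' denominator pools the rise-phase means across all conditions present
#' for the subject (`denominator = "pooled"`); with
#' `denominator = "per-condition"` each condition is normalised to its own
#' rise mean. The choice is recorded in the `denominator` attribute of the
#' result.
#'
#' @param features a [phase_features()]-style data.frame with columns
#'   `phase`, `wl_*`, and (for cohorts) `subject`.
#' @param subject_col name of the subject column; when absent all rows are
#'   treated as one subject.
#' @param denominator `"pooled"` or `"per-condition"` (requires a
#'   `variant` column).
#' @return The input with each `wl_*` column replaced by its relative
#'   value; zero rise-phase denominators yield `NA` with a warning.
#' @export
normalize_emg_to_rise <- function(features, subject_col = "subject",
                                  denominator = c("pooled", "per-condition")) {
  denominator <- match.arg(denominator)
  wl_cols <- grep("^wl_", names(features), value = TRUE)
  hr_assert(length(wl_cols) > 0, "hr_data_error",
            "normalize_emg_to_rise(): no wl_* columns")
  if (!subject_col %in% names(features)) {
    features[[subject_col]] <- 1L
  }
  groups <- if (denominator == "per-condition") {
    hr_assert("variant" %in% names(features), "hr_data_error",
              "per-condition denominator requires a 'variant' column")
    interaction(features[[subject_col]], features$variant, drop = TRUE)
  } else {
    factor(features[[subject_col]])
  }
  out <- features
  for (g in levels(groups)) {
    sel <- groups == g
    rise <- sel & features$phase == "rise"
    hr_assert(any(rise), "hr_data_error",
              "normalize_emg_to_rise(): group %s has no rise-phase rows", g)
    for (ch in wl_cols) {
      denom <- mean(features[[ch]][rise], na.rm = TRUE)
      if (!is.finite(denom) || denom == 0) {
        warning(sprintf("zero/undefined rise-phase mean for %s in group %s; NA",
                        ch, g))
        out[[ch]][sel] <- NA_real_
      } else {
        out[[ch]][sel] <- features[[ch]][sel] / denom
      }
    }
  }
  structure(out, denominator = denominator)
}
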