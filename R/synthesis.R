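# synthesis: ground-truth-labelled synthetic heel-raise sessions emulating
# the cued protocol (idle 5 s, rise 1 s, hold 3 s, drop 1 s; 5 repetitions)
# across the four variants DL-EV, DL-IV, SL-EV, SL-IV.

HR_VARIANTS <- c("DL-EV", "DL-IV", "SL-EV", "SL-IV")

variant_is_eversion <- function(variant) grepl("EV$", variant)
variant_is_single_leg <- function(variant) grepl("^SL", variant)

#' Default per-muscle EMG activation gains
#'
#' Envelope amplitudes (mV, standard deviation of the amplitude-modulated
#' noise) per muscle and phase, encoding the activation contrasts the
#' pipeline is meant to recover: the peroneus longus (PL) is strongly
#' recruited during the rise phase only under eversion, and its onset is
#' delayed under inversion; gastrocnemius medialis/lateralis (GM, GL)
#' respond to single-vs-double leg load but not to ankle orientation;
#' soleus (SL) carries a modest orientation effect. Activation peaks in the
#' rise phase and decays through hold and drop. Single-leg variants scale
#' the plantar-flexor gains by 1.6.
#'
#' @param variant one of `"DL-EV"`, `"DL-IV"`, `"SL-EV"`, `"SL-IV"`.
#' @return Named list per muscle with elements `rise`, `hold`, `drop`
#'   (mV) and `delay_s` (activation onset delay into the rise phase).
#' @export
default_emg_gains <- function(variant) {
  ev <- variant_is_eversion(variant)
  load <- if (variant_is_single_leg(variant)) 1.6 else 1.0
  list(
    PL = list(rise = if (ev) 0.12 else 0.03,
              hold = if (ev) 0.06 else 0.02,
              drop = if (ev) 0.04 else 0.015,
              delay_s = if (ev) 0 else 0.4),
    GM = list(rise = 0.10 * load, hold = 0.06 * load, drop = 0.04 * load,
              delay_s = 0),
    GL = list(rise = 0.09 * load, hold = 0.055 * load, drop = 0.035 * load,
              delay_s = 0),
    SL = list(rise = (if (ev) 0.10 else 0.07) * load,
              hold = 0.06 * load, drop = 0.04 * load, delay_s = 0)
  )
}

#' Synthetic-session parameters
#'
#' Study conditions for [generate_session()]. Defaults encode the cued
#' protocol (phase durations 5/1/3/1 s, five repetitions) and
#' variant-dependent signal morphology: under eversion the roll excursion
#' during the rise is non-negative (+5 deg) and the medial partial pressure
#' (MPP) climbs from 55 to 75 %; under inversion the foot rolls outward
#' (-10 deg) and MPP falls from 45 to 25 %.
#'
#' @param variant heel-raise variant, one of `"DL-EV"`, `"DL-IV"`,
#'   `"SL-EV"`, `"SL-IV"` (double/single leg x eversion/inversion).
#' @param n_events number of repetitions (>= 1).
#' @param phase_durations_s mean idle/rise/hold/drop durations, seconds.
#' @param pitch_max_deg peak heel-raise pitch, degrees.
#' @param roll_delta_deg signed roll excursion during the rise, degrees
#'   (default +5 for EV, -10 for IV).
#' @param mpp_baseline_pct,mpp_raised_pct MPP during idle and hold, percent
#'   (defaults EV 55 -> 75, IV 45 -> 25).
#' @param duration_jitter_cv coefficient of variation of the per-event
#'   phase durations.
#' @param noise_sd named list of additive Gaussian noise SDs:
#'   `pitch`/`roll` (deg), `accel` (g), `force` (device units),
#'   `cop` (mm).
#' @param emg_rate_hz EMG sampling rate, Hz.
#' @param muscles EMG channel names to synthesize (`NULL` for no EMG
#'   stream).
#' @param emg_gain per-muscle gain table as from [default_emg_gains()].
#' @param include_gridcop synthesize a grid-pressure COP stream?
#' @param taper_s width of the cosine slope taper centred on each
#'   trapezoid corner of the pitch profile, seconds.
#' @param tail_s idle tail appended after the last drop, seconds.
#' @param insole_rate_hz master (insole) sampling rate, Hz.
#' @param total_force_units total plantar load in device units.
#' @param seed RNG seed (`NULL` = use the current RNG state).
#' @return A list of class `synthesis_params`.
#' @export
synthesis_params <- function(variant = "DL-EV",
                             n_events = 5,
                             phase_durations_s = c(idle = 5, rise = 1,
                                                   hold = 3, drop = 1),
                             pitch_max_deg = 25,
                             roll_delta_deg = NULL,
                             mpp_baseline_pct = NULL,
                             mpp_raised_pct = NULL,
                             duration_jitter_cv = 0.08,
                             noise_sd = list(pitch = 0.3, roll = 0.3,
                                             accel = 0.02, force = 1.5,
                                             cop = 1.0),
                             emg_rate_hz = 2000,
                             muscles = c("PL", "GM", "GL", "SL"),
                             emg_gain = NULL,
                             include_gridcop = TRUE,
                             taper_s = 0.2,
                             tail_s = 3,
                             insole_rate_hz = 30,
                             total_force_units = 600,
                             seed = NULL) {
  variant <- match.arg(variant, HR_VARIANTS)
  ev <- variant_is_eversion(variant)
  p <- list(
    variant = variant,
    n_events = as.integer(n_events),
    phase_durations_s = stats::setNames(as.numeric(phase_durations_s),
                                        c("idle", "rise", "hold", "drop")),
    pitch_max_deg = pitch_max_deg,
    roll_delta_deg = roll_delta_deg %||% (if (ev) 5 else -10),
    mpp_baseline_pct = mpp_baseline_pct %||% (if (ev) 55 else 45),
    mpp_raised_pct = mpp_raised_pct %||% (if (ev) 75 else 25),
    duration_jitter_cv = duration_jitter_cv,
    noise_sd = utils::modifyList(list(pitch = 0.3, roll = 0.3, accel = 0.02,
                                      force = 1.5, cop = 1.0),
                                 as.list(noise_sd)),
    emg_rate_hz = emg_rate_hz,
    muscles = muscles,
    emg_gain = emg_gain %||% default_emg_gains(variant),
    include_gridcop = isTRUE(include_gridcop),
    taper_s = taper_s,
    tail_s = tail_s,
    insole_rate_hz = insole_rate_hz,
    total_force_units = total_force_units,
    seed = seed
  )
  hr_assert(p$n_events >= 1, "hr_parameter_error", "n_events must be >= 1")
  hr_assert(all(p$phase_durations_s > 0), "hr_parameter_error",
            "phase durations must be > 0")
  hr_assert(p$mpp_baseline_pct >= 0 && p$mpp_baseline_pct <= 100 &&
              p$mpp_raised_pct >= 0 && p$mpp_raised_pct <= 100,
            "hr_parameter_error", "MPP percentages must lie in [0, 100]")
  hr_assert(p$pitch_max_deg > 0 && p$pitch_max_deg <= 90,
            "hr_parameter_error", "pitch_max_deg must lie in (0, 90]")
  structure(p, class = "synthesis_params")
}

# Integral of a unit-slope ramp whose slope turns on through a raised-cosine
# transition of width tau centred at c. Exact plateau and return-to-zero
# values follow from using the closed form rather than numeric integration.
ramp_integral <- function(t, c, tau) {
  s <- (t - c + tau / 2) / tau
  out <- numeric(length(t))
  mid <- s > 0 & s < 1
  out[s >= 1] <- t[s >= 1] - c
  out[mid] <- 0.5 * tau * (s[mid] - sin(pi * s[mid]) / pi)
  out
}

# Smooth 0 -> 1 step of width w centred at c (raised cosine).
smooth_step <- function(t, c, w) {
  s <- clamp((t - c + w / 2) / w, 0, 1)
  0.5 * (1 - cos(pi * s))
}

# Noiseless pitch profile (degrees) on time grid t for event corner times
# (r0, r1, r2, r3) = rise start, hold start, drop start, drop end.
pitch_profile <- function(t, corners, pitch_max, tau) {
  p <- numeric(length(t))
  for (i in seq_len(nrow(corners))) {
    r0 <- corners$t_start[i]; r1 <- corners$t_rise_end[i]
    r2 <- corners$t_drop_start[i]; r3 <- corners$t_end[i]
    m_r <- pitch_max / (r1 - r0)
    m_d <- pitch_max / (r3 - r2)
    p <- p + m_r * (ramp_integral(t, r0, tau) - ramp_integral(t, r1, tau)) -
      m_d * (ramp_integral(t, r2, tau) - ramp_integral(t, r3, tau))
  }
  p
}

draw_duration <- function(mean_s, cv, floor_s) {
  if (cv <= 0) return(mean_s)
  d <- stats::rnorm(1, mean_s, cv * mean_s)
  tries <- 0
  while (d < floor_s && tries < 100) {
    if (d <= 0) warning("jittered phase duration <= 0; redrawing")
    d <- stats::rnorm(1, mean_s, cv * mean_s)
    tries <- tries + 1
  }
  max(d, floor_s)
}

#' Generate a synthetic heel-raise session with ground truth
#'
#' Builds a fully synchronized multi-sensor session following the cued
#' protocol. Per event, phase durations are drawn around the programmed
#' means with the configured jitter. The pitch trace is a trapezoid whose
#' corners are smoothed by cosine slope tapers centred on the corner times,
#' so the programmed boundaries are exactly recoverable. Roll ramps by
#' `roll_delta_deg` with the pitch and returns during the drop; forefoot
#' forces are scaled so the instantaneous medial partial pressure
#' interpolates baseline -> raised between idle and hold; the heel channel
#' unloads as the heel lifts; accelerometer channels are derived from the
#' noiseless angles (`ay = sin(pitch)`, `ax = sin(roll)`,
#' `az = cos(pitch) cos(roll)`, in g) plus band-limited motion bursts
#' during rise/drop and additive noise. EMG channels are zero-mean Gaussian
#' noise amplitude-modulated per muscle and phase (see
#' [default_emg_gains()]).
#'
#' @param params a [synthesis_params()] object.
#' @return A list with elements `session` (a [synced_session()]) and
#'   `truth` (class `ground_truth`): per-event corner times `t_start`,
#'   `t_rise_end`, `t_drop_start`, `t_end`, the preceding idle duration,
#'   the variant label, and programmed per-phase MPP/roll means.
#' @examples
#' gs <- generate_session(synthesis_params(variant = "DL-EV", seed = 1,
#'                                         muscles = NULL))
#' gs$truth$events
#' @export
generate_session <- function(params = synthesis_params()) {
  hr_assert(inherits(params, "synthesis_params"), "hr_parameter_error",
            "generate_session() expects synthesis_params()")
  with_seed(params$seed, {
    pd <- params$phase_durations_s
    cv <- params$duration_jitter_cv
    tau <- params$taper_s
    floor_s <- max(2.5 * tau, 0.25)
    ev_rows <- vector("list", params$n_events)
    cursor <- 0
    for (i in seq_len(params$n_events)) {
      idle <- draw_duration(pd[["idle"]], cv, floor_s)
      rise <- draw_duration(pd[["rise"]], cv, floor_s)
      hold <- draw_duration(pd[["hold"]], cv, floor_s)
      drop <- draw_duration(pd[["drop"]], cv, floor_s)
      r0 <- cursor + idle
      ev_rows[[i]] <- data.frame(event_index = i, t_start = r0,
                                 t_rise_end = r0 + rise,
                                 t_drop_start = r0 + rise + hold,
                                 t_end = r0 + rise + hold + drop,
                                 preceding_idle_s = idle)
      cursor <- r0 + rise + hold + drop
    }
    corners <- do.call(rbind, ev_rows)
    total <- cursor + params$tail_s
    dt <- 1 / params$insole_rate_hz
    t <- seq(0, by = dt, length.out = floor(total / dt) + 1L)

    pitch0 <- pitch_profile(t, corners, params$pitch_max_deg, tau)
    w <- clamp(pitch0 / params$pitch_max_deg, 0, 1)
    roll0 <- params$roll_delta_deg * w
    mpp0 <- params$mpp_baseline_pct +
      (params$mpp_raised_pct - params$mpp_baseline_pct) * w

    Tf <- params$total_force_units
    F4 <- 0.45 * Tf * (1 - w)^2
    F1 <- 0.08 * Tf * (1 + 0.5 * w)
    F23 <- Tf - F4 - F1
    F2 <- F23 * mpp0 / 100
    F3 <- F23 - F2

    # Accelerometer: static-tilt projection of gravity plus motion bursts
    # (damped 4 Hz oscillation during rise and drop) and sensor noise.
    deg <- pi / 180
    ax <- sin(roll0 * deg)
    ay <- sin(pitch0 * deg)
    az <- cos(pitch0 * deg) * cos(roll0 * deg)
    burst <- function(a, b) {
      amp <- stats::rnorm(1, 0, 0.04)
      env <- smooth_step(t, a + 0.1, 0.2) - smooth_step(t, b - 0.1, 0.2)
      amp * env * sin(2 * pi * 4 * (t - a))
    }
    for (i in seq_len(nrow(corners))) {
      for (ph in list(c(corners$t_start[i], corners$t_rise_end[i]),
                      c(corners$t_drop_start[i], corners$t_end[i]))) {
        ax <- ax + burst(ph[1], ph[2])
        ay <- ay + burst(ph[1], ph[2])
        az <- az + burst(ph[1], ph[2])
      }
    }
    ns <- params$noise_sd
    n <- length(t)
    add_noise <- function(x, sd) if (sd > 0) x + stats::rnorm(n, 0, sd) else x
    insole <- insole_stream(
      t,
      F1 = pmax(0, add_noise(F1, ns$force)),
      F2 = pmax(0, add_noise(F2, ns$force)),
      F3 = pmax(0, add_noise(F3, ns$force)),
      F4 = pmax(0, add_noise(F4, ns$force)),
      ax = add_noise(ax, ns$accel),
      ay = add_noise(ay, ns$accel),
      az = add_noise(az, ns$accel),
      rate_hz = params$insole_rate_hz
    )
    orientation <- orientation_stream(
      t,
      pitch = clamp(add_noise(pitch0, ns$pitch), -90, 90),
      roll = clamp(add_noise(roll0, ns$roll), -90, 90),
      rate_hz = params$insole_rate_hz
    )

    emg <- NULL
    if (length(params$muscles) > 0) {
      te <- seq(0, by = 1 / params$emg_rate_hz,
                length.out = floor(total * params$emg_rate_hz) + 1L)
      te <- te[te <= t[n] + 1e-12]
      chans <- list()
      for (m in params$muscles) {
        g <- params$emg_gain[[m]]
        hr_assert(!is.null(g), "hr_parameter_error",
                  "no emg_gain entry for muscle %s", m)
        env <- rep(0.01, length(te))
        for (i in seq_len(nrow(corners))) {
          r0 <- corners$t_start[i] + (g$delay_s %||% 0)
          r1 <- corners$t_rise_end[i]
          r2 <- corners$t_drop_start[i]
          r3 <- corners$t_end[i]
          env <- env +
            g$rise * (smooth_step(te, r0, 0.2) - smooth_step(te, r1, 0.2)) +
            g$hold * (smooth_step(te, r1, 0.2) - smooth_step(te, r2, 0.2)) +
            g$drop * (smooth_step(te, r2, 0.2) - smooth_step(te, r3, 0.2))
        }
        chans[[m]] <- env * stats::rnorm(length(te))
      }
      emg <- emg_stream(te, chans, rate_hz = params$emg_rate_hz)
    }

    gridcop <- NULL
    if (params$include_gridcop) {
      width_mm <- 100
      tg <- seq(0, by = 1 / 50, length.out = floor(total * 50) + 1L)
      tg <- tg[tg <= t[n] + 1e-12]
      wg <- stats::approx(t, w, xout = tg, rule = 2)$y
      # Grid ML COP tracks the MPP contrast but attenuated: the full-foot
      # COP moves less than the two-sensor forefoot ratio.
      mlcop <- 50 + (params$mpp_baseline_pct - 50 +
                       (params$mpp_raised_pct - params$mpp_baseline_pct) * wg) * 0.6
      cop_x <- width_mm * (1 - mlcop / 100)
      if (ns$cop > 0) cop_x <- cop_x + stats::rnorm(length(tg), 0, ns$cop)
      gridcop <- gridcop_stream(tg, clamp(cop_x, 0, width_mm),
                                width_mm = width_mm, rate_hz = 50)
    }

    truth_phases <- do.call(rbind, lapply(seq_len(nrow(corners)), function(i) {
      ranges <- phase_index_ranges(t, corners[i, ])
      do.call(rbind, lapply(names(ranges), function(ph) {
        m <- ranges[[ph]]
        data.frame(event_index = i, phase = ph,
                   mpp_pct = mean(mpp0[m]), roll_deg = mean(roll0[m]))
      }))
    }))

    session <- synced_session(insole, orientation, emg, gridcop,
                              meta = list(variant = params$variant,
                                          seed = params$seed,
                                          synthetic = TRUE))
    truth <- structure(list(events = corners, variant = params$variant,
                            phase_profile = truth_phases,
                            params = params),
                       class = "ground_truth")
    list(session = session, truth = truth)
  })
}

#' Generate a synthetic multi-subject cohort
#'
#' Applies subject-level offsets to the MPP baselines and the roll
#' excursion before generating all four heel-raise variants per subject.
#' The default offset specification emulates the pronounced between-subject
#' scatter seen in small cohorts: MPP offsets are laid out on
#' quantile-spaced positions spanning `+/-spread` (plus Gaussian jitter),
#' so within-subject eversion/inversion separation is preserved while a
#' single pooled MPP threshold is not reliable — the motivation for
#' per-subject calibration. Roll offsets are Gaussian.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param per_subject_offsets list with components `mpp` (either
#'   `list(type = "stratified", spread, jitter_sd)` or
#'   `list(type = "normal", sd)` or `list(type = "none")`) and `roll`
#'   (`list(type = "normal", sd)` or `list(type = "none")`), percent and
#'   degrees respectively.
#' @param seed RNG seed for the whole cohort.
#' @param variants heel-raise variants generated per subject.
#' @param base_params a [synthesis_params()] used as template (its variant
#'   field is overridden).
#' @return List of class `hr_cohort`: one element per subject x variant
#'   with fields `subject`, `variant`, `session`, `truth`,
#'   `offsets`.
#' @export
generate_cohort <- function(n_subjects = 5,
                            per_subject_offsets = list(
                              mpp = list(type = "stratified", spread = 20,
                                         jitter_sd = 3),
                              roll = list(type = "normal", sd = 1.5)),
                            seed = NULL,
                            variants = HR_VARIANTS,
                            base_params = synthesis_params()) {
  hr_assert(is.numeric(n_subjects) && n_subjects >= 1, "hr_parameter_error",
            "n_subjects must be >= 1")
  n_subjects <- as.integer(n_subjects)
  with_seed(seed, {
    mspec <- per_subject_offsets$mpp %||% list(type = "none")
    rspec <- per_subject_offsets$roll %||% list(type = "none")
    mpp_off <- switch(mspec$type,
      none = rep(0, n_subjects),
      normal = stats::rnorm(n_subjects, 0, mspec$sd),
      stratified = {
        base <- if (n_subjects == 1) 0 else
          seq(-mspec$spread, mspec$spread, length.out = n_subjects)
        sample(base) + stats::rnorm(n_subjects, 0, mspec$jitter_sd %||% 0)
      },
      hr_error("hr_parameter_error", "unknown mpp offset type '%s'", mspec$type)
    )
    roll_off <- switch(rspec$type,
      none = rep(0, n_subjects),
      normal = stats::rnorm(n_subjects, 0, rspec$sd),
      hr_error("hr_parameter_error", "unknown roll offset type '%s'", rspec$type)
    )
    out <- list()
    for (s in seq_len(n_subjects)) {
      for (v in variants) {
        p <- base_params
        p$variant <- v
        evv <- variant_is_eversion(v)
        p$roll_delta_deg <- (if (evv) 5 else -10) + roll_off[s]
        p$mpp_baseline_pct <- clamp((if (evv) 55 else 45) + mpp_off[s], 2, 98)
        p$mpp_raised_pct <- clamp((if (evv) 75 else 25) + mpp_off[s], 2, 98)
        p$emg_gain <- default_emg_gains(v)
        p$seed <- NULL  # inherit the cohort RNG stream
        class(p) <- "synthesis_params"
        gs <- generate_session(p)
        gs$session$meta$subject <- s
        out[[length(out) + 1L]] <- list(subject = s, variant = v,
                                        session = gs$session,
                                        truth = gs$truth,
                                        offsets = c(mpp = mpp_off[s],
                                                    roll = roll_off[s]))
      }
    }
    structure(out, class = "hr_cohort")
  })
}
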