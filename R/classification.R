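# classification: eversion/inversion posture labelling on the (MPP, roll)
# plane, per-subject calibration, and the accel-vs-angle linear relation.

#' Event-phase points on the (MPP, roll) plane
#'
#' One point per event x selected phase, carrying the phase-mean medial
#' partial pressure and roll. Points with undefined MPP are omitted with a
#' warning. Any `subject`, `variant` or `label` columns present in the
#' feature table are passed through.
#'
#' @param features a [phase_features()] table.
#' @param phases which phases contribute points (default all three, as in
#'   a calibration scatter).
#' @return data.frame with columns `event_index`, `phase`, `mpp`, `roll`
#'   plus any pass-through columns.
#' @export
event_points <- function(features, phases = c("rise", "hold", "drop")) {
  keep <- features$phase %in% phases
  out <- features[keep, , drop = FALSE]
  drop <- is.na(out$mean_mpp_pct)
  if (any(drop)) {
    warning(sprintf("event_points: omitted %d point(s) with undefined MPP",
                    sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  res <- data.frame(event_index = out$event_index, phase = out$phase,
                    mpp = out$mean_mpp_pct, roll = out$mean_roll_deg)
  for (col in intersect(c("subject", "variant", "label"), names(out))) {
    res[[col]] <- out[[col]]
  }
  res
}

#' Fit an eversion/inversion decision boundary
#'
#' Two boundary kinds:
#' * `"mpp_threshold"` — a single vertical line at the midpoint between
#'   the class mean MPPs. Mirrors the naive approach that works within a
#'   subject but breaks down across subjects without calibration.
#' * `"linear_2d"` — a two-class linear discriminant on (MPP, roll) with
#'   equal priors and pooled within-class covariance; the minimal linear
#'   rule that uses foot orientation alongside pressure.
#'
#' @param points data.frame with columns `mpp`, `roll`.
#' @param labels vector of class labels, `"EV"`/`"IV"`, one per point.
#' @param kind boundary kind.
#' @return Object of class `orientation_boundary`: `kind`, parameters
#'   (`threshold` + `ev_high`, or `weight_mpp`, `weight_roll`, `offset`),
#'   and training metadata (`n_ev`, `n_iv`, `subjects`).
#' @export
fit_boundary <- function(points, labels,
                         kind = c("mpp_threshold", "linear_2d")) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  hr_assert(length(labels) == nrow(points), "hr_parameter_error",
            "fit_boundary(): one label per point required")
  hr_assert(all(labels %in% c("EV", "IV")), "hr_parameter_error",
            "fit_boundary(): labels must be 'EV' or 'IV'")
  ev <- points[labels == "EV", , drop = FALSE]
  iv <- points[labels == "IV", , drop = FALSE]
  if (nrow(ev) == 0 || nrow(iv) == 0) {
    hr_error("hr_calibration_error",
             "fit_boundary(): need >= 1 point per class (EV: %d, IV: %d)",
             nrow(ev), nrow(iv))
  }
  meta <- list(n_ev = nrow(ev), n_iv = nrow(iv),
               subjects = if ("subject" %in% names(points))
                 sort(unique(points$subject)) else NULL)
  if (kind == "mpp_threshold") {
    mu_ev <- mean(ev$mpp); mu_iv <- mean(iv$mpp)
    b <- list(kind = kind, threshold = (mu_ev + mu_iv) / 2,
              ev_high = mu_ev >= mu_iv, meta = meta)
  } else {
    if (nrow(ev) < 2 || nrow(iv) < 2) {
      hr_error("hr_calibration_error",
               "linear_2d boundary needs >= 2 points per class")
    }
    X_ev <- cbind(ev$mpp, ev$roll)
    X_iv <- cbind(iv$mpp, iv$roll)
    mu_e <- colMeans(X_ev); mu_i <- colMeans(X_iv)
    Sw <- (stats::cov(X_ev) * (nrow(X_ev) - 1) +
             stats::cov(X_iv) * (nrow(X_iv) - 1)) /
      (nrow(X_ev) + nrow(X_iv) - 2)
    # ridge for degenerate (collinear/duplicated) training sets
    Sw <- Sw + diag(1e-8 * (sum(diag(Sw)) + 1), 2)
    w <- solve(Sw, mu_e - mu_i)
    hr_assert(any(w != 0), "hr_calibration_error",
              "linear_2d boundary degenerate: zero weights")
    b <- list(kind = kind, weight_mpp = w[1], weight_roll = w[2],
              offset = sum(w * (mu_e + mu_i) / 2), meta = meta)
  }
  structure(b, class = "orientation_boundary")
}

#' @export
print.orientation_boundary <- function(x, ...) {
  if (x$kind == "mpp_threshold") {
    cat(sprintf("<orientation_boundary> MPP threshold at %.2f%% (EV %s)\n",
                x$threshold, if (x$ev_high) "above" else "below"))
  } else {
    cat(sprintf("<orientation_boundary> linear: %.4f*MPP %+.4f*roll > %.4f => EV\n",
                x$weight_mpp, x$weight_roll, x$offset))
  }
  cat(sprintf("  trained on %d EV / %d IV points\n", x$meta$n_ev, x$meta$n_iv))
  invisible(x)
}

boundary_score <- function(points, boundary) {
  if (boundary$kind == "mpp_threshold") {
    s <- points$mpp - boundary$threshold
    if (!boundary$ev_high) s <- -s
    s
  } else {
    boundary$weight_mpp * points$mpp + boundary$weight_roll * points$roll -
      boundary$offset
  }
}

#' Classify event-phase points as eversion or inversion
#'
#' Deterministic side-of-boundary labelling; a point exactly on the
#' boundary is labelled `"IV"` — in a rehabilitation setting the
#' conservative call is to flag possibly improper posture. Event-level
#' labels are the majority over the event's phase points (ties again to
#' `"IV"`).
#'
#' @param points data.frame from [event_points()].
#' @param boundary an [fit_boundary()] result.
#' @return list with `points` (input plus `pred` column) and `events`
#'   (per `event_index` — and per subject/variant when present — majority
#'   label).
#' @export
classify <- function(points, boundary) {
  hr_assert(inherits(boundary, "orientation_boundary"), "hr_parameter_error",
            "classify(): boundary must come from fit_boundary()")
  s <- boundary_score(points, boundary)
  pts <- points
  pts$pred <- ifelse(s > 0, "EV", "IV")
  keys <- c(intersect(c("subject", "variant"), names(pts)), "event_index")
  grp <- do.call(paste, c(pts[keys], sep = "\r"))
  ev_rows <- lapply(unique(grp), function(g) {
    sub <- pts[grp == g, , drop = FALSE]
    n_ev <- sum(sub$pred == "EV")
    lab <- if (n_ev > nrow(sub) - n_ev) "EV" else "IV"
    out <- sub[1, keys, drop = FALSE]
    out$pred <- lab
    out
  })
  events <- do.call(rbind, ev_rows)
  rownames(events) <- NULL
  list(points = pts, events = events)
}

#' Ordinary least-squares relation between acceleration and angle
#'
#' Quantifies how well an accelerometer channel tracks an orientation
#' angle over a session with a simple regression line and its R-squared.
#'
#' @param x accelerometer trace (g).
#' @param y angle trace (degrees), same length.
#' @return Object of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`. A constant `y` (zero total variance) is degenerate:
#'   `r_squared` is `NA` with a warning. A constant `x` is a fit error.
#' @export
fit_linear_relation <- function(x, y) {
  hr_assert(length(x) == length(y) && length(x) >= 3, "hr_parameter_error",
            "fit_linear_relation(): equal lengths >= 3 required")
  hr_assert(all(is.finite(x)) && all(is.finite(y)), "hr_data_error",
            "fit_linear_relation(): non-finite values")
  if (stats::var(x) == 0) {
    hr_error("hr_data_error", "fit_linear_relation(): zero variance in x")
  }
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    warning("fit_linear_relation(): constant y, R^2 undefined")
    NA_real_
  } else {
    clamp(1 - sum(stats::residuals(fit)^2) / sst, 0, 1)
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4f x %+0.4f, R^2 = %s, n = %d\n",
              x$slope, x$intercept,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$n))
  invisible(x)
}
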