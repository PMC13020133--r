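# --- gaze preprocessing and pursuit kinematics ------------------------------

check_uniform <- function(t_ms, tol = 1e-6) {
  dt <- diff(t_ms)
  if (length(dt) == 0 || any(abs(dt - dt[1]) > tol)) {
    stop("trace time base is not uniformly sampled", call. = FALSE)
  }
  dt[1]
}

# Odd (antisymmetric) reflection padding, MATLAB-filtfilt style, so that
# constant and linear trends pass the zero-phase filter without edge
# transients.
reflect_pad <- function(x, k) {
  n <- length(x)
  k <- min(k, n - 1)
  c(2 * x[1] - x[(k + 1):2], x, 2 * x[n] - x[(n - 1):(n - k)])
}

#' Low-pass filter gaze position
#'
#' Zero-phase (forward-backward) second-order Butterworth low-pass filter
#' applied independently to the horizontal and vertical position
#' channels.  Two passes give a squared magnitude response, so the
#' amplitude gain at the cutoff is 0.5.  The trace is padded by odd
#' reflection before filtering to suppress edge transients.
#'
#' @param trace Tibble with uniformly sampled columns `t_ms`, `x_deg`,
#'   `y_deg` (one trial).
#' @param cutoff_hz Cutoff frequency in Hz (default 30).
#' @param order Filter order per pass (default 2).
#' @return The trace with filtered `x_deg`, `y_deg`.
#' @export
lowpass_position <- function(trace, cutoff_hz = 30, order = 2) {
  dt <- check_uniform(trace$t_ms)
  if (nrow(trace) < 50) {
    stop("trace too short to filter (need >= 50 samples)", call. = FALSE)
  }
  fs <- 1000 / dt
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  k <- min(nrow(trace) - 1, round(0.2 * fs))
  smooth1 <- function(x) {
    xp <- reflect_pad(x, k)
    yp <- signal::filtfilt(bf, xp)
    yp[(k + 1):(k + length(x))]
  }
  trace$x_deg <- smooth1(trace$x_deg)
  trace$y_deg <- smooth1(trace$y_deg)
  trace
}

#' Differentiate gaze position to velocity
#'
#' Central differences, `v(t) = (p(t + dt) - p(t - dt)) / (2 dt)`, exact
#' for locally quadratic position; one-sided differences at the
#' endpoints.
#'
#' @param trace Tibble with uniform `t_ms`, `x_deg`, `y_deg`.
#' @return A velocity tibble with `t_ms`, `vx`, `vy` (deg/s) and an
#'   all-`FALSE` `saccade_mask` column.
#' @export
differentiate <- function(trace) {
  dt <- check_uniform(trace$t_ms) / 1000  # seconds
  n <- nrow(trace)
  if (n < 3) stop("need at least 3 samples to differentiate", call. = FALSE)
  cdiff <- function(p) {
    v <- numeric(n)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
    v[1] <- (p[2] - p[1]) / dt
    v[n] <- (p[n] - p[n - 1]) / dt
    v
  }
  tibble::tibble(
    t_ms = trace$t_ms,
    vx = cdiff(trace$x_deg),
    vy = cdiff(trace$y_deg),
    saccade_mask = FALSE
  )
}

#' Detect and mask saccades by speed threshold
#'
#' Samples whose 2-D speed exceeds `speed_threshold`, padded by `pad_ms`
#' on each side, are flagged in `saccade_mask` and their velocity samples
#' replaced by `NA`.  Unmasked samples are passed through untouched.
#'
#' @param vel Velocity tibble from [differentiate()].
#' @param speed_threshold Speed threshold in deg/s (default 30, suited to
#'   10 deg/s pursuit).
#' @param pad_ms Padding applied to each side of a detection, in ms.
#' @return The velocity tibble with `saccade_mask` set and masked `vx`,
#'   `vy` turned into `NA`; detected events are attached as the
#'   `"events"` attribute (tibble `onset_ms`, `offset_ms`).
#' @export
detect_and_mask_saccades <- function(vel, speed_threshold = 30, pad_ms = 10) {
  if (speed_threshold <= 0) {
    stop("`speed_threshold` must be positive", call. = FALSE)
  }
  dt <- check_uniform(vel$t_ms)
  speed <- sqrt(vel$vx^2 + vel$vy^2)
  over <- !is.na(speed) & speed > speed_threshold
  pad_k <- round(pad_ms / dt)
  mask <- over
  if (pad_k > 0 && any(over)) {
    idx <- which(over)
    for (shift in seq_len(pad_k)) {
      mask[pmax(idx - shift, 1)] <- TRUE
      mask[pmin(idx + shift, length(mask))] <- TRUE
    }
  }
  events <- tibble::tibble(onset_ms = numeric(0), offset_ms = numeric(0))
  if (any(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    events <- tibble::tibble(
      onset_ms = vel$t_ms[starts[keep]],
      offset_ms = vel$t_ms[ends[keep]]
    )
  }
  vel$saccade_mask <- vel$saccade_mask | mask
  vel$vx[vel$saccade_mask] <- NA_real_
  vel$vy[vel$saccade_mask] <- NA_real_
  attr(vel, "events") <- events
  vel
}

#' Project eye velocity onto a direction
#'
#' Signed component of the velocity vector along direction `theta`:
#' `vproj = vx * cos(theta) + vy * sin(theta)` (theta in degrees,
#' converted internally).  Missing velocity samples give missing output.
#'
#' @param vx,vy Velocity components in deg/s.
#' @param theta Direction in degrees.
#' @return Signed projected velocity in deg/s.
#' @examples
#' project_velocity(3, 4, 0)              # 3
#' project_velocity(3, 4, atan2(4, 3) * 180 / pi)  # 5
#' @export
project_velocity <- function(vx, vy, theta) {
  vx * cospi(theta / 180) + vy * sinpi(theta / 180)
}

window_sel <- function(t_ms, window) {
  t_ms >= window[1] & t_ms < window[2]
}

#' Anticipatory pursuit metrics
#'
#' Mean horizontal and vertical velocity over the anticipation window
#' (default -50 to 100 ms around stimulus onset, half-open), giving the
#' anticipation amplitude (vector norm), angle, and the projection onto
#' `theta` if supplied.  A trial is `valid` only when the amplitude lies
#' in `bounds` (default 0.25-2.5 deg/s: larger amplitudes are likely to
#' contain unmarked saccades, smaller ones noise or unstable fixation)
#' and at least half of the window samples are unmasked.
#'
#' @param vel Masked velocity tibble.
#' @param window Analysis window `c(start, end)` in ms, half-open.
#' @param theta Optional direction (deg) onto which to project the mean
#'   anticipatory velocity.
#' @param bounds Amplitude validity bounds in deg/s.
#' @param min_coverage Minimum unmasked fraction of window samples.
#' @return A one-row tibble: `amp`, `angle`, `vproj`, `valid`, `coverage`.
#' @export
anticipation_metrics <- function(vel, window = c(-50, 100), theta = NULL,
                                 bounds = c(0.25, 2.5), min_coverage = 0.5) {
  if (window[1] < min(vel$t_ms) || window[2] > max(vel$t_ms) + 1e-9) {
    stop("anticipation window lies outside the trace", call. = FALSE)
  }
  sel <- window_sel(vel$t_ms, window)
  coverage <- mean(!vel$saccade_mask[sel])
  if (!is.finite(coverage) || coverage < min_coverage) {
    return(tibble::tibble(amp = NA_real_, angle = NA_real_,
                          vproj = NA_real_, valid = FALSE,
                          coverage = coverage))
  }
  mvx <- mean(vel$vx[sel], na.rm = TRUE)
  mvy <- mean(vel$vy[sel], na.rm = TRUE)
  amp <- sqrt(mvx^2 + mvy^2)
  tibble::tibble(
    amp = amp,
    angle = circ_wrap(atan2(mvy, mvx) * 180 / pi),
    vproj = if (is.null(theta)) NA_real_ else project_velocity(mvx, mvy, theta),
    valid = amp >= bounds[1] & amp <= bounds[2],
    coverage = coverage
  )
}

#' Early (open-loop) pursuit acceleration
#'
#' Difference between the mean projected velocity in two 20-ms windows
#' (defaults 100-120 ms and 200-220 ms after motion onset) divided by
#' 0.1 s, in deg/s^2.  Either window empty after masking gives `NA`.
#'
#' @param vel Masked velocity tibble.
#' @param theta Stimulus direction in degrees.
#' @param window_early,window_late The two averaging windows in ms.
#' @return Acceleration in deg/s^2 (scalar, possibly `NA`).
#' @export
early_acceleration <- function(vel, theta, window_early = c(100, 120),
                               window_late = c(200, 220)) {
  vproj <- project_velocity(vel$vx, vel$vy, theta)
  m1 <- vproj[window_sel(vel$t_ms, window_early)]
  m2 <- vproj[window_sel(vel$t_ms, window_late)]
  if (all(is.na(m1)) || all(is.na(m2))) return(NA_real_)
  (mean(m2, na.rm = TRUE) - mean(m1, na.rm = TRUE)) /
    ((mean(window_late) - mean(window_early)) / 1000)
}

#' Steady-state pursuit velocity
#'
#' Mean projected velocity and the direction of the mean velocity vector
#' in the steady-state window (default 400-600 ms).
#'
#' @param vel Masked velocity tibble.
#' @param theta Stimulus direction in degrees.
#' @param window Averaging window in ms, half-open.
#' @param min_coverage Minimum unmasked fraction of window samples.
#' @return One-row tibble: `steady_vproj`, `steady_angle`, `coverage`.
#' @export
steady_state <- function(vel, theta, window = c(400, 600),
                         min_coverage = 0.5) {
  sel <- window_sel(vel$t_ms, window)
  coverage <- mean(!vel$saccade_mask[sel])
  if (!is.finite(coverage) || coverage < min_coverage) {
    return(tibble::tibble(steady_vproj = NA_real_, steady_angle = NA_real_,
                          coverage = coverage))
  }
  mvx <- mean(vel$vx[sel], na.rm = TRUE)
  mvy <- mean(vel$vy[sel], na.rm = TRUE)
  tibble::tibble(
    steady_vproj = project_velocity(mvx, mvy, theta),
    steady_angle = circ_wrap(atan2(mvy, mvx) * 180 / pi),
    coverage = coverage
  )
}

#' Per-trial pursuit kinematics for a set of traces
#'
#' Runs the full measurement chain on each trial's trace: 30-Hz
#' zero-phase low-pass on position, central-difference velocity, speed-
#' threshold saccade masking, then the three kinematic phases
#' (anticipation, open-loop acceleration, steady state).
#'
#' @param traces Long trace tibble (`subject_id`, `session`, `trial`,
#'   `t_ms`, `x_deg`, `y_deg`).
#' @param trials Trial tibble supplying `rdk_dir_deg` per trial.
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param speed_threshold,pad_ms Saccade masking parameters.
#' @param anticipation_window,accel_window_early,accel_window_late,steady_window
#'   Analysis windows in ms (half-open).
#' @param anticipation_bounds Validity bounds on anticipation amplitude.
#' @return A kinematic summary tibble, one row per trial: anticipation
#'   amplitude/angle/projection/validity, acceleration, steady-state
#'   projected velocity and angle, window coverages.
#' @export
extract_kinematics <- function(traces, trials,
                               cutoff_hz = 30,
                               speed_threshold = 30, pad_ms = 10,
                               anticipation_window = c(-50, 100),
                               accel_window_early = c(100, 120),
                               accel_window_late = c(200, 220),
                               steady_window = c(400, 600),
                               anticipation_bounds = c(0.25, 2.5)) {
  key <- c("subject_id", "session", "trial")
  info <- dplyr::distinct(
    dplyr::select(trials, dplyr::all_of(c(key, "rdk_dir_deg", "coherence")))
  )
  grouped <- dplyr::group_by(traces, dplyr::across(dplyr::all_of(key)))
  out <- dplyr::group_modify(grouped, function(tr, g) {
    theta <- info$rdk_dir_deg[
      info$subject_id == g$subject_id & info$session == g$session &
        info$trial == g$trial
    ]
    if (length(theta) != 1) {
      stop("trial ", g$trial, " not found (or duplicated) in `trials`",
           call. = FALSE)
    }
    vel <- differentiate(lowpass_position(tr, cutoff_hz = cutoff_hz))
    vel <- detect_and_mask_saccades(vel, speed_threshold, pad_ms)
    ant <- anticipation_metrics(vel, anticipation_window, theta = theta,
                                bounds = anticipation_bounds)
    st <- steady_state(vel, theta, steady_window)
    tibble::tibble(
      rdk_dir_deg = theta,
      anticipation_amp = ant$amp,
      anticipation_angle = ant$angle,
      anticipation_vproj = ant$vproj,
      anticipation_valid = ant$valid,
      anticipation_coverage = ant$coverage,
      accel = early_acceleration(vel, theta, accel_window_early,
                                 accel_window_late),
      steady_vproj = st$steady_vproj,
      steady_angle = st$steady_angle,
      steady_coverage = st$coverage,
      n_masked = sum(vel$saccade_mask)
    )
  })
  out <- dplyr::ungroup(out)
  dplyr::left_join(out,
                   dplyr::select(info, dplyr::all_of(c(key, "coherence"))),
                   by = key)
}

#' Normalised angular histogram
#'
#' Bins angles into the 16 direction bins and returns the per-bin
#' fraction of trials (all 16 bins reported, zeros included; fractions
#' sum to 1).
#'
#' @param data Data frame of trials.
#' @param angle Column of angles in degrees (tidy-eval).
#' @param n_bins Number of bins.
#' @return A tibble of class `angular_histogram` with `bin_center` and
#'   `freq`; the number of trials is in the `"n_trials"` attribute.
#' @export
anticipation_histogram <- function(data, angle, n_bins = 16) {
  ang <- dplyr::pull(data, {{ angle }})
  ang <- ang[!is.na(ang)]
  if (length(ang) == 0) {
    stop("no trials with a finite angle to histogram", call. = FALSE)
  }
  centers <- direction_bin_centers(n_bins)
  k <- match(bin_direction(ang, n_bins), centers)
  out <- tibble::tibble(
    bin_center = centers,
    freq = tabulate(k, n_bins) / length(ang)
  )
  attr(out, "n_trials") <- length(ang)
  class(out) <- c("angular_histogram", class(out))
  out
}
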