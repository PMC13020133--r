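# Quintic smoothstep: C2 transition from 0 (u <= 0) to 1 (u >= 1).
smootherstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * u * (u * (u * 6 - 15) + 10)
}

# Deterministic (noise- and saccade-free) velocity components of one
# trial, evaluated on the time grid `t` (ms relative to stimulus onset).
# Returns list(ant = anticipatory speed profile, vis = visual speed
# profile along the stimulus direction).
pursuit_profile <- function(t, observer, gain, gap = 300) {
  lat <- observer$pursuit_latency_ms
  ant <- observer$anticipation_gain *
    smootherstep((t + gap) / observer$anticipation_rise_ms) *
    (1 - smootherstep((t - lat) / observer$anticipation_decay_ms))
  vis <- gain * 10 * smootherstep((t - lat) / observer$pursuit_rise_ms)
  list(ant = ant, vis = vis)
}

#' Simulate 500-Hz eye traces for a trial table
#'
#' Each trial's two-channel gaze trace spans
#' `-(fixation_ms + gap_ms)` to `stim_ms` at 500 Hz (2-ms samples, t = 0
#' at stimulus onset).  Velocity is the sum of: a smooth anticipatory
#' ramp that starts at gap onset, plateaus at `anticipation_gain` deg/s
#' toward a direction drawn around the observer's expected direction, and
#' decays after pursuit latency; a visually driven component that rises
#' smoothly from latency to `pursuit_gain[coherence] * 10` deg/s along the
#' stimulus direction (plateau reached at latency + `pursuit_rise_ms`,
#' i.e. by the 400-ms steady-state window with the defaults); white
#' Gaussian velocity noise; and raised-cosine saccade pulses injected as
#' a Poisson process.  Position is the cumulative (trapezoid) integral of
#' velocity.
#'
#' The expected direction is the session's frequent direction for biased
#' trials and a per-subject idiosyncratic direction (drawn once per
#' subject, uniform on the circle) for unbiased trials.
#'
#' @param trials Trial tibble (see [sample_trials()]).
#' @param observer An [observer_params()] object.
#' @param seed Optional integer seed; per-trial substreams are derived.
#' @return A list of class `eye_simulation` with elements
#'   \describe{
#'     \item{traces}{long tibble `subject_id`, `session`, `trial`, `t_ms`,
#'       `x_deg`, `y_deg`;}
#'     \item{saccades}{ground-truth saccade intervals `subject_id`,
#'       `session`, `trial`, `onset_ms`, `offset_ms`;}
#'     \item{truth}{per-trial generator ground truth: anticipation
#'       direction and amplitude, and the acceleration and steady-state
#'       projected velocity implied by the deterministic profile under the
#'       package's measurement windows.}
#'   }
#' @export
simulate_eye_traces <- function(trials, observer, seed = NULL) {
  stopifnot(inherits(observer, "observer_params"))
  req <- c("subject_id", "trial", "rdk_dir_deg", "coherence", "fixation_ms")
  if (!all(req %in% names(trials))) {
    stop("`trials` must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  subjects <- unique(trials$subject_id)
  # per-subject idiosyncratic anticipation direction for unbiased trials
  pref <- with_seed_or_not(
    if (is.null(seed)) NULL else derive_seed(seed, 999),
    stats::setNames(circ_wrap(stats::runif(length(subjects), -180, 180)),
                    subjects)
  )
  session_col <- if ("session" %in% names(trials)) trials$session else "session"
  fd <- if ("frequent_dir_deg" %in% names(trials)) {
    trials$frequent_dir_deg
  } else {
    rep(NA_real_, nrow(trials))
  }
  one_trial <- function(i) {
    row <- trials[i, ]
    trial_seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
    with_seed_or_not(trial_seed, {
      gap <- if ("gap_ms" %in% names(row)) row$gap_ms else 300
      stim <- if ("stim_ms" %in% names(row)) row$stim_ms else 1000
      t0 <- -2 * round((row$fixation_ms + gap) / 2)
      t <- seq(t0, stim, by = 2)
      n <- length(t)
      expected <- if (!is.na(fd[i])) fd[i] else pref[[as.character(row$subject_id)]]
      kappa_ant <- (180 / (pi * observer$anticipation_spread))^2
      ant_dir <- rvonmises(1, expected, kappa_ant)
      gain <- observer$pursuit_gain[coherence_index(observer, row$coherence)]
      prof <- pursuit_profile(t, observer, gain, gap = gap)
      vx <- prof$ant * cospi(ant_dir / 180) +
        prof$vis * cospi(row$rdk_dir_deg / 180)
      vy <- prof$ant * sinpi(ant_dir / 180) +
        prof$vis * sinpi(row$rdk_dir_deg / 180)
      if (observer$velocity_noise_sd > 0) {
        vx <- vx + stats::rnorm(n, 0, observer$velocity_noise_sd)
        vy <- vy + stats::rnorm(n, 0, observer$velocity_noise_sd)
      }
      sacc <- NULL
      if (observer$saccade_rate > 0) {
        span_s <- (stim - t0) / 1000
        n_sacc <- stats::rpois(1, observer$saccade_rate * span_s)
        if (n_sacc > 0) {
          dur <- observer$saccade_duration_ms
          onset <- sort(stats::runif(n_sacc, t0, stim - dur))
          dir <- stats::runif(n_sacc, -180, 180)
          for (s in seq_len(n_sacc)) {
            sel <- t >= onset[s] & t <= onset[s] + dur
            pulse <- observer$saccade_peak_speed / 2 *
              (1 - cos(2 * pi * (t[sel] - onset[s]) / dur))
            vx[sel] <- vx[sel] + pulse * cospi(dir[s] / 180)
            vy[sel] <- vy[sel] + pulse * sinpi(dir[s] / 180)
          }
          sacc <- tibble::tibble(
            subject_id = row$subject_id, session = row$session,
            trial = row$trial, onset_ms = onset, offset_ms = onset + dur
          )
        }
      }
      dt_s <- 0.002
      x <- c(0, cumsum((vx[-1] + vx[-n]) / 2) * dt_s)
      y <- c(0, cumsum((vy[-1] + vy[-n]) / 2) * dt_s)
      # generator-side truth under the package's measurement windows
      vproj_det <- prof$vis +
        prof$ant * cospi((ant_dir - row$rdk_dir_deg) / 180)
      w1 <- t >= 100 & t < 120
      w2 <- t >= 200 & t < 220
      ws <- t >= 400 & t < 600
      truth <- tibble::tibble(
        subject_id = row$subject_id, session = row$session, trial = row$trial,
        ant_dir_deg = ant_dir, ant_amp = observer$anticipation_gain,
        accel = (mean(vproj_det[w2]) - mean(vproj_det[w1])) / 0.1,
        steady_vproj = mean(vproj_det[ws]),
        steady_angle_deg = row$rdk_dir_deg
      )
      list(
        trace = tibble::tibble(
          subject_id = row$subject_id, session = row$session,
          trial = row$trial, t_ms = t, x_deg = x, y_deg = y
        ),
        saccades = sacc,
        truth = truth
      )
    })
  }
  parts <- purrr::map(seq_len(nrow(trials)), one_trial)
  structure(
    list(
      traces = purrr::list_rbind(purrr::map(parts, "trace")),
      saccades = purrr::list_rbind(purrr::compact(purrr::map(parts, "saccades"))),
      truth = purrr::list_rbind(purrr::map(parts, "truth"))
    ),
    class = "eye_simulation"
  )
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: samples trials for each session design, simulates
#' perceptual reports and (optionally) eye traces.
#'
#' @param designs A list of [make_session_design()] objects.
#' @param observer An [observer_params()] object.
#' @param n_subjects Number of subjects (shared across sessions).
#' @param seed Optional integer seed.
#' @param traces Simulate eye traces as well? (They dominate run time.)
#' @return A list with `trials` (all sessions bound together) and, when
#'   `traces = TRUE`, `traces`, `saccades` and `truth` tibbles.
#' @export
simulate_experiment <- function(designs, observer, n_subjects = 1,
                                seed = NULL, traces = TRUE) {
  stopifnot(is.list(designs), length(designs) > 0)
  trials <- purrr::list_rbind(purrr::map2(
    designs, seq_along(designs),
    function(d, k) {
      s <- if (is.null(seed)) NULL else derive_seed(seed, 10000 + k)
      sample_trials(d, n_subjects = n_subjects, seed = s)
    }
  ))
  rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, 20000)
  trials <- simulate_reports(trials, observer, seed = rep_seed)
  out <- list(trials = trials)
  if (traces) {
    tr_seed <- if (is.null(seed)) NULL else derive_seed(seed, 30000)
    sim <- simulate_eye_traces(trials, observer, seed = tr_seed)
    out$traces <- sim$traces
    out$saccades <- sim$saccades
    out$truth <- sim$truth
  }
  out
}
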