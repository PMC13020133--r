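# Shared fixture builders (all generated in code at test time).

# Observer whose reports are pure guesses from the cardinal/avoidance
# mixture (no sensory component, no lapses).
guess_observer <- function(avoidance_strength = 0, kappa_avoid = 8,
                           cardinal_weights = c(2, 1.2, 0.8, 1.5),
                           kappa_cardinal = 6) {
  observer_params(w_sensory = c(0, 0, 0), lapse_rate = 0,
                  cardinal_weights = cardinal_weights,
                  kappa_cardinal = kappa_cardinal,
                  avoidance_strength = avoidance_strength,
                  kappa_avoid = kappa_avoid)
}

# Observer guessing uniformly on the circle.
uniform_observer <- function() {
  guess_observer(cardinal_weights = c(1, 1, 1, 1), kappa_cardinal = 0)
}

# Two-session per-subject angle data where the biased session's guesses
# come from `observer_b` and the unbiased session's from `observer_a`
# (same distribution when the two observers coincide).
two_session_guesses <- function(n_subjects, n_trials, observer_a,
                                observer_b = observer_a,
                                frequent_direction = 0, seed = NULL) {
  d_unb <- make_session_design("unbiased", n_trials = n_trials)
  d_bia <- make_session_design("biased",
                               frequent_direction = frequent_direction,
                               n_trials = n_trials)
  ta <- sample_trials(d_unb, n_subjects,
                      seed = if (is.null(seed)) NULL else seed)
  tb <- sample_trials(d_bia, n_subjects,
                      seed = if (is.null(seed)) NULL else seed + 1)
  ta <- simulate_reports(ta, observer_a,
                         seed = if (is.null(seed)) NULL else seed + 2)
  tb <- simulate_reports(tb, observer_b,
                         seed = if (is.null(seed)) NULL else seed + 3)
  dplyr::bind_rows(ta, tb)
}

# Straight-line gaze trace (constant velocity), for kinematic unit tests.
constant_velocity_trace <- function(vx, vy, t_from = -400, t_to = 1000) {
  t <- seq(t_from, t_to, by = 2)
  tibble::tibble(t_ms = t, x_deg = vx * t / 1000, y_deg = vy * t / 1000)
}

# Velocity tibble built directly (bypassing position), for window tests.
velocity_tibble <- function(t_ms, vx, vy) {
  tibble::tibble(t_ms = t_ms, vx = vx, vy = vy, saccade_mask = FALSE)
}
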