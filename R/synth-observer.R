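#' Generative parameters of the synthetic observer
#'
#' The synthetic observer stands in for a human participant.  Perceptual
#' reports are drawn from a mixture: with probability `lapse_rate` a
#' uniform guess; otherwise with probability `w_sensory[coherence]` a von
#' Mises centred on the true RDK direction with concentration
#' `kappa[coherence]`; otherwise a "guess" from a cardinal-prior mixture
#' whose density is multiplicatively suppressed around the session's
#' frequent direction (avoidance).  Eye traces combine an anticipatory
#' ramp toward the expected direction, a visually driven pursuit component
#' along the stimulus direction, white velocity noise and injected
#' saccades.
#'
#' @param coherence_levels Coherence levels the per-coherence vectors refer
#'   to.
#' @param kappa Sensory von Mises concentration per coherence level.
#' @param w_sensory Probability that the report is stimulus-locked, per
#'   coherence level.
#' @param cardinal_directions Centers of the cardinal prior components.
#' @param cardinal_weights Nonnegative mixture weights of the cardinal
#'   components (normalised internally).
#' @param kappa_cardinal Shared concentration of the cardinal components;
#'   0 makes the guess distribution uniform.
#' @param avoidance_strength `a` in `[0, 1]`: depth of the multiplicative
#'   dip of the guess density at the frequent direction (0 = no
#'   avoidance, 1 = complete suppression at the dip center).
#' @param kappa_avoid Concentration (width) of the avoidance dip.
#' @param lapse_rate Probability of a uniform lapse report.
#' @param anticipation_gain Asymptotic anticipatory eye speed in deg/s.
#' @param anticipation_spread Angular spread (deg, SD-like) of the
#'   per-trial anticipation direction around the expected direction.
#' @param anticipation_rise_ms,anticipation_decay_ms Durations of the
#'   smooth anticipatory ramp-up (starting at gap onset) and of its decay
#'   after pursuit latency.
#' @param pursuit_latency_ms Visuomotor latency in ms.
#' @param pursuit_rise_ms Duration of the smooth rise of visually driven
#'   pursuit from latency to its plateau.
#' @param pursuit_gain Steady-state pursuit gain per coherence level
#'   (eye speed = gain x 10 deg/s).
#' @param velocity_noise_sd White velocity noise SD per channel (deg/s).
#' @param saccade_rate Saccade events per second.
#' @param saccade_peak_speed Peak speed of injected saccade pulses (deg/s).
#' @param saccade_duration_ms Duration of each saccade pulse (ms).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(coherence_levels = c(0.05, 0.15, 0.40),
                            kappa = c(8, 25, 60),
                            w_sensory = c(0.30, 0.80, 0.95),
                            cardinal_directions = c(0, -90, 90, 180),
                            cardinal_weights = c(2, 1.2, 0.8, 1.5),
                            kappa_cardinal = 6,
                            avoidance_strength = 0.6,
                            kappa_avoid = 8,
                            lapse_rate = 0.02,
                            anticipation_gain = 0.8,
                            anticipation_spread = 40,
                            anticipation_rise_ms = 200,
                            anticipation_decay_ms = 150,
                            pursuit_latency_ms = 100,
                            pursuit_rise_ms = 300,
                            pursuit_gain = c(0.55, 0.75, 0.90),
                            velocity_noise_sd = 0.5,
                            saccade_rate = 2,
                            saccade_peak_speed = 150,
                            saccade_duration_ms = 30) {
  stopifnot(
    length(kappa) == length(coherence_levels),
    length(w_sensory) == length(coherence_levels),
    length(pursuit_gain) == length(coherence_levels),
    all(kappa >= 0), all(w_sensory >= 0), all(w_sensory <= 1),
    length(cardinal_weights) == length(cardinal_directions),
    all(cardinal_weights >= 0), sum(cardinal_weights) > 0,
    kappa_cardinal >= 0,
    avoidance_strength >= 0, avoidance_strength <= 1, kappa_avoid >= 0,
    lapse_rate >= 0, lapse_rate <= 1,
    anticipation_gain >= 0, anticipation_spread > 0,
    pursuit_latency_ms > 0, pursuit_rise_ms > 0,
    velocity_noise_sd >= 0, saccade_rate >= 0,
    saccade_peak_speed > 0, saccade_duration_ms > 0
  )
  structure(
    list(
      coherence_levels = coherence_levels,
      kappa = kappa,
      w_sensory = w_sensory,
      cardinal_directions = circ_wrap(cardinal_directions),
      cardinal_weights = cardinal_weights / sum(cardinal_weights),
      kappa_cardinal = kappa_cardinal,
      avoidance_strength = avoidance_strength,
      kappa_avoid = kappa_avoid,
      lapse_rate = lapse_rate,
      anticipation_gain = anticipation_gain,
      anticipation_spread = anticipation_spread,
      anticipation_rise_ms = anticipation_rise_ms,
      anticipation_decay_ms = anticipation_decay_ms,
      pursuit_latency_ms = pursuit_latency_ms,
      pursuit_rise_ms = pursuit_rise_ms,
      pursuit_gain = pursuit_gain,
      velocity_noise_sd = velocity_noise_sd,
      saccade_rate = saccade_rate,
      saccade_peak_speed = saccade_peak_speed,
      saccade_duration_ms = saccade_duration_ms
    ),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat("  coherence:", paste(x$coherence_levels, collapse = "/"),
      " kappa:", paste(x$kappa, collapse = "/"),
      " w_sensory:", paste(x$w_sensory, collapse = "/"), "\n")
  cat("  avoidance:", x$avoidance_strength, "(kappa", x$kappa_avoid, ")",
      " lapse:", x$lapse_rate, "\n")
  cat("  anticipation gain:", x$anticipation_gain, "deg/s; pursuit gain:",
      paste(x$pursuit_gain, collapse = "/"), "\n")
  invisible(x)
}

coherence_index <- function(observer, coherence) {
  idx <- match(coherence, observer$coherence_levels)
  if (anyNA(idx)) {
    stop("coherence level not present in `observer$coherence_levels`",
         call. = FALSE)
  }
  idx
}

# Unnormalised guess weight profile: cardinal mixture times the avoidance
# factor 1 - a * vM(theta; frequent, kappa_avoid)/max(vM).
guess_weight <- function(theta, observer, frequent_direction = NULL) {
  card <- rep(0, length(theta))
  for (j in seq_along(observer$cardinal_directions)) {
    card <- card + observer$cardinal_weights[j] *
      dvonmises(theta, observer$cardinal_directions[j], observer$kappa_cardinal)
  }
  avoid <- 1
  if (!is.null(frequent_direction) && !is.na(frequent_direction) &&
      observer$avoidance_strength > 0) {
    avoid <- 1 - observer$avoidance_strength *
      exp(observer$kappa_avoid *
            (cospi((theta - frequent_direction) / 180) - 1))
  }
  card * avoid
}

#' Guess density of the synthetic observer
#'
#' Normalised density (per degree, integrating to 1 over the circle) of
#' the observer's non-sensory "guess" component: a cardinal von Mises
#' mixture suppressed around the frequent direction.
#'
#' @param theta Angles in degrees at which to evaluate the density.
#' @param observer An [observer_params()] object.
#' @param frequent_direction Frequent direction of the session in degrees,
#'   or `NULL`/`NA` for an unbiased session (no avoidance dip).
#' @return Density values per degree.
#' @export
guess_density <- function(theta, observer, frequent_direction = NULL) {
  stopifnot(inherits(observer, "observer_params"))
  grid <- seq(-180, 180 - 360 / 4096, length.out = 4096)
  z <- mean(guess_weight(grid, observer, frequent_direction)) * 360
  guess_weight(theta, observer, frequent_direction) / z
}

# Exact draws from the guess density by rejection from the cardinal
# mixture (acceptance probability = the avoidance factor <= 1).
sample_guess <- function(n, observer, frequent_direction = NULL) {
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  need <- n
  filled <- 0
  while (need > 0) {
    m <- ceiling(need / max(0.2, 1 - observer$avoidance_strength * 0.9))
    comp <- sample.int(length(observer$cardinal_weights), m, replace = TRUE,
                       prob = observer$cardinal_weights)
    theta <- rvonmises(m, 0, observer$kappa_cardinal) +
      observer$cardinal_directions[comp]
    theta <- circ_wrap(theta)
    keep <- rep(TRUE, m)
    if (!is.null(frequent_direction) && !is.na(frequent_direction) &&
        observer$avoidance_strength > 0) {
      p_acc <- 1 - observer$avoidance_strength *
        exp(observer$kappa_avoid *
              (cospi((theta - frequent_direction) / 180) - 1))
      keep <- stats::runif(m) < p_acc
    }
    theta <- theta[keep]
    take <- min(length(theta), need)
    if (take > 0) {
      out[filled + seq_len(take)] <- theta[seq_len(take)]
      filled <- filled + take
      need <- need - take
    }
  }
  out
}

#' Simulate perceptual reports for a trial table
#'
#' Fills the `report_dir_deg` column of a trial table with draws from the
#' observer's report mixture (see [observer_params()]).  The avoidance dip
#' is placed at each trial's `frequent_dir_deg`; unbiased trials
#' (`frequent_dir_deg` missing) get no dip.
#'
#' @param trials Trial tibble from [sample_trials()].
#' @param observer An [observer_params()] object.
#' @param seed Optional integer seed.
#' @return The trial tibble with `report_dir_deg` filled in.
#' @export
simulate_reports <- function(trials, observer, seed = NULL) {
  stopifnot(inherits(observer, "observer_params"))
  req <- c("rdk_dir_deg", "coherence")
  if (!all(req %in% names(trials))) {
    stop("`trials` must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  with_seed_or_not(seed, {
    n <- nrow(trials)
    idx <- coherence_index(observer, trials$coherence)
    u_lapse <- stats::runif(n)
    u_sens <- stats::runif(n)
    report <- numeric(n)
    is_lapse <- u_lapse < observer$lapse_rate
    is_sens <- !is_lapse & u_sens < observer$w_sensory[idx]
    is_guess <- !is_lapse & !is_sens
    if (any(is_lapse)) {
      report[is_lapse] <- circ_wrap(stats::runif(sum(is_lapse), -180, 180))
    }
    if (any(is_sens)) {
      # vectorised over kappa by grouping on coherence level
      for (k in unique(idx[is_sens])) {
        sel <- is_sens & idx == k
        report[sel] <- rvonmises(sum(sel), 0, observer$kappa[k]) +
          trials$rdk_dir_deg[sel]
      }
    }
    if (any(is_guess)) {
      fd <- trials$frequent_dir_deg
      if (is.null(fd)) fd <- rep(NA_real_, n)
      for (f in unique(fd[is_guess])) {
        sel <- is_guess & (is.na(fd) == is.na(f)) &
          (is.na(f) | (!is.na(fd) & fd == f))
        report[sel] <- sample_guess(sum(sel), observer, f)
      }
    }
    trials$report_dir_deg <- circ_wrap(report)
    trials
  })
}
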