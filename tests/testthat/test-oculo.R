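test_that("zero-phase low-pass has unit DC gain and the oracle response", {
  t <- seq(-500, 1000, by = 2)
  const <- tibble::tibble(t_ms = t, x_deg = 3, y_deg = -1.5)
  out <- lowpass_position(const)
  expect_lt(max(abs(out$x_deg - 3)), 1e-6)
  expect_lt(max(abs(out$y_deg + 1.5)), 1e-6)

  # sinusoids: measure amplitude away from the edges, compare to the
  # squared-transfer-function oracle
  t_s <- t / 1000
  interior <- t > -300 & t < 800
  for (f in c(30, 100)) {
    tr <- tibble::tibble(t_ms = t, x_deg = sin(2 * pi * f * t_s), y_deg = 0)
    filt <- lowpass_position(tr)
    amp <- fit_sine_amplitude(t_s[interior], filt$x_deg[interior], f)
    expect_equal(unname(amp), filtfilt_gain_oracle(f, 30, 500),
                 tolerance = 0.02)
  }
  # two passes of -3 dB at the cutoff: amplitude ratio 1/2
  expect_equal(filtfilt_gain_oracle(30, 30, 500), 0.5, tolerance = 1e-12)
  # 100 Hz is crushed below 5%
  expect_lt(filtfilt_gain_oracle(100, 30, 500), 0.05)

  bad <- tibble::tibble(t_ms = c(0, 2, 6, 8), x_deg = 0, y_deg = 0)
  expect_error(lowpass_position(bad), "uniform")
  expect_error(lowpass_position(const[1:10, ]), "50 samples")
})

test_that("central differences are exact for polynomial position", {
  t <- seq(0, 400, by = 2)
  lin <- tibble::tibble(t_ms = t, x_deg = 5 * t / 1000, y_deg = 2)
  v <- differentiate(lin)
  inner <- 2:(length(t) - 1)
  expect_equal(v$vx[inner], rep(5, length(inner)), tolerance = 1e-10)
  expect_equal(v$vy, rep(0, length(t)), tolerance = 1e-12)
  # quadratic x = a t^2 / 2 with a = 20 deg/s^2: v = 20 t exactly
  quad <- tibble::tibble(t_ms = t, x_deg = 0.5 * 20 * (t / 1000)^2, y_deg = 0)
  vq <- differentiate(quad)
  expect_equal(vq$vx[inner], 20 * t[inner] / 1000, tolerance = 1e-9)
  expect_error(differentiate(lin[1:2, ]), "3 samples")
})

test_that("velocity projection matches the norm-cosine identity", {
  expect_equal(project_velocity(3, 4, 0), 3)
  expect_equal(project_velocity(0, 4, 90), 4)
  expect_equal(project_velocity(3, 4, atan2(4, 3) * 180 / pi), 5)
  expect_true(is.na(project_velocity(NA, 4, 90)))
  set.seed(2)
  vx <- rnorm(300); vy <- rnorm(300); th <- runif(300, -180, 180)
  ident <- sqrt(vx^2 + vy^2) *
    cospi((atan2(vy, vx) * 180 / pi - th) / 180)
  expect_lt(max(abs(project_velocity(vx, vy, th) - ident)), 1e-10)
})

test_that("saccade masking flags pulses, spares pursuit, never edits data", {
  t <- seq(-200, 1000, by = 2)
  vx <- rep(1, length(t)); vy <- rep(0, length(t))
  pulse <- t >= 300 & t <= 330
  vx2 <- vx; vx2[pulse] <- vx2[pulse] + 200
  vel <- velocity_tibble(t, vx2, vy)
  masked <- detect_and_mask_saccades(vel, speed_threshold = 30, pad_ms = 10)
  expect_true(all(masked$saccade_mask[pulse]))
  # padding extends 10 ms each side, nothing beyond
  expect_true(all(masked$saccade_mask[t >= 290 & t <= 340]))
  expect_false(any(masked$saccade_mask[t < 290 | t > 340]))
  expect_true(all(is.na(masked$vx[masked$saccade_mask])))
  # unmasked samples pass through bit-identically
  expect_identical(masked$vx[!masked$saccade_mask],
                   vel$vx[!masked$saccade_mask])
  ev <- attr(masked, "events")
  expect_equal(nrow(ev), 1)
  # pure pursuit: no masking at all
  clean <- detect_and_mask_saccades(velocity_tibble(t, vx, vy))
  expect_equal(sum(clean$saccade_mask), 0)
  expect_error(detect_and_mask_saccades(vel, speed_threshold = 0),
               "positive")
})

test_that("detector recovers generator ground-truth saccades", {
  obs <- observer_params()  # defaults: rate 2/s, 150 deg/s peak, 30 ms
  d <- make_session_design("unbiased", n_trials = 50)
  tr <- sample_trials(d, 1, seed = 20)
  sim <- simulate_eye_traces(tr, obs, seed = 21)
  guard <- 22  # ms: deliberate padding + filter smear around true events
  res <- sim$traces |>
    dplyr::group_by(trial) |>
    dplyr::group_map(function(trc, g) {
      vel <- detect_and_mask_saccades(differentiate(lowpass_position(trc)))
      sc <- dplyr::filter(sim$saccades, trial == g$trial)
      if (nrow(sc) == 0) return(c(hit = NA, fa = mean(vel$saccade_mask)))
      in_true <- in_guard <- rep(FALSE, nrow(vel))
      for (i in seq_len(nrow(sc))) {
        in_true <- in_true |
          (vel$t_ms >= sc$onset_ms[i] & vel$t_ms <= sc$offset_ms[i])
        in_guard <- in_guard |
          (vel$t_ms >= sc$onset_ms[i] - guard &
             vel$t_ms <= sc$offset_ms[i] + guard)
      }
      c(hit = mean(vel$saccade_mask[in_true]),
        fa = mean(vel$saccade_mask[!in_guard]))
    })
  m <- do.call(rbind, res)
  expect_gte(mean(m[, "hit"], na.rm = TRUE), 0.95)
  expect_lt(mean(m[, "fa"], na.rm = TRUE), 0.02)
})

test_that("anticipation metrics apply the amplitude validity band", {
  t <- seq(-400, 1000, by = 2)
  m1 <- anticipation_metrics(velocity_tibble(t, 1, 0))
  expect_equal(m1$amp, 1)
  expect_equal(m1$angle, 0)
  expect_true(m1$valid)
  # too fast: probable unmarked saccade
  m3 <- anticipation_metrics(velocity_tibble(t, 3, 0))
  expect_equal(m3$amp, 3)
  expect_false(m3$valid)
  # too slow: noise / unstable fixation
  m0 <- anticipation_metrics(velocity_tibble(t, 0.1, 0))
  expect_false(m0$valid)
  # window must sit inside the trace
  short <- velocity_tibble(seq(0, 500, 2), 1, 0)
  expect_error(anticipation_metrics(short), "outside")
  # an all-masked window propagates missingness and invalidates the trial
  vel <- velocity_tibble(t, 1, 0)
  vel$saccade_mask <- vel$t_ms >= -60 & vel$t_ms < 110
  vel$vx[vel$saccade_mask] <- NA
  mm <- anticipation_metrics(vel)
  expect_true(is.na(mm$amp))
  expect_false(mm$valid)
})

test_that("early acceleration follows the two-window formula", {
  t <- seq(-100, 1000, by = 2)
  # means 1 and 3 deg/s -> 20 deg/s^2, forced by the formula
  vx <- ifelse(t < 150, 1, 3)
  expect_equal(early_acceleration(velocity_tibble(t, vx, 0), 0), 20)
  expect_equal(early_acceleration(velocity_tibble(t, 5, 0), 0), 0)
  # linear ramp v = 20 t: window centers are 100 ms apart
  ramp <- velocity_tibble(t, 20 * t / 1000, 0)
  expect_equal(early_acceleration(ramp, 0), 20, tolerance = 1e-9)
  # empty windows give missing
  vel <- velocity_tibble(t, 1, 0)
  vel$vx[t >= 100 & t < 120] <- NA
  expect_true(is.na(early_acceleration(vel, 0)))
})

test_that("steady state projects the mean velocity vector", {
  t <- seq(-100, 1000, by = 2)
  st <- steady_state(velocity_tibble(t, 8, 0), 0)
  expect_equal(st$steady_vproj, 8)
  expect_equal(st$steady_angle, 0)
  orth <- steady_state(velocity_tibble(t, 0, 3), 0)
  expect_equal(orth$steady_vproj, 0)
  expect_equal(orth$steady_angle, 90)
})

test_that("doubling a noise-free trace doubles every kinematic metric", {
  obs <- observer_params(velocity_noise_sd = 0, saccade_rate = 0)
  d <- make_session_design("biased", frequent_direction = 0, n_trials = 16)
  tr <- sample_trials(d, 1, seed = 30)[1, ]
  tr$coherence <- 0.15
  sim <- simulate_eye_traces(tr, obs, seed = 31)
  trace1 <- sim$traces
  trace2 <- dplyr::mutate(trace1, x_deg = 2 * x_deg, y_deg = 2 * y_deg)
  k1 <- extract_kinematics(trace1, tr, anticipation_bounds = c(0, Inf))
  k2 <- extract_kinematics(trace2, tr, anticipation_bounds = c(0, Inf))
  expect_equal(k2$anticipation_amp, 2 * k1$anticipation_amp,
               tolerance = 1e-10)
  expect_equal(k2$accel, 2 * k1$accel, tolerance = 1e-10)
  expect_equal(k2$steady_vproj, 2 * k1$steady_vproj, tolerance = 1e-10)
})

test_that("kinematics recover generator parameters with realistic noise", {
  obs <- observer_params()  # noise sd 0.5, saccades on
  d <- make_session_design("biased", frequent_direction = 0, n_trials = 60)
  tr <- sample_trials(d, 1, seed = 32)
  tr$coherence <- 0.40
  sim <- simulate_eye_traces(tr, obs, seed = 33)
  kin <- extract_kinematics(sim$traces, tr)
  truth <- sim$truth
  expect_lt(abs(mean(kin$anticipation_amp, na.rm = TRUE) -
                  obs$anticipation_gain) / obs$anticipation_gain, 0.10)
  expect_gt(mean(kin$accel, na.rm = TRUE), 0)
  expect_lt(abs(mean(kin$steady_vproj, na.rm = TRUE) - 9) / 9, 0.05)
  expect_lt(abs(mean(kin$accel, na.rm = TRUE) - mean(truth$accel)) /
              mean(truth$accel), 0.10)
})

test_that("angular histograms are normalised and order-invariant", {
  one <- anticipation_histogram(tibble::tibble(a = rep(0, 7)), a)
  expect_equal(one$freq[one$bin_center == 0], 1)
  expect_equal(sum(one$freq), 1)
  set.seed(3)
  ang <- tibble::tibble(a = runif(1e4, -180, 180))
  h <- anticipation_histogram(ang, a)
  expect_equal(sum(h$freq), 1, tolerance = 1e-10)
  expect_true(all(abs(h$freq - 1 / 16) < 0.008))
  hp <- anticipation_histogram(ang[sample(nrow(ang)), ], a)
  expect_equal(h$freq, hp$freq)
  expect_error(anticipation_histogram(tibble::tibble(a = NA_real_), a),
               "no trials")
})
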