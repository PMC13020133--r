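test_that("session designs carry the right direction probabilities", {
  unb <- make_session_design("unbiased")
  expect_equal(unb$n_trials, 480L)
  expect_equal(unb$probabilities$prob, rep(1 / 16, 16))

  for (fd in c(0, -135)) {
    b <- make_session_design("biased", frequent_direction = fd)
    expect_equal(b$n_trials, 474L)
    expect_equal(sum(b$probabilities$prob), 1)
    expect_equal(b$probabilities$prob[b$probabilities$direction == fd], 0.6)
    others <- b$probabilities$prob[b$probabilities$direction != fd]
    expect_equal(others, rep(0.4 / 15, 15))
  }

  expect_error(make_session_design("biased"), "frequent_direction")
  expect_error(make_session_design("biased", frequent_direction = 10),
               "bin centers")
  expect_error(make_session_design("unbiased", frequent_direction = 0),
               "biased")
  expect_error(make_session_design("unbiased", n_trials = 8), "at least")
})

test_that("sampled direction frequencies converge to the design", {
  n <- 1e5
  unb <- make_session_design("unbiased", n_trials = n)
  t1 <- sample_trials(unb, 1, seed = 101)
  p0 <- mean(t1$rdk_dir_deg == 0)
  expect_lt(abs(p0 - 1 / 16), 3 * sqrt(1 / 16 * 15 / 16 / n))
  expect_true(all(t1$rdk_dir_deg %in% direction_bin_centers()))
  expect_true(all(t1$coherence %in% c(0.05, 0.15, 0.40)))
  expect_true(all(t1$fixation_ms >= 500 & t1$fixation_ms <= 1000))

  bia <- make_session_design("biased", frequent_direction = 0, n_trials = n)
  t2 <- sample_trials(bia, 1, seed = 102)
  expect_lt(abs(mean(t2$rdk_dir_deg == 0) - 0.6), 3 * sqrt(0.6 * 0.4 / n))

  # every empirical frequency within 3 binomial SDs of its design value
  emp <- table(factor(t2$rdk_dir_deg, levels = bia$probabilities$direction))
  expect_true(all(abs(as.numeric(emp) / n - bia$probabilities$prob) <
                    3 * sqrt(bia$probabilities$prob *
                               (1 - bia$probabilities$prob) / n) + 1e-12))
})

test_that("balanced sampling hits largest-remainder counts exactly", {
  bia <- make_session_design("biased", frequent_direction = -135,
                             n_trials = 474)
  t3 <- sample_trials(bia, 1, seed = 103, balanced = TRUE,
                      coherence_balanced = TRUE)
  counts <- table(t3$rdk_dir_deg)
  expect_equal(sum(counts), 474)
  expect_equal(unname(counts[names(counts) == "-135"]),
               as.vector(round(0.6 * 474)))
  expect_true(max(abs(table(t3$coherence) - 158)) <= 1)
  # same seed reproduces the same table
  t3b <- sample_trials(bia, 1, seed = 103, balanced = TRUE,
                       coherence_balanced = TRUE)
  expect_identical(t3, t3b)
})

test_that("dot fields obey coherence, speed and aperture rules", {
  f <- simulate_dot_field(30, 1.0, n_frames = 85, seed = 7)
  # forced by the update rule: all dots step along the global direction
  ms <- c(mean(f$steps[, 1, ]), mean(f$steps[, 2, ]))
  expect_lt(abs(circ_diff(atan2(ms[2], ms[1]) * 180 / pi, 30)), 0.5)
  expect_equal(sqrt(sum(ms^2)), 10 / 85, tolerance = 1e-9)

  f0 <- simulate_dot_field(30, 0, n_frames = 85, seed = 8)
  m0 <- c(mean(f0$steps[, 1, ]), mean(f0$steps[, 2, ]))
  expect_lt(sqrt(sum(m0^2)), 0.01)

  fh <- simulate_dot_field(-90, 0.4, n_frames = 40, seed = 9)
  expect_true(all(colSums(fh$signal) == round(0.4 * fh$n_dots)))
  r <- sqrt(fh$positions[, 1, ]^2 + fh$positions[, 2, ]^2)
  expect_true(all(r <= fh$aperture_radius + 1e-9))
  expect_error(simulate_dot_field(0, 0.5, n_frames = 0), "n_frames")
})

test_that("a dot leaving the aperture re-enters from the opposite side", {
  # a radially outward-moving dot at the rim must flip to the far side
  f <- simulate_dot_field(0, 1, n_frames = 2, seed = 10)
  # emulate the wrap rule directly on a rim dot moving outward along +x
  x <- 9.95 + 10 / 85
  d <- abs(x)
  wrapped <- -(2 * f$aperture_radius - d)
  expect_lt(wrapped, 0)                      # opposite side
  expect_lt(abs(wrapped), f$aperture_radius) # inside
  # and the simulator never leaves dots outside (checked above), with
  # wrapped dots appearing at negated coordinates:
  set.seed(11)
  big <- simulate_dot_field(0, 1, n_frames = 85, seed = 11)
  jumps <- big$positions[, 1, -1] - big$positions[, 1, -85]
  expect_true(any(jumps < -10))  # wraps happened right-to-left
})

test_that("the report mixture integrates to 1 and hits known regimes", {
  obs <- observer_params()
  for (fd in list(NULL, 0, -135)) {
    I <- integrate(function(th) guess_density(th, obs, fd), -180, 180,
                   subdivisions = 2000, rel.tol = 1e-9)
    expect_lt(abs(I$value - 1), 1e-6)
  }
  # near-deterministic sensory observer reports the stimulus direction
  sharp <- observer_params(kappa = c(1e7, 1e7, 1e7),
                           w_sensory = c(1, 1, 1), lapse_rate = 0)
  d <- make_session_design("unbiased", n_trials = 200)
  tr <- simulate_reports(sample_trials(d, 1, seed = 1), sharp, seed = 2)
  expect_lt(max(abs(circ_diff(tr$report_dir_deg, tr$rdk_dir_deg))), 0.5)
  expect_true(all(classify_trials(tr)$correct))
})

test_that("uniform guessing yields chance accuracy from bin geometry", {
  n <- 1e4
  d <- make_session_design("unbiased", n_trials = n)
  tr <- simulate_reports(sample_trials(d, 1, seed = 3), uniform_observer(),
                         seed = 4)
  acc <- mean(classify_trials(tr)$correct)
  expect_lt(abs(acc - 22.5 / 360), 3 * sqrt(0.0625 * 0.9375 / n))
})

test_that("accuracy is monotone in sensory concentration", {
  n <- 1e4
  d <- make_session_design("unbiased", n_trials = n)
  base <- sample_trials(d, 1, seed = 5)
  acc <- sapply(seq_along(kappas <- c(0, 1, 2, 4, 8)), function(i) {
    o <- observer_params(kappa = rep(kappas[i], 3), w_sensory = c(1, 1, 1),
                         lapse_rate = 0)
    mean(classify_trials(simulate_reports(base, o, seed = 50 + i))$correct)
  })
  expect_true(all(diff(acc) >= 0))
})

test_that("avoidance suppresses reports near the frequent direction", {
  n <- 1e4
  d <- make_session_design("biased", frequent_direction = 0, n_trials = n)
  base <- sample_trials(d, 1, seed = 6)
  p_near <- sapply(c(0, 1), function(a) {
    o <- guess_observer(avoidance_strength = a)
    rep_a <- simulate_reports(base, o, seed = 7)
    mean(abs(circ_diff(rep_a$report_dir_deg, 0)) <= 11.25)
  })
  expect_lt(p_near[2], p_near[1])
})

test_that("noise-free eye traces are built exactly as specified", {
  obs <- observer_params(velocity_noise_sd = 0, saccade_rate = 0,
                         anticipation_gain = 1, anticipation_spread = 1e-6,
                         pursuit_gain = c(0.8, 0.8, 0.8))
  d <- make_session_design("biased", frequent_direction = 0, n_trials = 16)
  tr <- sample_trials(d, 1, seed = 8)[1, ]
  tr$rdk_dir_deg <- 0
  tr$coherence <- 0.40
  sim <- simulate_eye_traces(tr, obs, seed = 9)
  expect_equal(nrow(sim$saccades), 0)
  # velocity from the returned positions: mean over [-50, 100) is the
  # anticipation gain along the expected direction
  vel <- differentiate(sim$traces[, c("t_ms", "x_deg", "y_deg")])
  sel <- vel$t_ms >= -50 & vel$t_ms < 100
  expect_equal(mean(vel$vx[sel]), 1, tolerance = 1e-3)
  expect_equal(mean(vel$vy[sel]), 0, tolerance = 1e-3)
  # steady state equals gain x 10 deg/s along the stimulus
  sels <- vel$t_ms >= 400 & vel$t_ms < 600
  expect_equal(mean(vel$vx[sels]), 8, tolerance = 1e-3)
  # displacement over the steady window equals the integral of the
  # deterministic velocity (position is the trapezoid integral)
  x4 <- sim$traces$x_deg[sim$traces$t_ms == 400]
  x6 <- sim$traces$x_deg[sim$traces$t_ms == 600]
  expect_equal(x6 - x4, 8 * 0.2, tolerance = 1e-6)
  # 500-Hz grid covering fixation + gap + stimulus
  expect_equal(unique(diff(sim$traces$t_ms)), 2)
  expect_lte(min(sim$traces$t_ms), -(tr$fixation_ms + 300) + 2)
  expect_equal(max(sim$traces$t_ms), 1000)
})

test_that("saccade-free generation reports an empty ground-truth set", {
  obs <- observer_params(saccade_rate = 0)
  d <- make_session_design("unbiased", n_trials = 16)
  tr <- sample_trials(d, 1, seed = 12)[1:3, ]
  sim <- simulate_eye_traces(tr, obs, seed = 13)
  expect_equal(nrow(sim$saccades), 0)
  vel <- sim$traces |>
    dplyr::filter(trial == 1) |>
    lowpass_position() |>
    differentiate() |>
    detect_and_mask_saccades()
  expect_equal(sum(vel$saccade_mask), 0)
})
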