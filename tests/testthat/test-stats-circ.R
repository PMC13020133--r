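test_that("Watson-Williams matches the independent oracle", {
  set.seed(70)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    mus <- runif(k, -180, 180)
    kap <- runif(1, 2, 10)
    groups <- lapply(1:k, function(j) rvonmises(sample(8:25, 1), mus[j], kap))
    df <- tibble::tibble(
      angle = unlist(groups),
      grp = rep(seq_len(k), lengths(groups))
    )
    got <- suppressWarnings(watson_williams(df, angle, grp))
    want <- ww_oracle(groups)
    expect_lt(abs(got$statistic - want$F), 1e-6)
    expect_lt(abs(got$p_value - want$p), 1e-9)
  }
})

test_that("Watson-Williams edge behaviour and diagnostics", {
  d2 <- tibble::tibble(a = rep(c(-10, 0, 10), 2),
                       g = rep(c("x", "y"), each = 3))
  w <- watson_williams(d2, a, g)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)

  set.seed(71)
  sep <- tibble::tibble(a = c(rvonmises(50, 0, 5), rvonmises(50, 90, 5)),
                        g = rep(c("x", "y"), each = 50))
  expect_lt(watson_williams(sep, a, g)$p_value, 1e-6)

  # diffuse data triggers the low-concentration warning
  set.seed(72)
  diffuse <- tibble::tibble(a = runif(60, -180, 180),
                            g = rep(c("x", "y"), each = 30))
  expect_warning(watson_williams(diffuse, a, g), "0.45")

  tiny <- tibble::tibble(a = c(0, 10, 20), g = c("x", "x", "y"))
  expect_error(watson_williams(tiny, a, g), "at least 2")
  # a group of exactly opposed angles has zero resultant
  degen <- tibble::tibble(a = c(0, 180, 10, 20), g = c("x", "x", "y", "y"))
  expect_error(watson_williams(degen, a, g), "zero resultant")
})

test_that("Watson-Williams keeps its nominal size under the null", {
  set.seed(73)
  n_rep <- 400
  rej <- mean(replicate(n_rep, {
    df <- tibble::tibble(a = rvonmises(60, 0, 3),
                         g = rep(c("x", "y"), each = 30))
    watson_williams(df, a, g)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("serial-dependence binning follows the wrap-then-bin rule", {
  # direction 10 after 350: difference +20, assigned to the 22.5 bin
  expect_equal(circ_diff(10, 350), 20)
  expect_equal(bin_direction(circ_diff(10, 350)), 22.5)
})

test_that("serial-dependence recovers an injected attraction bias", {
  set.seed(74)
  n_subj <- 8; n_tr <- 300
  d <- purrr::map_dfr(seq_len(n_subj), function(s) {
    tibble::tibble(subject_id = s, trial = seq_len(n_tr),
                   rdk_dir_deg = sample(direction_bin_centers(), n_tr,
                                        replace = TRUE))
  })
  d <- dplyr::mutate(dplyr::group_by(d, subject_id),
                     prev = dplyr::lag(rdk_dir_deg))
  d <- dplyr::ungroup(d)
  d$delta <- rnorm(nrow(d), 0, 15)
  near <- !is.na(d$prev) & abs(circ_diff(d$rdk_dir_deg, d$prev)) <= 45
  # pull the report toward the previous direction: delta (stimulus minus
  # report) moves with the sign of the direction change
  d$delta[near] <- d$delta[near] +
    10 * sign(circ_diff(d$rdk_dir_deg, d$prev))[near]
  sc <- serial_dependence_curve(d)
  expect_lt(sc$ww$p_value, 0.01)
  m <- sc$curve
  expect_gt(m$mean_delta[m$bin == 22.5], 3)
  expect_lt(m$mean_delta[m$bin == -22.5], -3)
  expect_true(all(is.finite(m$sem)))
})

test_that("serial-dependence curve is flat without history dependence", {
  set.seed(75)
  n_subj <- 8; n_tr <- 400
  d <- purrr::map_dfr(seq_len(n_subj), function(s) {
    tibble::tibble(subject_id = s, trial = seq_len(n_tr),
                   rdk_dir_deg = sample(direction_bin_centers(), n_tr,
                                        replace = TRUE),
                   delta = rnorm(n_tr, 0, 15))
  })
  sc <- serial_dependence_curve(d)
  expect_lt(max(abs(sc$curve$mean_delta)), 5)
  tiny <- tibble::tibble(subject_id = 1, trial = 1, rdk_dir_deg = 0,
                         delta = 0)
  expect_error(serial_dependence_curve(tiny), "at least 2")
})

test_that("angle correlation behaves across signal regimes", {
  set.seed(76)
  a <- circ_wrap(rvonmises(1000, 20, 2))
  ident <- angle_report_correlation(tibble::tibble(a = a, b = a), a, b)
  expect_equal(ident$r, 1, tolerance = 1e-12)
  # independent angles
  big <- tibble::tibble(a = runif(1e4, -180, 180), b = runif(1e4, -180, 180))
  expect_lt(abs(angle_report_correlation(big, a, b)$r), 0.03)
  # noisy copy
  noisy <- tibble::tibble(a = a, b = circ_wrap(a + rvonmises(1000, 0, 4)))
  expect_gt(angle_report_correlation(noisy, a, b)$r, 0.5)
  few <- tibble::tibble(a = 1:5, b = 1:5)
  expect_error(angle_report_correlation(few, a, b), "at least 10")
  const <- tibble::tibble(a = rep(0, 20), b = runif(20, -180, 180))
  expect_error(angle_report_correlation(const, a, b), "degenerate")
})

test_that("paired comparison handles regular and degenerate input", {
  x <- c(1.2, 0.8, 1.5, 1.1, 0.9, 1.3)
  same <- paired_comparison(x, x)
  expect_true(same$degenerate)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$cohens_d, 0)
  expect_error(paired_comparison(x, x + 1), "zero-variance")
  expect_error(paired_comparison(x[1:2], x[1:2] * 2), "at least 3")
  set.seed(77)
  pc <- paired_comparison(rnorm(21, 1.5), rnorm(21, 1.0))
  expect_true(is.finite(pc$t) && is.finite(pc$wilcoxon_p) &&
                is.finite(pc$shapiro_p))
  expect_equal(pc$df, 20)
})

test_that("Cohen's d estimate is unbiased at the simulated effect size", {
  set.seed(78)
  n_rep <- 400
  dhat <- replicate(n_rep, {
    diff <- rnorm(21, 0.5, 1)
    paired_comparison(diff, rep(0, 21))$cohens_d
  })
  # small-sample bias of d is ~ +3/(4n-5) ~ 0.005; well inside tolerance
  expect_lt(abs(mean(dhat) - 0.5), 0.05)
})
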