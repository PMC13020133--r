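# Independent oracles used to cross-check package computations.  These
# are deliberately standalone scalar transcriptions of textbook formulas,
# sharing no code with the package internals.

# Watson-Williams circular ANOVA, written directly from the classical
# formulas: per-group resultant lengths, pooled within-group resultant,
# Fisher's A1-inverse for kappa, and the 1 + 3/(8 kappa) corrected F.
ww_oracle <- function(groups) {
  to_rad <- function(g) g * pi / 180
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  R_i <- vapply(groups, function(g) {
    sqrt(sum(cos(to_rad(g)))^2 + sum(sin(to_rad(g)))^2)
  }, numeric(1))
  all_ang <- to_rad(unlist(groups))
  R <- sqrt(sum(cos(all_ang))^2 + sum(sin(all_ang))^2)
  rw <- sum(R_i) / N
  kappa <- if (rw < 0.53) {
    2 * rw + rw^3 + 5 * rw^5 / 6
  } else if (rw < 0.85) {
    -0.4 + 1.39 * rw + 0.43 / (1 - rw)
  } else {
    1 / (rw^3 - 4 * rw^2 + 3 * rw)
  }
  Fstat <- (1 + 3 / (8 * kappa)) *
    ((N - k) * (sum(R_i) - R)) / ((k - 1) * (N - sum(R_i)))
  list(F = Fstat,
       p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

# Amplitude gain of a zero-phase (two-pass) digital Butterworth low-pass
# of the given order, from the prewarped analog prototype: one pass has
# power gain 1 / (1 + r^(2 order)) with r the warped frequency ratio, so
# the forward-backward filter has amplitude gain equal to that power.
filtfilt_gain_oracle <- function(f_hz, cutoff_hz, fs, order = 2) {
  r <- tan(pi * f_hz / fs) / tan(pi * cutoff_hz / fs)
  1 / (1 + r^(2 * order))
}

# Amplitude of a sinusoidal component at frequency f in a sampled signal,
# by least squares on a sin/cos basis.
fit_sine_amplitude <- function(t_s, x, f_hz) {
  X <- cbind(sin(2 * pi * f_hz * t_s), cos(2 * pi * f_hz * t_s))
  b <- stats::coef(stats::lm(x ~ X))
  sqrt(b[2]^2 + b[3]^2)
}
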