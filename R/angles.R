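#' Wrap angles onto the half-open interval (-180, 180]
#'
#' All angles in the package live on `(-180, 180]` degrees, with 0 =
#' rightward motion and positive values running clockwise (downward on the
#' screen).  The representative is unique: both -180 and 540 map to 180.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped to `(-180, 180]`.
#' @examples
#' circ_wrap(c(340, 180, -190))
#' @export
circ_wrap <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

#' Signed shortest-arc difference between two angles
#'
#' Computes `a - b` on the circle, wrapped to `(-180, 180]`, so that the
#' difference between 350 and 10 degrees is 20, not 340.  Antisymmetric up
#' to the +180 boundary (both `circ_diff(0, 180)` and `circ_diff(180, 0)`
#' are +180 by the half-open convention).
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Signed difference in degrees on `(-180, 180]`.
#' @examples
#' circ_diff(350, 10)   # 20, not 340
#' @export
circ_diff <- function(a, b) {
  circ_wrap(a - b)
}

#' Direction bins of the stimulus space
#'
#' The 16 motion-direction bins used throughout: centers spaced 22.5
#' degrees apart on `(-180, 180]`, each bin a half-open interval
#' `[center - 11.25, center + 11.25)`.  Cardinal centers are 0, +/-90 and
#' 180; the upper hemifield holds the strictly negative centers and the
#' lower the strictly positive ones, with 0 and 180 belonging to neither.
#'
#' @param n_bins Number of bins tiling the circle (default 16).
#' @return A tibble with columns `bin_center`, `cardinal` (logical) and
#'   `hemifield` (`"upper"`, `"lower"` or `"boundary"`).
#' @examples
#' direction_bins()
#' @export
direction_bins <- function(n_bins = 16) {
  centers <- direction_bin_centers(n_bins)
  tibble::tibble(
    bin_center = centers,
    cardinal = centers %in% c(0, -90, 90, 180),
    hemifield = dplyr::case_when(
      centers < 0 & centers > -180 ~ "upper",
      centers > 0 & centers < 180 ~ "lower",
      TRUE ~ "boundary"
    )
  )
}

#' @rdname direction_bins
#' @export
direction_bin_centers <- function(n_bins = 16) {
  sort(circ_wrap(seq(0, 360 - 360 / n_bins, by = 360 / n_bins)))
}

#' Assign angles to direction-bin centers
#'
#' Maps each angle to the center of the half-open bin
#' `[center - width/2, center + width/2)` containing it.
#'
#' @param x Numeric vector of angles in degrees.
#' @param n_bins Number of bins tiling the circle (default 16).
#' @return Vector of bin centers on `(-180, 180]`.
#' @examples
#' bin_direction(c(-11.25, 11.25, 179))
#' @export
bin_direction <- function(x, n_bins = 16) {
  width <- 360 / n_bins
  circ_wrap(width * floor((circ_wrap(x) + width / 2) / width))
}

#' Circular mean and resultant length
#'
#' @param x Angles in degrees.
#' @param na.rm Drop missing values first?
#' @return `circ_mean()` returns the mean direction in degrees on
#'   `(-180, 180]`; `circ_r()` the mean resultant length in `[0, 1]`.
#' @export
circ_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  circ_wrap(atan2(mean(sinpi(x / 180)), mean(cospi(x / 180))) * 180 / pi)
}

#' @rdname circ_mean
#' @export
circ_r <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean(cospi(x / 180))^2 + mean(sinpi(x / 180))^2)
}

#' von Mises density on degrees
#'
#' Density of the von Mises distribution expressed per degree, so that it
#' integrates to 1 over any 360-degree interval.  `kappa = 0` gives the
#' uniform density 1/360.  Stable for large `kappa` (uses the
#' exponentially scaled Bessel function).
#'
#' @param x Angles in degrees.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration parameter (>= 0).
#' @return Density values per degree.
#' @export
dvonmises <- function(x, mu, kappa) {
  stopifnot(kappa >= 0)
  exp(kappa * (cospi((x - mu) / 180) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE)) * pi / 180
}

#' Draw from a von Mises distribution (degrees)
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to the uniform
#' distribution on `(-180, 180]`.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (>= 0).
#' @return `n` angles in degrees on `(-180, 180]`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) {
    return(circ_wrap(stats::runif(n, -180, 180)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    m <- length(need)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      u3 <- stats::runif(sum(ok))
      theta <- sign(u3 - 0.5) * acos(f[ok]) * 180 / pi
      out[need[ok]] <- theta
      need <- need[!ok]
    }
  }
  circ_wrap(mu + out)
}

# Derive a reproducible child seed from a parent seed and an index, kept
# below 2^31 so it is a valid R integer.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 100003 * 20011 + i * 7919) %% 2147483647)
}

# Evaluate code under a temporary RNG seed (or as-is when seed is NULL).
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
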