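#' Simulate a random-dot kinematogram dot field
#'
#' Dots live in a circular aperture (10 deg radius by default) at a
#' density of 1.5 dots per square degree (~470 dots) and move at
#' 10 deg/s, i.e. `speed / frame_rate` degrees per frame at 85 Hz.
#' Signal/noise labels are reshuffled every `block_frames` frames (4
#' frames = 47 ms): in each block, `round(coherence * n_dots)` dots are
#' signal and step along the global direction while every noise dot gets
#' its own fresh random direction for the whole block.  A dot stepping
#' outside the aperture re-enters from the diametrically opposite side.
#'
#' @param rdk_dir Global motion direction in degrees.
#' @param coherence Fraction of signal dots in `[0, 1]`.
#' @param n_frames Number of frames to simulate (default 85, i.e. 1 s).
#' @param seed Optional integer seed.
#' @param density Dot density in dots per square degree.
#' @param aperture_radius Aperture radius in degrees.
#' @param dot_speed Dot speed in deg/s.
#' @param frame_rate Display refresh rate in Hz.
#' @param block_frames Frames per label-reshuffle block.
#' @param dot_diameter Dot diameter in degrees (metadata only).
#' @return An object of class `dot_field`: a list with `positions`
#'   (`n_dots` x 2 x `n_frames` array), `steps` (the applied per-frame
#'   motion vectors before wrapping, `n_dots` x 2 x `n_frames - 1`),
#'   `signal` (logical `n_dots` x `n_blocks` matrix) and the stimulus
#'   parameters.
#' @export
simulate_dot_field <- function(rdk_dir, coherence, n_frames = 85,
                               seed = NULL, density = 1.5,
                               aperture_radius = 10, dot_speed = 10,
                               frame_rate = 85, block_frames = 4,
                               dot_diameter = 0.14) {
  stopifnot(coherence >= 0, coherence <= 1)
  if (n_frames <= 0) stop("`n_frames` must be positive", call. = FALSE)
  n_dots <- rdk_dot_count(density, aperture_radius)
  step_len <- dot_speed / frame_rate
  n_blocks <- ceiling((n_frames - 1) / block_frames)
  with_seed_or_not(seed, {
    # uniform positions in the disc
    r <- aperture_radius * sqrt(stats::runif(n_dots))
    phi <- stats::runif(n_dots, 0, 2 * pi)
    pos <- array(NA_real_, c(n_dots, 2, n_frames))
    steps <- array(NA_real_, c(n_dots, 2, max(n_frames - 1, 1)))
    pos[, 1, 1] <- r * cos(phi)
    pos[, 2, 1] <- r * sin(phi)
    signal <- matrix(FALSE, n_dots, max(n_blocks, 1))
    n_signal <- round(coherence * n_dots)
    for (b in seq_len(n_blocks)) {
      signal[sample.int(n_dots, n_signal), b] <- TRUE
      noise_dir <- stats::runif(n_dots, -180, 180)  # per-dot, fixed in block
      dir <- ifelse(signal[, b], rdk_dir, noise_dir)
      dx <- step_len * cospi(dir / 180)
      dy <- step_len * sinpi(dir / 180)
      frames <- intersect(((b - 1) * block_frames + 1):(b * block_frames),
                          seq_len(n_frames - 1))
      for (f in frames) {
        steps[, 1, f] <- dx
        steps[, 2, f] <- dy
        x <- pos[, 1, f] + dx
        y <- pos[, 2, f] + dy
        out <- sqrt(x^2 + y^2) > aperture_radius
        if (any(out)) {
          # re-enter from the opposite side, same distance inside the rim
          d <- sqrt(x[out]^2 + y[out]^2)
          scale <- -(2 * aperture_radius - d) / d
          x[out] <- x[out] * scale
          y[out] <- y[out] * scale
        }
        pos[, 1, f + 1] <- x
        pos[, 2, f + 1] <- y
      }
    }
    structure(
      list(positions = pos, steps = steps, signal = signal,
           rdk_dir = circ_wrap(rdk_dir), coherence = coherence,
           n_dots = n_dots, aperture_radius = aperture_radius,
           dot_speed = dot_speed, frame_rate = frame_rate,
           block_frames = block_frames, dot_diameter = dot_diameter),
      class = "dot_field"
    )
  })
}

#' Design constants of the RDK stimulus
#'
#' Helpers recomputing the stimulus constants from first principles:
#' the number of dots implied by density and aperture area, and the
#' label-reshuffle lifetime implied by the block length and refresh rate.
#'
#' @param density Dots per square degree.
#' @param aperture_radius Aperture radius in degrees.
#' @param block_frames Frames per label block.
#' @param frame_rate Refresh rate in Hz.
#' @return `rdk_dot_count()`: integer dot count;
#'   `rdk_block_lifetime_ms()`: block duration in ms.
#' @examples
#' rdk_dot_count()          # ~470
#' rdk_block_lifetime_ms()  # ~47 ms
#' @export
rdk_dot_count <- function(density = 1.5, aperture_radius = 10) {
  as.integer(round(density * pi * aperture_radius^2))
}

#' @rdname rdk_dot_count
#' @export
rdk_block_lifetime_ms <- function(block_frames = 4, frame_rate = 85) {
  block_frames / frame_rate * 1000
}
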