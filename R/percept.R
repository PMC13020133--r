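# --- circular classification of perceptual reports --------------------------

#' Classify perceptual reports against the stimulus direction
#'
#' Adds to the trial table the signed angular error
#' `delta = circ_diff(rdk, report)` and a three-way label: `correct` when
#' the report falls in the half-open bin `[rdk - 11.25, rdk + 11.25)`,
#' `opposite` when it falls in the same bin around `rdk + 180`, and
#' `general` otherwise.  Each response is also assigned to its direction
#' bin (`response_bin`), and error trials receive the per-trial cardinal
#' and hemifield bias scores (`NA` on correct trials, where the scores
#' are undefined).
#'
#' The half-open bins tile the circle exactly once, so every
#' (stimulus, report) pair receives exactly one label.
#'
#' @param trials Trial tibble with stimulus and report columns.
#' @param rdk,report Columns holding the stimulus and reported directions
#'   in degrees (tidy-eval; defaults `rdk_dir_deg`, `report_dir_deg`).
#' @param n_bins Number of direction bins (default 16; bin half-width
#'   `180 / n_bins` degrees).
#' @return The input tibble with `delta`, `label`, `response_bin`,
#'   `correct` (logical), `cardinal_score`, `hemifield_score` added.
#' @examples
#' classify_trials(tibble::tibble(rdk_dir_deg = 0,
#'                                report_dir_deg = c(5, 178, 90)))
#' @export
classify_trials <- function(trials, rdk = rdk_dir_deg,
                            report = report_dir_deg, n_bins = 16) {
  rdk_v <- dplyr::pull(trials, {{ rdk }})
  rep_v <- dplyr::pull(trials, {{ report }})
  half <- 180 / n_bins
  d_resp <- circ_diff(rep_v, rdk_v)
  d_opp <- circ_diff(rep_v, rdk_v + 180)
  correct <- d_resp >= -half & d_resp < half
  opposite <- !correct & d_opp >= -half & d_opp < half
  label <- dplyr::case_when(
    correct ~ "correct",
    opposite ~ "opposite",
    TRUE ~ "general"
  )
  bin <- bin_direction(rep_v, n_bins)
  trials$delta <- circ_diff(rdk_v, rep_v)
  trials$label <- factor(label, levels = c("correct", "opposite", "general"))
  trials$response_bin <- bin
  trials$correct <- correct
  trials$cardinal_score <- ifelse(correct, NA_real_, cardinal_score(bin, n_bins))
  trials$hemifield_score <- ifelse(correct, NA_real_,
                                   hemifield_score(bin, n_bins))
  trials
}

#' Classify a single stimulus/report pair
#'
#' Scalar-friendly wrapper around [classify_trials()].
#'
#' @param rdk_dir,report_dir Angles in degrees.
#' @param n_bins Number of direction bins.
#' @return One-row tibble with `delta`, `label`, `response_bin` and the
#'   bias scores.
#' @export
classify_response <- function(rdk_dir, report_dir, n_bins = 16) {
  out <- classify_trials(
    tibble::tibble(rdk_dir_deg = rdk_dir, report_dir_deg = report_dir),
    n_bins = n_bins
  )
  dplyr::select(out, -"rdk_dir_deg", -"report_dir_deg")
}

#' Per-trial cardinal bias score
#'
#' For an error trial whose response fell in `response_bin`: `+1/4` if
#' the bin is cardinal (0, +/-90, 180), `-1/12` otherwise, i.e. the
#' per-trial normalised difference between cardinal and non-cardinal
#' error fractions (4 cardinal vs. 12 non-cardinal bins).  Under uniform
#' guessing the expected score is 0.
#'
#' @param response_bin Direction-bin centers in degrees.
#' @param n_bins Number of bins.
#' @return Numeric scores.
#' @export
cardinal_score <- function(response_bin, n_bins = 16) {
  check_bin_center(response_bin, n_bins)
  n_card <- 4
  ifelse(response_bin %in% c(0, -90, 90, 180),
         1 / n_card, -1 / (n_bins - n_card))
}

#' Per-trial hemifield bias score
#'
#' `+1/7` when the response bin lies strictly in the upper hemifield
#' (negative centers), `-1/7` strictly in the lower (positive centers),
#' and 0 for the boundary bins 0 and 180, which belong to neither
#' hemifield (7 bins per hemifield).
#'
#' @inheritParams cardinal_score
#' @return Numeric scores.
#' @export
hemifield_score <- function(response_bin, n_bins = 16) {
  check_bin_center(response_bin, n_bins)
  n_hemi <- (n_bins - 2) / 2
  dplyr::case_when(
    response_bin < 0 & response_bin > -180 ~ 1 / n_hemi,
    response_bin > 0 & response_bin < 180 ~ -1 / n_hemi,
    TRUE ~ 0
  )
}

check_bin_center <- function(x, n_bins) {
  centers <- direction_bin_centers(n_bins)
  bad <- !is.na(x) & !(circ_wrap(x) %in% centers)
  if (any(bad)) {
    stop("`response_bin` values must be direction-bin centers", call. = FALSE)
  }
  invisible(x)
}

#' Direction-choice histogram of error trials
#'
#' Normalised 16-bin histogram of the response bins among error
#' (non-correct) trials, optionally restricted to a subset of coherence
#' levels (the low-reliability analysis pools 5% and 15%).
#'
#' @param classified Output of [classify_trials()].
#' @param coherences Optional coherence levels to keep before pooling.
#' @param n_bins Number of direction bins.
#' @return An `angular_histogram` tibble (`bin_center`, `freq`).
#' @export
choice_histogram <- function(classified, coherences = NULL, n_bins = 16) {
  stopifnot("label" %in% names(classified))
  err <- dplyr::filter(classified, .data$label != "correct")
  if (!is.null(coherences)) {
    err <- dplyr::filter(err, .data$coherence %in% coherences)
  }
  if (nrow(err) == 0) stop("no error trials to histogram", call. = FALSE)
  anticipation_histogram(err, response_bin, n_bins = n_bins)
}
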