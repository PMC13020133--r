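#' Build a session design
#'
#' A session is defined by the probability distribution of the 16 global
#' motion directions.  In an unbiased session every direction has
#' probability 1/16; in a biased session one "frequent" direction carries
#' `frequent_share` (default 0.60) of the trials and the remaining mass is
#' split evenly over the other 15 directions.
#'
#' @param session_kind `"unbiased"` or `"biased"`.
#' @param frequent_direction Frequent direction in degrees (must be one of
#'   the 16 bin centers).  Required for, and only allowed in, biased
#'   sessions.
#' @param n_trials Number of trials; defaults to 480 (unbiased) or 474
#'   (biased).
#' @param frequent_share Probability of the frequent direction in a biased
#'   session (default 0.6).
#' @param coherence_levels Set of signal-dot coherence levels.
#' @param n_directions Number of motion directions (default 16).
#' @return An object of class `session_design`: a list with the design
#'   parameters and a `probabilities` tibble (`direction`, `prob`).
#' @examples
#' make_session_design("biased", frequent_direction = -135)
#' @export
make_session_design <- function(session_kind = c("unbiased", "biased"),
                                frequent_direction = NULL,
                                n_trials = NULL,
                                frequent_share = 0.6,
                                coherence_levels = c(0.05, 0.15, 0.40),
                                n_directions = 16) {
  session_kind <- match.arg(session_kind)
  centers <- direction_bin_centers(n_directions)
  if (session_kind == "biased") {
    if (is.null(frequent_direction)) {
      stop("a biased design requires `frequent_direction`", call. = FALSE)
    }
    frequent_direction <- circ_wrap(frequent_direction)
    if (!any(abs(circ_diff(frequent_direction, centers)) < 1e-9)) {
      stop("`frequent_direction` must be one of the direction-bin centers",
           call. = FALSE)
    }
    stopifnot(frequent_share > 0, frequent_share < 1)
  } else if (!is.null(frequent_direction)) {
    stop("`frequent_direction` is only meaningful in a biased design",
         call. = FALSE)
  }
  if (is.null(n_trials)) {
    n_trials <- if (session_kind == "unbiased") 480L else 474L
  }
  if (n_trials < n_directions) {
    stop("`n_trials` must be at least the number of directions", call. = FALSE)
  }
  prob <- if (session_kind == "unbiased") {
    rep(1 / n_directions, n_directions)
  } else {
    ifelse(abs(circ_diff(centers, frequent_direction)) < 1e-9,
           frequent_share,
           (1 - frequent_share) / (n_directions - 1))
  }
  structure(
    list(
      session_kind = session_kind,
      frequent_direction = if (session_kind == "biased") frequent_direction else NA_real_,
      n_trials = as.integer(n_trials),
      frequent_share = if (session_kind == "biased") frequent_share else NA_real_,
      coherence_levels = coherence_levels,
      probabilities = tibble::tibble(direction = centers, prob = prob),
      label = if (session_kind == "unbiased") "unbiased"
              else sprintf("biased_%g", frequent_direction)
    ),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat("<session_design>", x$label, "-", x$n_trials, "trials\n")
  if (x$session_kind == "biased") {
    cat("  frequent direction:", x$frequent_direction, "deg, share",
        x$frequent_share, "\n")
  }
  cat("  coherence levels:", paste(x$coherence_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Sample a trial table from a session design
#'
#' Draws per-subject trial sequences: motion directions i.i.d. from the
#' design probabilities (or with fixed counts closest to the proportions
#' when `balanced = TRUE`, using largest-remainder rounding) and coherence
#' i.i.d. uniform over the coherence levels (or balanced counts when
#' `coherence_balanced = TRUE`).  Fixation duration is uniform on
#' 500-1000 ms, followed by a fixed 300-ms gap and a 1000-ms stimulus.
#'
#' @param design A [make_session_design()] object.
#' @param n_subjects Number of simulated subjects.
#' @param seed Optional integer seed; per-subject substreams are derived
#'   from it so any subject is reproducible in isolation.
#' @param balanced Use fixed per-direction counts instead of i.i.d. draws.
#' @param coherence_balanced Balance coherence counts instead of i.i.d.
#' @param subject_ids Optional character vector of subject labels.
#' @return A tibble with one row per trial: `subject_id`, `session`,
#'   `frequent_dir_deg`, `trial`, `rdk_dir_deg`, `coherence`,
#'   `fixation_ms`, `gap_ms`, `stim_ms`, `report_dir_deg` (NA until a
#'   report is simulated or observed).
#' @examples
#' d <- make_session_design("unbiased", n_trials = 32)
#' sample_trials(d, n_subjects = 2, seed = 1)
#' @export
sample_trials <- function(design, n_subjects = 1, seed = NULL,
                          balanced = FALSE, coherence_balanced = FALSE,
                          subject_ids = NULL) {
  stopifnot(inherits(design, "session_design"))
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("S%02d", seq_len(n_subjects))
  }
  stopifnot(length(subject_ids) == n_subjects)
  one_subject <- function(s) {
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, s)
    with_seed_or_not(sub_seed, {
      n <- design$n_trials
      dirs <- if (balanced) {
        counts <- largest_remainder(design$probabilities$prob * n)
        sample(rep(design$probabilities$direction, counts))
      } else {
        sample(design$probabilities$direction, n, replace = TRUE,
               prob = design$probabilities$prob)
      }
      coh <- if (coherence_balanced) {
        counts <- largest_remainder(rep(n / length(design$coherence_levels),
                                        length(design$coherence_levels)))
        sample(rep(design$coherence_levels, counts))
      } else {
        sample(design$coherence_levels, n, replace = TRUE)
      }
      tibble::tibble(
        subject_id = subject_ids[s],
        session = design$label,
        frequent_dir_deg = design$frequent_direction,
        trial = seq_len(n),
        rdk_dir_deg = dirs,
        coherence = coh,
        fixation_ms = stats::runif(n, 500, 1000),
        gap_ms = 300,
        stim_ms = 1000,
        report_dir_deg = NA_real_
      )
    })
  }
  purrr::list_rbind(purrr::map(seq_len(n_subjects), one_subject))
}

# Integer counts summing to round(sum(x)), proportional to x, by
# largest-remainder (Hare) rounding.
largest_remainder <- function(x) {
  total <- round(sum(x))
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
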