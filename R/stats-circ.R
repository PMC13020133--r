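# --- circular inference ------------------------------------------------------

# Fisher's approximate inverse of A(kappa) = I1/I0, used for the
# Watson-Williams concentration correction.
a1inv <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equal mean directions
#'
#' Classical circular one-way ANOVA comparing the mean directions of two
#' or more groups of angles: the F statistic on resultant lengths with
#' the standard `1 + 3 / (8 kappa)` concentration correction, `kappa`
#' estimated from the pooled within-group mean resultant length via
#' Fisher's A1-inverse.  A warning is issued when the pooled resultant
#' length is below 0.45, where the test's assumptions are doubtful.
#'
#' @param data Data frame with one row per observation.
#' @param angle Column of angles in degrees (tidy-eval).
#' @param group Grouping column (2 or more levels, each with >= 2
#'   observations).
#' @return An object of class `watson_williams`: `statistic` (F), `df1`,
#'   `df2`, `p_value`, `correction`, `kappa`, `r_within`, and a
#'   per-group summary tibble.
#' @examples
#' d <- tibble::tibble(angle = c(-10, 0, 10, 80, 90, 100),
#'                     grp = rep(c("a", "b"), each = 3))
#' watson_williams(d, angle, grp)
#' @export
watson_williams <- function(data, angle, group) {
  ang <- dplyr::pull(data, {{ angle }})
  grp <- dplyr::pull(data, {{ group }})
  ok <- !is.na(ang) & !is.na(grp)
  ang <- ang[ok]; grp <- as.character(grp[ok])
  groups <- split(ang, grp)
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  n <- lengths(groups)
  N <- sum(n)
  res <- function(g) {
    cx <- sum(cospi(g / 180)); sy <- sum(sinpi(g / 180))
    sqrt(cx^2 + sy^2)
  }
  R_i <- vapply(groups, res, numeric(1))
  if (any(R_i < 1e-12)) {
    stop("a group has zero resultant length; mean direction undefined",
         call. = FALSE)
  }
  R <- res(ang)
  r_within <- sum(R_i) / N
  if (r_within < 0.45) {
    warning("pooled mean resultant length ", signif(r_within, 3),
            " < 0.45: Watson-Williams assumptions are doubtful",
            call. = FALSE)
  }
  kappa <- a1inv(r_within)
  correction <- 1 + 3 / (8 * kappa)
  f_stat <- correction * ((N - k) * (sum(R_i) - R)) /
    ((k - 1) * (N - sum(R_i)))
  f_stat <- max(f_stat, 0)
  structure(
    list(
      statistic = f_stat, df1 = k - 1, df2 = N - k,
      p_value = stats::pf(f_stat, k - 1, N - k, lower.tail = FALSE),
      correction = correction, kappa = kappa, r_within = r_within,
      groups = tibble::tibble(
        group = names(groups), n = as.integer(n),
        mean_direction = vapply(groups, circ_mean, numeric(1)),
        resultant_length = R_i / n
      )
    ),
    class = "watson_williams"
  )
}

#' @export
print.watson_williams <- function(x, ...) {
  cat("Watson-Williams circular ANOVA\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g  (correction %.4g)\n",
              x$df1, x$df2, x$statistic, x$p_value, x$correction))
  invisible(x)
}

#' Serial-dependence curve of angular error
#'
#' Within each subject (and optional block), trials are put in
#' presentation order; the direction change between consecutive trials,
#' `rdk_diff = circ_diff(dir_n, dir_n-1)`, is binned into 22.5-degree
#' steps (first trial of each block dropped), and the circular mean of
#' the signed angular error `delta` is computed per subject and bin.
#' The group curve is the per-bin circular mean of the subject means with
#' a between-subject SEM, and a Watson-Williams test asks whether the
#' mean error direction varies across `rdk_diff` bins.
#'
#' @param data Classified trial tibble (needs `delta`).
#' @param direction,error,subject,order Columns holding the stimulus
#'   direction, signed error, subject id and presentation order
#'   (tidy-eval; defaults `rdk_dir_deg`, `delta`, `subject_id`, `trial`).
#' @param block Optional column (e.g. session) within which trial order
#'   is meaningful; consecutive-trial pairs never straddle blocks.
#' @param n_bins Number of `rdk_diff` bins.
#' @param min_subjects_per_bin Bins represented by fewer subjects are
#'   dropped from the Watson-Williams comparison (still shown in the
#'   curve).
#' @return An object of class `serial_curve`: `curve` (per-bin group
#'   mean, SEM, n), `subject_means`, and `ww` (the [watson_williams()]
#'   result).
#' @export
serial_dependence_curve <- function(data, direction = rdk_dir_deg,
                                    error = delta, subject = subject_id,
                                    order = trial, block = NULL,
                                    n_bins = 16,
                                    min_subjects_per_bin = 2) {
  df <- tibble::tibble(
    dir = dplyr::pull(data, {{ direction }}),
    delta = dplyr::pull(data, {{ error }}),
    subject = as.character(dplyr::pull(data, {{ subject }})),
    ord = dplyr::pull(data, {{ order }})
  )
  blk <- rlang::enquo(block)
  df$block <- if (rlang::quo_is_null(blk)) "all" else {
    as.character(dplyr::pull(data, !!blk))
  }
  df <- dplyr::arrange(df, .data$subject, .data$block, .data$ord)
  df <- dplyr::group_by(df, .data$subject, .data$block)
  if (any(dplyr::group_size(df) < 2)) {
    stop("every subject (x block) needs at least 2 ordered trials",
         call. = FALSE)
  }
  df <- dplyr::mutate(df, prev_dir = dplyr::lag(.data$dir))
  df <- dplyr::ungroup(df)
  df <- dplyr::filter(df, !is.na(.data$prev_dir), !is.na(.data$delta))
  df$rdk_diff <- circ_diff(df$dir, df$prev_dir)
  df$bin <- bin_direction(df$rdk_diff, n_bins)
  subj_means <- dplyr::summarise(
    dplyr::group_by(df, .data$subject, .data$bin),
    mean_delta = circ_mean(.data$delta), n_trials = dplyr::n(),
    .groups = "drop"
  )
  curve <- dplyr::summarise(
    dplyr::group_by(subj_means, .data$bin),
    group_mean = circ_mean(.data$mean_delta),
    sem = stats::sd(circ_diff(.data$mean_delta, .data$group_mean)) /
      sqrt(dplyr::n()),
    n_subjects = dplyr::n(),
    .groups = "drop"
  )
  curve <- dplyr::rename(curve, mean_delta = "group_mean")
  ww_data <- dplyr::filter(
    subj_means,
    .data$bin %in% curve$bin[curve$n_subjects >= min_subjects_per_bin]
  )
  ww <- watson_williams(ww_data, mean_delta, bin)
  structure(
    list(curve = dplyr::arrange(curve, .data$bin),
         subject_means = subj_means, ww = ww, n_bins = n_bins),
    class = "serial_curve"
  )
}

#' @export
print.serial_curve <- function(x, ...) {
  cat("<serial_curve> ", nrow(x$curve), " direction-change bins\n", sep = "")
  cat(sprintf("  Watson-Williams across bins: F(%d, %d) = %.3g, p = %.3g\n",
              x$ww$df1, x$ww$df2, x$ww$statistic, x$ww$p_value))
  invisible(x)
}

#' Trial-by-trial correlation between two angular measures
#'
#' Pearson correlation between two angle series after wrapping both to
#' `(-180, 180]` and re-centring both on the circular mean of the first
#' series (so the arbitrary cut point of the circle is placed opposite
#' the bulk of the data).  A linear correlation on circular quantities is
#' not uniquely defined; this re-centring rule is the package's
#' documented choice and is adequate when the joint distribution is
#' concentrated.
#'
#' @param data Data frame.
#' @param a,b Angle columns in degrees (tidy-eval).
#' @param min_n Minimum number of complete pairs (default 10).
#' @return A tibble with `r`, `p_value`, `n`.
#' @export
angle_report_correlation <- function(data, a, b, min_n = 10) {
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  ok <- !is.na(av) & !is.na(bv)
  av <- av[ok]; bv <- bv[ok]
  if (length(av) < min_n) {
    stop("need at least ", min_n, " complete pairs", call. = FALSE)
  }
  mu <- circ_mean(av)
  a2 <- circ_diff(av, mu)
  b2 <- circ_diff(bv, mu)
  if (stats::sd(a2) < 1e-12 || stats::sd(b2) < 1e-12) {
    stop("degenerate variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(a2, b2)
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(a2))
}
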