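# --- broom-style tidiers -----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Watson-Williams result
#'
#' @param x A `watson_williams` object.
#' @param ... Ignored.
#' @return `tidy()`: the per-group summary tibble; `glance()`: a one-row
#'   tibble with the test statistics.
#' @method tidy watson_williams
#' @export
tidy.watson_williams <- function(x, ...) {
  x$groups
}

#' @rdname tidy.watson_williams
#' @method glance watson_williams
#' @export
glance.watson_williams <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p_value = x$p_value, correction = x$correction,
                 kappa = x$kappa, r_within = x$r_within)
}

#' Tidy a histogram permutation test
#'
#' @param x A `hist_perm_test` object.
#' @param ... Ignored.
#' @return `tidy()`: the per-bin table (`bin_center`, `observed_diff`,
#'   `p_value`, `significant`); `glance()`: one row of test settings and
#'   the number of significant bins.
#' @method tidy hist_perm_test
#' @export
tidy.hist_perm_test <- function(x, ...) {
  x$table
}

#' @rdname tidy.hist_perm_test
#' @method glance hist_perm_test
#' @export
glance.hist_perm_test <- function(x, ...) {
  tibble::tibble(
    baseline = x$baseline, comparison = x$comparison,
    n_subjects = x$n_subjects, n_perm = x$n_perm, alpha = x$alpha,
    alternative = x$alternative, null_unit = x$null_unit,
    n_significant = sum(x$table$significant),
    min_p = min(x$table$p_value)
  )
}

#' Tidy a paired comparison
#'
#' @param x A `paired_comparison` object.
#' @param ... Ignored.
#' @return A one-row tibble with all test statistics.
#' @method tidy paired_comparison
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(
    t = x$t, df = x$df, p_value = x$p_value, cohens_d = x$cohens_d,
    wilcoxon_p = x$wilcoxon_p, shapiro_p = x$shapiro_p,
    mean_diff = x$mean_diff, n = x$n, degenerate = x$degenerate
  )
}

#' Tidy a serial-dependence curve
#'
#' @param x A `serial_curve` object.
#' @param ... Ignored.
#' @return `tidy()`: the group curve tibble; `glance()`: the
#'   Watson-Williams summary across bins.
#' @method tidy serial_curve
#' @export
tidy.serial_curve <- function(x, ...) {
  x$curve
}

#' @rdname tidy.serial_curve
#' @method glance serial_curve
#' @export
glance.serial_curve <- function(x, ...) {
  glance.watson_williams(x$ww)
}

#' Tidy a mixed-model wrapper
#'
#' @param x A `glmm_fit` object.
#' @param ... Ignored.
#' @return The coefficient tibble.
#' @method tidy glmm_fit
#' @export
tidy.glmm_fit <- function(x, ...) {
  x$coefficients
}
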