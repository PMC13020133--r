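# --- paired comparisons and mixed-model wrappers -----------------------------

#' Paired comparison of two subject-level measures
#'
#' Standard paired battery: paired t-test, Wilcoxon signed-rank test and
#' a Shapiro-Wilk normality check on the differences, with Cohen's d for
#' paired data (`mean(diff) / sd(diff)`).  Identical vectors are reported
#' as t = 0, p = 1, d = 0 with `degenerate = TRUE`; a constant non-zero
#' shift (zero-variance differences with non-zero mean) is an error,
#' since no finite statistic describes it.
#'
#' @param x,y Paired numeric vectors (same length, n >= 3).
#' @return An object of class `paired_comparison`: `t`, `df`, `p_value`,
#'   `cohens_d`, `wilcoxon_p`, `shapiro_p`, `mean_diff`, `n`,
#'   `degenerate`.
#' @export
paired_comparison <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) < 1e-12) {
    if (abs(mean(d)) > 1e-12) {
      stop("zero-variance differences with non-zero mean: ",
           "paired statistics are degenerate", call. = FALSE)
    }
    out <- list(t = 0, df = n - 1, p_value = 1, cohens_d = 0,
                wilcoxon_p = 1, shapiro_p = NA_real_,
                mean_diff = 0, n = n, degenerate = TRUE)
    return(structure(out, class = "paired_comparison"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = FALSE))
  sh <- stats::shapiro.test(d)
  structure(
    list(
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      cohens_d = mean(d) / stats::sd(d),
      wilcoxon_p = wt$p.value, shapiro_p = sh$p.value,
      mean_diff = mean(d), n = n, degenerate = FALSE
    ),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired comparison (n = %d): t(%g) = %.3g, p = %.3g, d = %.3g\n",
              x$n, x$df, x$t, x$p_value, x$cohens_d))
  cat(sprintf("  Wilcoxon p = %.3g; Shapiro-Wilk p = %s\n",
              x$wilcoxon_p,
              if (is.na(x$shapiro_p)) "NA" else sprintf("%.3g", x$shapiro_p)))
  invisible(x)
}

# Capture convergence complaints from a mixed-model fit instead of
# letting them vanish; they are surfaced in the returned object.
collect_messages <- function(expr) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    expr,
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(fit = fit, messages = msgs)
}

#' Mixed-effects model of response correctness
#'
#' Contract-level wrapper over a logistic generalized linear mixed model
#' predicting trial correctness from coherence and session, with a
#' random intercept per subject.  Coherence enters as a numeric
#' covariate.  Convergence complaints are captured and returned, never
#' silently dropped.
#'
#' @param classified Output of [classify_trials()]; must contain
#'   `correct`, `coherence`, `session`, `subject_id`.
#' @param formula Optional model formula overriding the default
#'   `correct ~ coherence + session + (1 | subject_id)`.
#' @return A list of class `glmm_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), `converged`,
#'   `messages`, and the underlying `fit`.
#' @export
fit_correctness_glmm <- function(classified, formula = NULL) {
  if (is.null(formula)) {
    formula <- correct ~ coherence + session + (1 | subject_id)
  }
  res <- collect_messages(
    lme4::glmer(formula, data = classified, family = stats::binomial())
  )
  co <- summary(res$fit)$coefficients
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(co),
        estimate = co[, "Estimate"],
        std_error = co[, "Std. Error"],
        statistic = co[, "z value"],
        p_value = co[, "Pr(>|z|)"]
      ),
      converged = length(res$messages) == 0,
      messages = res$messages,
      fit = res$fit
    ),
    class = "glmm_fit"
  )
}

#' Mixed-effects model of anticipation angle on previous direction
#'
#' Linear mixed model predicting the anticipatory pursuit angle on trial
#' n from the stimulus direction on trial n - 1, with a random intercept
#' per subject (Satterthwaite p-value for the slope).  Angles enter as
#' linear covariates on `(-180, 180]`.
#'
#' @param data Data frame with the anticipation angle, previous-trial
#'   direction and subject columns.
#' @param angle,prev_direction,subject Columns (tidy-eval; defaults
#'   `anticipation_angle`, `prev_rdk_dir`, `subject_id`).
#' @return A list of class `lmm_fit`: `slope`, `std_error`, `statistic`,
#'   `p_value`, `converged`, `messages`, `fit`.
#' @export
fit_anticipation_lmm <- function(data, angle = anticipation_angle,
                                 prev_direction = prev_rdk_dir,
                                 subject = subject_id) {
  df <- tibble::tibble(
    y = dplyr::pull(data, {{ angle }}),
    x = dplyr::pull(data, {{ prev_direction }}),
    subject = as.character(dplyr::pull(data, {{ subject }}))
  )
  df <- dplyr::filter(df, !is.na(.data$y), !is.na(.data$x))
  if (length(unique(df$subject)) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  res <- collect_messages(
    lmerTest::lmer(y ~ x + (1 | subject), data = df)
  )
  co <- summary(res$fit)$coefficients
  structure(
    list(
      slope = co["x", "Estimate"],
      std_error = co["x", "Std. Error"],
      statistic = co["x", "t value"],
      p_value = co["x", "Pr(>|t|)"],
      converged = length(res$messages) == 0,
      messages = res$messages,
      fit = res$fit
    ),
    class = "lmm_fit"
  )
}
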