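# --- file interchange --------------------------------------------------------

trial_cols <- c("subject_id", "session", "trial", "rdk_dir_deg",
                "coherence", "report_dir_deg", "fixation_ms")
trace_cols <- c("subject_id", "trial", "t_ms", "x_deg", "y_deg")

#' Read and write trial tables
#'
#' CSV round-trip of trial tables.  On read, required columns are
#' checked and angle columns are re-wrapped onto the canonical
#' `(-180, 180]` range (with a message when any value changed, e.g. 350
#' read back as -10).
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_trials()` returns the trial tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(trial_cols, names(out))
  if (length(missing) > 0) {
    stop("trial file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("rdk_dir_deg", "report_dir_deg", "frequent_dir_deg")) {
    if (col %in% names(out)) {
      wrapped <- circ_wrap(out[[col]])
      changed <- !is.na(out[[col]]) & abs(wrapped - out[[col]]) > 1e-9
      if (any(changed)) {
        message("re-wrapped ", sum(changed), " value(s) of `", col,
                "` onto (-180, 180]")
        out[[col]] <- wrapped
      }
    }
  }
  out
}

#' Read and write eye-trace tables
#'
#' Long-format 500-Hz gaze tables (`subject_id`, `trial`, `t_ms`,
#' `x_deg`, `y_deg`, plus `session` if present), t = 0 at stimulus
#' onset.  On read, each trial's time base is checked for uniform
#' sampling; any gap is an error.
#'
#' @param traces Long trace tibble.
#' @param path File path.
#' @return `read_traces()` returns the trace tibble; `write_traces()`
#'   returns `path` invisibly.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(trace_cols, names(out))
  if (length(missing) > 0) {
    stop("trace file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- intersect(c("subject_id", "session", "trial"), names(out))
  check <- dplyr::group_by(out, dplyr::across(dplyr::all_of(key)))
  bad <- dplyr::summarise(
    check,
    uniform = length(unique(round(diff(.data$t_ms), 9))) <= 1,
    .groups = "drop"
  )
  if (any(!bad$uniform)) {
    stop("non-uniform trace sampling detected in ", sum(!bad$uniform),
         " trial(s)", call. = FALSE)
  }
  out
}

#' Write a structured run report
#'
#' Serialises a [run_pipeline()] result (or any list) to JSON: the
#' config echo (seeds, windows, thresholds), stage counts and all test
#' outputs, omitting the bulky trial/trace tables and fitted model
#' objects.
#'
#' @param run A `pursuit_run` object (or serialisable list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(run, path) {
  payload <- if (inherits(run, "pursuit_run")) {
    list(
      package_version = run$version,
      seed = run$config$seed,
      n_subjects = run$config$n_subjects,
      sessions = lapply(run$config$designs, function(d) {
        list(label = d$label, n_trials = d$n_trials,
             frequent_direction = d$frequent_direction)
      }),
      settings = run$config[c("anticipation_window", "accel_window_early",
                              "accel_window_late", "steady_window",
                              "anticipation_bounds", "lowpass_cutoff_hz",
                              "saccade_threshold", "saccade_pad_ms",
                              "n_perm", "alpha", "pooled_coherences")],
      counts = run$counts,
      results = serialise_results(run$results),
      elapsed_s = run$elapsed_s
    )
  } else {
    run
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

serialise_results <- function(x) {
  if (inherits(x, "hist_perm_test")) {
    return(list(type = "hist_perm_test", baseline = x$baseline,
                comparison = x$comparison, n_perm = x$n_perm,
                alpha = x$alpha, alternative = x$alternative,
                table = x$table))
  }
  if (inherits(x, "watson_williams")) {
    return(list(type = "watson_williams", F = x$statistic, df1 = x$df1,
                df2 = x$df2, p_value = x$p_value))
  }
  if (inherits(x, "serial_curve")) {
    return(list(type = "serial_curve", curve = x$curve,
                ww = serialise_results(x$ww)))
  }
  if (inherits(x, "paired_comparison")) {
    return(unclass(x))
  }
  if (inherits(x, c("glmm_fit", "lmm_fit"))) {
    return(list(type = class(x)[1],
                coefficients = x$coefficients, slope = x$slope,
                p_value = x$p_value, converged = x$converged,
                messages = x$messages))
  }
  if (is.list(x) && !is.data.frame(x)) {
    return(lapply(x, serialise_results))
  }
  x
}

#' Read and write analysis configurations
#'
#' YAML round-trip of [analysis_config()] objects (designs and observer
#' included).
#'
#' @param config An `analysis_config` object.
#' @param path File path.
#' @return `read_config()` returns the rebuilt `analysis_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  plain <- unclass(config)
  plain$designs <- lapply(config$designs, function(d) {
    list(session_kind = d$session_kind,
         frequent_direction = if (is.na(d$frequent_direction)) NULL else
           d$frequent_direction,
         n_trials = d$n_trials,
         frequent_share = if (is.na(d$frequent_share)) NULL else
           d$frequent_share,
         coherence_levels = d$coherence_levels)
  })
  plain$observer <- unclass(config$observer)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  designs <- lapply(raw$designs, function(d) {
    args <- d[!vapply(d, is.null, logical(1))]
    if (identical(args$session_kind, "unbiased")) {
      args$frequent_share <- NULL
    }
    do.call(make_session_design, args)
  })
  observer <- do.call(observer_params, raw$observer)
  args <- raw[setdiff(names(raw), c("designs", "observer"))]
  do.call(analysis_config, c(list(designs = designs, observer = observer),
                             args))
}
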