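# --- configuration and end-to-end orchestration -----------------------------

#' Analysis configuration
#'
#' Single source of truth for every constant of the measurement chain.
#' Defaults encode the standard study conditions: three sessions
#' (unbiased; biased toward 0 deg; biased toward -135 deg), 21 subjects,
#' the -50 to 100 ms anticipation window with 0.25-2.5 deg/s amplitude
#' bounds, 100-120 vs. 200-220 ms acceleration windows, the 400-600 ms
#' steady-state window, a 30-Hz position low-pass, 30 deg/s saccade
#' threshold with 10-ms padding, and 10000-permutation histogram tests at
#' alpha 0.01 pooling the 5% and 15% coherence levels.
#'
#' @param n_subjects Number of simulated subjects.
#' @param designs List of [make_session_design()] objects (exactly one
#'   unbiased design, used as the baseline).
#' @param observer An [observer_params()] object.
#' @param simulate_traces Simulate and analyse eye traces (they dominate
#'   run time; perceptual stages run regardless).
#' @param anticipation_window,accel_window_early,accel_window_late,steady_window
#'   Analysis windows in ms, half-open.
#' @param anticipation_bounds Anticipation amplitude validity bounds
#'   (deg/s).
#' @param lowpass_cutoff_hz Position low-pass cutoff.
#' @param saccade_threshold,saccade_pad_ms Saccade masking parameters.
#' @param n_perm,alpha Permutation-test settings.
#' @param pooled_coherences Coherence levels pooled for the error-trial
#'   choice histograms.
#' @param fit_models Also fit the mixed-effects models (slower).
#' @param seed Master integer seed; every random stage derives its
#'   substream from it.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(n_subjects = 21,
                            designs = list(
                              make_session_design("unbiased"),
                              make_session_design("biased",
                                                  frequent_direction = 0),
                              make_session_design("biased",
                                                  frequent_direction = -135)
                            ),
                            observer = observer_params(),
                            simulate_traces = TRUE,
                            anticipation_window = c(-50, 100),
                            accel_window_early = c(100, 120),
                            accel_window_late = c(200, 220),
                            steady_window = c(400, 600),
                            anticipation_bounds = c(0.25, 2.5),
                            lowpass_cutoff_hz = 30,
                            saccade_threshold = 30,
                            saccade_pad_ms = 10,
                            n_perm = 10000,
                            alpha = 0.01,
                            pooled_coherences = c(0.05, 0.15),
                            fit_models = FALSE,
                            seed = 1L) {
  stopifnot(n_subjects >= 1, is.list(designs),
            inherits(observer, "observer_params"))
  kinds <- vapply(designs, function(d) d$session_kind, character(1))
  if (sum(kinds == "unbiased") != 1) {
    stop("`designs` must contain exactly one unbiased session", call. = FALSE)
  }
  stim_ms <- 1000
  for (nm in c("anticipation_window", "accel_window_early",
               "accel_window_late", "steady_window")) {
    w <- get(nm)
    if (length(w) != 2 || w[1] >= w[2]) {
      stop("window `", nm, "` must be an increasing pair", call. = FALSE)
    }
    if (w[2] > stim_ms) {
      stop("window `", nm, "` [", w[1], ", ", w[2],
           "] ms extends beyond the ", stim_ms, "-ms stimulus",
           call. = FALSE)
    }
  }
  stopifnot(anticipation_bounds[1] > 0,
            anticipation_bounds[1] < anticipation_bounds[2],
            saccade_threshold > 0, n_perm >= 100,
            alpha > 0, alpha < 1)
  structure(
    list(
      n_subjects = n_subjects, designs = designs, observer = observer,
      simulate_traces = simulate_traces,
      anticipation_window = anticipation_window,
      accel_window_early = accel_window_early,
      accel_window_late = accel_window_late,
      steady_window = steady_window,
      anticipation_bounds = anticipation_bounds,
      lowpass_cutoff_hz = lowpass_cutoff_hz,
      saccade_threshold = saccade_threshold,
      saccade_pad_ms = saccade_pad_ms,
      n_perm = n_perm, alpha = alpha,
      pooled_coherences = pooled_coherences,
      fit_models = fit_models,
      seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>", x$n_subjects, "subjects,",
      length(x$designs), "sessions; seed", x$seed, "\n")
  for (d in x$designs) cat("  -", d$label, "(", d$n_trials, "trials )\n")
  cat("  traces:", x$simulate_traces, "; n_perm:", x$n_perm,
      "; alpha:", x$alpha, "\n")
  invisible(x)
}

#' Run the full simulate-analyse-test pipeline
#'
#' Executes every stage under the configured seed: simulate trials,
#' reports and (optionally) eye traces; extract per-trial pursuit
#' kinematics; classify perceptual reports; then run the inferential
#' layer (per-bin permutation tests of error-choice and anticipation
#' histograms for each biased session against the unbiased baseline,
#' the serial-dependence curve on the unbiased session, paired
#' comparisons of anticipatory velocity toward each frequent direction,
#' steady-state/report correlations per coherence, and optionally the
#' mixed models).  Re-running with the same config reproduces all
#' outputs bit-exactly.
#'
#' @param config An [analysis_config()] object.
#' @param out_dir Optional directory; when given, trial, kinematic and
#'   classified tables are written as CSV and the run report as JSON.
#' @return An object of class `pursuit_run`: `config`, `trials`
#'   (classified), `kinematics`, `counts` (per-stage reconciliation),
#'   `results` (all statistical outputs), `version`, `elapsed_s`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  t_start <- Sys.time()
  sim <- simulate_experiment(config$designs, config$observer,
                             n_subjects = config$n_subjects,
                             seed = config$seed,
                             traces = config$simulate_traces)
  trials <- classify_trials(sim$trials)
  unbiased_label <- purrr::detect(config$designs,
                                  ~ .x$session_kind == "unbiased")$label
  biased <- purrr::keep(config$designs, ~ .x$session_kind == "biased")

  kin <- NULL
  if (config$simulate_traces) {
    kin <- extract_kinematics(
      sim$traces, trials,
      cutoff_hz = config$lowpass_cutoff_hz,
      speed_threshold = config$saccade_threshold,
      pad_ms = config$saccade_pad_ms,
      anticipation_window = config$anticipation_window,
      accel_window_early = config$accel_window_early,
      accel_window_late = config$accel_window_late,
      steady_window = config$steady_window,
      anticipation_bounds = config$anticipation_bounds
    )
  }

  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # perceptual error-choice histogram tests, biased vs unbiased
  err_pool <- dplyr::filter(trials, .data$label != "correct",
                            .data$coherence %in% config$pooled_coherences)
  results$choice_tests <- purrr::map(biased, function(d) {
    stage(paste0("choice_test_", d$label), {
      dat <- dplyr::filter(err_pool, .data$session %in%
                             c(unbiased_label, d$label))
      histogram_permutation_test(
        dat, response_bin, session, subject_id,
        baseline = unbiased_label, n_perm = config$n_perm,
        alpha = config$alpha,
        seed = derive_seed(config$seed, 40001)
      )
    })
  })
  names(results$choice_tests) <- vapply(biased, `[[`, "", "label")

  # serial dependence on the unbiased session
  results$serial <- stage("serial_dependence", {
    serial_dependence_curve(
      dplyr::filter(trials, .data$session == unbiased_label)
    )
  })

  if (config$simulate_traces) {
    valid <- dplyr::filter(kin, .data$anticipation_valid)
    results$anticipation_tests <- purrr::map(biased, function(d) {
      stage(paste0("anticipation_test_", d$label), {
        dat <- dplyr::filter(valid, .data$session %in%
                               c(unbiased_label, d$label))
        histogram_permutation_test(
          dat, anticipation_angle, session, subject_id,
          baseline = unbiased_label, n_perm = config$n_perm,
          alpha = config$alpha,
          seed = derive_seed(config$seed, 40002)
        )
      })
    })
    names(results$anticipation_tests) <- vapply(biased, `[[`, "", "label")

    # paired anticipatory velocity toward each frequent direction:
    # trials whose anticipation direction falls in the frequent-direction
    # bin, projected onto it, averaged per subject and session
    results$anticipation_paired <- purrr::map(biased, function(d) {
      stage(paste0("anticipation_paired_", d$label), {
        fd <- d$frequent_direction
        sel <- dplyr::filter(
          valid,
          .data$session %in% c(unbiased_label, d$label),
          abs(circ_diff(.data$anticipation_angle, fd)) <= 11.25
        )
        sel$vproj_fd <- sel$anticipation_amp *
          cospi(circ_diff(sel$anticipation_angle, fd) / 180)
        per_subj <- dplyr::summarise(
          dplyr::group_by(sel, .data$subject_id, .data$session),
          vproj = mean(.data$vproj_fd), .groups = "drop"
        )
        wide <- tidyr::pivot_wider(per_subj, names_from = "session",
                                   values_from = "vproj")
        cmp <- dplyr::filter(wide, stats::complete.cases(wide))
        if (nrow(cmp) < 3) {
          list(error = "fewer than 3 subjects with valid trials in both sessions")
        } else {
          paired_comparison(cmp[[d$label]], cmp[[unbiased_label]])
        }
      })
    })
    names(results$anticipation_paired) <- vapply(biased, `[[`, "", "label")

    # steady-state direction vs perceptual report, per coherence level
    joined <- dplyr::left_join(
      kin,
      dplyr::select(trials, dplyr::all_of(c("subject_id", "session", "trial",
                                            "report_dir_deg"))),
      by = c("subject_id", "session", "trial")
    )
    results$steady_report_correlation <- stage("steady_correlation", {
      dplyr::group_modify(
        dplyr::group_by(joined, .data$session, .data$coherence),
        function(g, key) {
          ok <- !is.na(g$steady_angle) & !is.na(g$report_dir_deg)
          if (sum(ok) < 10) {
            return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                                  n = sum(ok)))
          }
          angle_report_correlation(g[ok, ], steady_angle, report_dir_deg)
        }
      ) |> dplyr::ungroup()
    })
  }

  if (config$fit_models) {
    results$correctness_glmm <- stage("correctness_glmm",
                                      fit_correctness_glmm(trials))
    if (config$simulate_traces) {
      results$anticipation_lmm <- stage("anticipation_lmm", {
        dat <- dplyr::filter(kin, .data$session == unbiased_label)
        dat <- dplyr::arrange(dat, .data$subject_id, .data$trial)
        dat <- dplyr::group_by(dat, .data$subject_id)
        dat <- dplyr::mutate(dat, prev_rdk_dir = dplyr::lag(.data$rdk_dir_deg))
        dat <- dplyr::ungroup(dat)
        fit_anticipation_lmm(
          dplyr::filter(dat, .data$anticipation_valid,
                        !is.na(.data$prev_rdk_dir))
        )
      })
    }
  }

  counts <- trial_counts(trials, kin)
  run <- structure(
    list(
      config = config,
      trials = trials,
      kinematics = kin,
      truth = sim$truth,
      counts = counts,
      results = results,
      version = as.character(utils::packageVersion("rdkpursuit")),
      elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
    ),
    class = "pursuit_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    if (!is.null(kin)) {
      readr::write_csv(kin, file.path(out_dir, "kinematics.csv"))
    }
    write_report(run, file.path(out_dir, "report.json"))
  }
  run
}

# Per-stage row counts that must reconcile: generated = analysed +
# excluded at every stage.
trial_counts <- function(trials, kin) {
  out <- tibble::tibble(
    session = character(0), stage = character(0), n = integer(0)
  )
  by_sess <- dplyr::count(trials, .data$session)
  out <- dplyr::bind_rows(
    tibble::tibble(session = by_sess$session, stage = "generated",
                   n = by_sess$n),
    dplyr::count(trials, .data$session, .data$label) |>
      dplyr::transmute(session = .data$session,
                       stage = paste0("label_", .data$label),
                       n = .data$n)
  )
  if (!is.null(kin)) {
    k <- dplyr::group_by(kin, .data$session)
    out <- dplyr::bind_rows(
      out,
      dplyr::summarise(k, stage = "anticipation_valid",
                       n = sum(.data$anticipation_valid), .groups = "drop"),
      dplyr::summarise(k, stage = "anticipation_excluded_amplitude",
                       n = sum(!.data$anticipation_valid &
                                 !is.na(.data$anticipation_amp)),
                       .groups = "drop"),
      dplyr::summarise(k, stage = "anticipation_excluded_coverage",
                       n = sum(is.na(.data$anticipation_amp)),
                       .groups = "drop")
    )
  }
  out
}

#' @export
print.pursuit_run <- function(x, ...) {
  cat("<pursuit_run> rdkpursuit", x$version, "- seed", x$config$seed, "\n")
  cat("  trials:", nrow(x$trials), "in",
      length(unique(x$trials$session)), "sessions;",
      if (is.null(x$kinematics)) "no traces" else
        paste(nrow(x$kinematics), "trials with kinematics"), "\n")
  cat("  results:", paste(names(x$results), collapse = ", "), "\n")
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
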