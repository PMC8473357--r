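#' Simulate a cohort of trials across tasks
#'
#' Generates `n_trials` trials for each scripted task, deriving one
#' sub-seed per trial from `seed` so cohorts are reproducible.
#'
#' @param tasks task numbers (see [task_script()]).
#' @param n_trials trials per task (the six-set split protocol needs at
#'   least 6).
#' @param seed cohort seed.
#' @param ... further arguments to [sim_config()] (e.g. `emg_lead_ms`,
#'   `accel_noise_sd`).
#' @return List of `gait_trial`s, each carrying a `task` attribute.
#' @export
simulate_cohort <- function(tasks = 1:5, n_trials = 6L, seed = 1L, ...) {
  trials <- list()
  for (task in tasks) {
    for (i in seq_len(n_trials)) {
      sub_seed <- (abs(seed) * 1009L + task * 131L + i) %% .Machine$integer.max
      cfg <- sim_config(task = task, seed = sub_seed, ...)
      trial <- simulate_trial(cfg)
      attr(trial, "task") <- task
      trials[[length(trials) + 1L]] <- trial
    }
  }
  trials
}

collect_training_rows <- function(train_trials, window_ms, stride, cols) {
  xs <- list()
  ys <- list()
  for (trial in train_trials) {
    feats <- build_features(trial, window_ms, step = stride)
    keep <- steady_state_mask(trial)[feats$sample_index]
    xs[[length(xs) + 1L]] <- feats$X[keep, cols, drop = FALSE]
    ys[[length(ys) + 1L]] <- as.character(feats$y[keep])
  }
  list(X = do.call(rbind, xs), y = as_mode(unlist(ys)))
}

#' Run the full recognition/prediction pipeline on a cohort
#'
#' Implements the study protocol end to end: per task the trials are
#' split into six random sets (five train, one test); classifiers are
#' trained on steady-state feature rows of the training trials only, with
#' normalization bounds fitted on the same rows; each held-out trial is
#' then streamed sample by sample through the classifier, the agreement
#' vote and the transition-legality rules, and scored for steady-state
#' recognition (CA/SE/SP) and transition prediction (PA/RT).
#'
#' @param trials list of `gait_trial`s (from [simulate_cohort()] or
#'   [read_trial()]), optionally carrying `task` attributes.
#' @param spec a [classifier_spec()].
#' @param window_ms sliding RMS window in milliseconds.
#' @param modality `"fusion"`, `"emg_only"` or `"accel_only"`.
#' @param agreement_n agreement-vote length.
#' @param train_stride training-row stride in samples (online test
#'   streams always use a one-sample step).
#' @param split_seed seed for the train/test split.
#' @param rules transition-legality table.
#' @return A `cohort_eval` list: `steady` ([score_steady()] report pooled
#'   over test trials), `transitions` (pooled outcome table with `PA` and
#'   `RT_mean_ms`), `model`, and the evaluation settings.
#' @export
evaluate_cohort <- function(trials, spec, window_ms = 80, modality = "fusion",
                            agreement_n = 100L, train_stride = 20L,
                            split_seed = spec$seed, rules = default_rules()) {
  task_of <- vapply(trials, function(tr) attr(tr, "task") %||% 1L, numeric(1))
  cols <- modality_columns(modality)
  trials <- lapply(trials, function(tr) {
    if (isTRUE(attr(tr, "preprocessed"))) tr else preprocess_trial(tr)
  })
  train_trials <- list()
  test_trials <- list()
  for (task in unique(task_of)) {
    sp <- split_trials(trials[task_of == task], 6L, seed = split_seed)
    train_trials <- c(train_trials, sp$train)
    test_trials <- c(test_trials, sp$test)
  }
  train <- collect_training_rows(train_trials, window_ms, train_stride, cols)
  bounds <- fit_norm_bounds(train$X)
  model <- tune_and_train(apply_norm(train$X, bounds), train$y, spec)

  truth_all <- character(0)
  pred_all <- character(0)
  outcome_list <- list()
  for (trial in test_trials) {
    feats <- build_features(trial, window_ms, step = 1L)
    Xn <- apply_norm(feats$X[, cols, drop = FALSE], bounds)
    raw <- predict_stream(model, Xn)
    cfg <- decision_config(agreement_n, initial_mode = feats$initial_mode)
    trace <- decide_stream(raw, cfg, rules, t = feats$t)
    keep <- steady_state_mask(trial)[feats$sample_index]
    truth_all <- c(truth_all, as.character(feats$y[keep]))
    pred_all <- c(pred_all, as.character(trace$output[keep]))
    tr_rep <- score_transitions(trace, transition_windows(trial))
    outcome_list[[length(outcome_list) + 1L]] <- tr_rep$outcomes
  }
  outcomes <- do.call(rbind, outcome_list)
  steady <- score_steady(as_mode(pred_all), as_mode(truth_all))
  pa <- if (nrow(outcomes)) 100 * mean(outcomes$counted) else NA_real_
  rt <- if (any(outcomes$counted)) mean(outcomes$RT_ms[outcomes$counted]) else NA_real_
  structure(list(
    steady = steady,
    transitions = list(PA = pa, RT_mean_ms = rt, outcomes = outcomes),
    model = model, window_ms = window_ms, modality = modality,
    agreement_n = agreement_n, n_train_rows = nrow(train$X),
    n_test_trials = length(test_trials)
  ), class = "cohort_eval")
}

#' @export
print.cohort_eval <- function(x, ...) {
  cat(sprintf(
    "<cohort_eval> %s, %s, %g ms window\n  CA %.2f%%  SE %.2f%%  SP %.2f%%  PA %.1f%%  RT %.1f ms\n",
    x$model$method, x$modality, x$window_ms, x$steady$CA, x$steady$SE_mean,
    x$steady$SP_mean, x$transitions$PA, x$transitions$RT_mean_ms))
  invisible(x)
}

#' Sliding-window size sweep
#'
#' Runs the full pipeline once per candidate window size on identical
#' splits and seeds and tabulates CA, PA and mean RT.
#'
#' @param trials cohort trial list.
#' @param spec a [classifier_spec()].
#' @param windows numeric vector of window sizes (ms), at least 2 for a
#'   sweep (a single value yields a one-row table).
#' @param ... passed to [evaluate_cohort()].
#' @return Data frame with one row per window: `window_ms`, `CA`, `PA`,
#'   `RT_mean_ms`.
#' @export
run_window_sweep <- function(trials, spec, windows, ...) {
  rows <- lapply(windows, function(w) {
    ev <- evaluate_cohort(trials, spec, window_ms = w, ...)
    data.frame(window_ms = w, CA = ev$steady$CA, PA = ev$transitions$PA,
               RT_mean_ms = ev$transitions$RT_mean_ms)
  })
  do.call(rbind, rows)
}

#' Sensing-modality comparison
#'
#' Runs the identical protocol with EMG-only (14 features),
#' acceleration-only (21) and fused (35) feature sets; modality
#' subsetting happens before normalization fitting so no cross-modality
#' information leaks.
#'
#' @param trials cohort trial list.
#' @param spec a [classifier_spec()].
#' @param window_ms sliding window (ms).
#' @param modalities subset of the three modality names.
#' @param ... passed to [evaluate_cohort()].
#' @return Data frame with one row per modality: `modality`,
#'   `n_features`, `CA`, `SE_mean`, `PA`, `RT_mean_ms`.
#' @export
run_modality_comparison <- function(trials, spec, window_ms = 80,
                                    modalities = c("emg_only", "accel_only", "fusion"),
                                    ...) {
  rows <- lapply(modalities, function(m) {
    ev <- evaluate_cohort(trials, spec, window_ms = window_ms, modality = m, ...)
    data.frame(modality = m, n_features = length(modality_columns(m)),
               CA = ev$steady$CA, SE_mean = ev$steady$SE_mean,
               PA = ev$transitions$PA, RT_mean_ms = ev$transitions$RT_mean_ms,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
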