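#' Steady-state recognition metrics
#'
#' Sample-wise comparison of the online output with the ground truth over
#' steady-state samples: classification accuracy CA = 100 * Ntrue / Nall,
#' and one-vs-rest sensitivity SE_i = TP/(TP+FN) and specificity
#' SP_i = TN/(TN+FP) per class, macro-averaged over the classes.
#'
#' @param predicted per-sample predicted labels, or a `decision_trace`
#'   (its `output` is used).
#' @param truth per-sample true labels, same length.
#' @param steady_mask logical mask selecting the steady-state samples
#'   (transition cycles excluded); must select at least one sample.
#' @return An `eval_report` list: `confusion` (true x predicted counts),
#'   `CA`, `SE_per_class`, `SP_per_class`, `SE_mean`, `SP_mean`
#'   (percent), and `n` evaluated samples.
#' @export
score_steady <- function(predicted, truth, steady_mask = NULL) {
  if (inherits(predicted, "decision_trace")) predicted <- predicted$output
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  if (is.null(steady_mask)) steady_mask <- rep(TRUE, length(truth))
  if (!any(steady_mask)) stop("steady mask selects no samples")
  lev <- if (is.factor(truth)) levels(truth) else levels(as_mode(truth))
  truth <- factor(as.character(truth)[steady_mask], levels = lev)
  predicted <- factor(as.character(predicted)[steady_mask], levels = lev)
  cm <- table(truth = truth, predicted = predicted)
  n <- sum(cm)
  ca <- 100 * sum(diag(cm)) / n
  se <- sp <- stats::setNames(numeric(length(lev)), lev)
  for (i in seq_along(lev)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    se[i] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    sp[i] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  }
  structure(list(confusion = cm, CA = ca,
                 SE_per_class = se, SP_per_class = sp,
                 SE_mean = mean(se, na.rm = TRUE),
                 SP_mean = mean(sp, na.rm = TRUE), n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> CA %.2f%%  SE %.2f%%  SP %.2f%%  (n = %d)\n",
              x$CA, x$SE_mean, x$SP_mean, x$n))
  invisible(x)
}

#' Prediction metrics over gait transitions
#'
#' For each transition, the prediction time T_pred is the earliest
#' instant within the transition cycle at which the online output equals
#' the upcoming steady mode *and holds it until the actual onset*
#' (transient flickers cannot claim an early prediction).  Response time
#' RT = (T_pred - T_actual) * 1000 ms is negative when the mode is
#' predicted before it begins.  A transition whose mode is only reached
#' after onset (within its steady segment) still counts as correctly
#' predicted, with positive RT.  Predictive accuracy PA is the percent of
#' transitions whose next mode is ever correctly output.
#'
#' @param trace a `decision_trace` whose `t` holds sample times.
#' @param transitions data frame from [transition_windows()] (or with
#'   columns `onset_s`, `prev_hs_s`, `next_mode`, `steady_end_s`).
#' @return A `transition_report`: `PA` (percent, `NA` when there are no
#'   transitions), `RT_mean_ms` over correctly predicted transitions, and
#'   `outcomes` (one row per transition: `next_mode`, `T_actual`,
#'   `T_pred`, `RT_ms`, `predicted_before`, `counted`).
#' @export
score_transitions <- function(trace, transitions) {
  if (!inherits(trace, "decision_trace")) stop("trace must be a decision_trace")
  t <- trace$t
  if (is.null(t)) stop("trace must carry sample times (t)")
  out <- as.character(trace$output)
  n_tr <- nrow(transitions)
  outcomes <- data.frame(
    next_mode = character(n_tr), T_actual = numeric(n_tr),
    T_pred = rep(NA_real_, n_tr), RT_ms = rep(NA_real_, n_tr),
    predicted_before = logical(n_tr), counted = logical(n_tr),
    stringsAsFactors = FALSE
  )
  if (n_tr == 0L) {
    return(structure(list(PA = NA_real_, RT_mean_ms = NA_real_,
                          outcomes = outcomes), class = "transition_report"))
  }
  for (k in seq_len(n_tr)) {
    target <- as.character(transitions$next_mode[k])
    t_on <- transitions$onset_s[k]
    outcomes$next_mode[k] <- target
    outcomes$T_actual[k] <- t_on
    pre <- which(t >= transitions$prev_hs_s[k] - 1e-9 & t < t_on - 1e-9)
    t_pred <- NA_real_
    before <- FALSE
    if (length(pre) && out[pre[length(pre)]] == target) {
      # walk back through the terminal run of correct outputs
      hit <- out[pre] == target
      run_start <- length(hit)
      while (run_start > 1L && hit[run_start - 1L]) run_start <- run_start - 1L
      t_pred <- t[pre[run_start]]
      before <- TRUE
    } else {
      post <- which(t >= t_on - 1e-9 & t <= transitions$steady_end_s[k] + 1e-9)
      hit <- which(out[post] == target)
      if (length(hit)) t_pred <- t[post[hit[1L]]]
    }
    if (!is.na(t_pred)) {
      outcomes$T_pred[k] <- t_pred
      outcomes$RT_ms[k] <- (t_pred - t_on) * 1000
      outcomes$predicted_before[k] <- before
      outcomes$counted[k] <- TRUE
    }
  }
  structure(list(
    PA = 100 * mean(outcomes$counted),
    RT_mean_ms = if (any(outcomes$counted)) {
      mean(outcomes$RT_ms[outcomes$counted])
    } else NA_real_,
    outcomes = outcomes
  ), class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("<transition_report> PA %.1f%%  mean RT %.1f ms over %d transitions\n",
              x$PA, x$RT_mean_ms, nrow(x$outcomes)))
  invisible(x)
}
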