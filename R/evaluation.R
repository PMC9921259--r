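# Estimation metrics (accuracy within a tolerance, RMSE, MAE, error SD,
# mean error) and the AAMI SP10 compliance report.

#' Estimation accuracy within a tolerance
#'
#' `100 * #(|estimate - actual| <= tolerance) / n`. A "correct" estimation
#' is one within `tolerance` mmHg of the reference; the default 5 mmHg
#' mirrors the AAMI mean-error bound.
#'
#' @param estimates,actuals Equal-length, non-empty numeric vectors (mmHg).
#' @param tolerance Non-negative tolerance in mmHg.
#' @return Percentage in `[0, 100]`.
#' @export
bp_accuracy <- function(estimates, actuals, tolerance = 5) {
  check_lengths(estimates, actuals)
  check_number(tolerance, "tolerance", 0, Inf)
  100 * mean(abs(estimates - actuals) <= tolerance)
}

#' Error metrics: RMSE, MAE, error SD, mean error
#'
#' `mae = mean |e_i|`, `rmse = sqrt(mean e_i^2)`,
#' `me = mean e_i`, `std_err = sqrt(sum((e_i - me)^2) / (n - 1))` with
#' `e_i = estimate_i - actual_i`.
#'
#' @param estimates,actuals Equal-length, non-empty numeric vectors (mmHg).
#' @return Named list with `rmse`, `mae`, `std_err`, `me`, `n`. `std_err`
#'   requires at least two values.
#' @export
error_metrics <- function(estimates, actuals) {
  check_lengths(estimates, actuals)
  e <- estimates - actuals
  n <- length(e)
  if (n < 2) stop_cuffbp("std_err needs at least 2 values")
  me <- mean(e)
  list(rmse = sqrt(mean(e^2)),
       mae = mean(abs(e)),
       std_err = sqrt(sum((e - me)^2) / (n - 1)),
       me = me,
       n = n)
}

check_lengths <- function(estimates, actuals) {
  if (!length(estimates) || length(estimates) != length(actuals)) {
    stop_cuffbp(sprintf(
      "estimates (%d) and actuals (%d) must be equal-length and non-empty",
      length(estimates), length(actuals)))
  }
}

#' Per-target metrics report
#'
#' Computes accuracy and the four error metrics for SBP and DBP estimates.
#'
#' @param sbp_est,sbp_act,dbp_est,dbp_act Estimates and references (mmHg).
#' @param tolerance Accuracy tolerance in mmHg.
#' @return An object of class `bp_metrics`: a list with one element per
#'   target, each holding `accuracy`, `rmse`, `mae`, `std_err`, `me`, `n`,
#'   `tolerance`.
#' @export
metrics_report <- function(sbp_est, sbp_act, dbp_est, dbp_act, tolerance = 5) {
  one <- function(est, act, name) {
    m <- error_metrics(est, act)
    c(list(target = name, accuracy = bp_accuracy(est, act, tolerance)), m,
      list(tolerance = tolerance))
  }
  structure(list(SBP = one(sbp_est, sbp_act, "SBP"),
                 DBP = one(dbp_est, dbp_act, "DBP")),
            class = "bp_metrics")
}

#' @export
print.bp_metrics <- function(x, ...) {
  cat(sprintf("%-4s %9s %8s %8s %8s %8s %6s\n",
              "", "accuracy", "RMSE", "MAE", "STD", "ME", "n"))
  for (t in names(x)) {
    m <- x[[t]]
    cat(sprintf("%-4s %8.2f%% %8.2f %8.2f %8.2f %8.2f %6d\n",
                t, m$accuracy, m$rmse, m$mae, m$std_err, m$me, m$n))
  }
  cat(sprintf("(accuracy tolerance: %g mmHg)\n", x$SBP$tolerance))
  invisible(x)
}

#' AAMI SP10 compliance check
#'
#' A BP estimator complies when, for both targets, MAE <= 5 mmHg and the
#' error standard deviation <= 8 mmHg, with a study population of at least
#' 85 subjects.
#'
#' @param metrics A [metrics_report()].
#' @param n_subjects Number of subjects in the study population.
#' @param mae_threshold,std_threshold,min_subjects The AAMI limits.
#' @return An object of class `bp_aami`: per-target pass flags, the cohort
#'   flag, and the overall pass flag.
#' @export
aami_check <- function(metrics, n_subjects, mae_threshold = 5,
                       std_threshold = 8, min_subjects = 85) {
  per_target <- lapply(metrics, function(m) {
    list(mae = m$mae, std_err = m$std_err,
         mae_pass = m$mae <= mae_threshold,
         std_pass = m$std_err <= std_threshold,
         pass = m$mae <= mae_threshold && m$std_err <= std_threshold)
  })
  subjects_pass <- n_subjects >= min_subjects
  structure(list(
    targets = per_target,
    n_subjects = n_subjects,
    subjects_pass = subjects_pass,
    mae_threshold = mae_threshold, std_threshold = std_threshold,
    min_subjects = min_subjects,
    overall_pass = subjects_pass && all(vapply(per_target, `[[`, logical(1), "pass"))
  ), class = "bp_aami")
}

#' @export
print.bp_aami <- function(x, ...) {
  cat(sprintf("%-18s %10s %18s %9s\n", "", "MAE", "Standard Deviation", "Subjects"))
  cat(sprintf("%-18s %10s %18s %9s\n", "AAMI standard",
              sprintf("<=%g mmHg", x$mae_threshold),
              sprintf("<=%g mmHg", x$std_threshold),
              sprintf(">=%d", x$min_subjects)))
  for (t in names(x$targets)) {
    m <- x$targets[[t]]
    cat(sprintf("%-18s %10.2f %18.2f %9s\n", t, m$mae, m$std_err,
                if (t == names(x$targets)[1]) as.character(x$n_subjects) else ""))
  }
  cat(sprintf("Overall: %s\n", if (x$overall_pass) "PASS" else "FAIL"))
  invisible(x)
}
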