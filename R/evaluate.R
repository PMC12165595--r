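# Cohort-level evaluation: accuracy, confidence-calibration MSE/PSNR, and the
# exact binomial lower confidence bound.

#' Exact (Clopper-Pearson) lower binomial confidence bound
#'
#' Lower limit of the two-sided `1 - alpha` exact binomial interval for the
#' success probability after observing `x` successes in `n` trials. For
#' `x = n` this is the closed form `(alpha/2)^(1/n)` (99.6% for 900/900 at
#' `alpha = 0.05`); for `0 < x < n` it is the `alpha/2` quantile of
#' `Beta(x, n - x + 1)`; for `x = 0` it is 0.
#'
#' The interval assumes independent observations. Repeated acquisitions from
#' the same organ are not independent, so for such cohorts the true lower
#' bound is smaller than this value.
#'
#' @param x successes (0..n).
#' @param n trials (>= 1).
#' @param alpha two-sided error level in (0, 1); default 0.05 for a 95%
#'   interval.
#' @return Lower bound as a fraction in \[0, 1\].
#' @export
clopper_pearson_lower <- function(x, n, alpha = 0.05) {
  if (!is.numeric(x) || !is.numeric(n) || length(x) != 1L || length(n) != 1L ||
      !is.finite(x) || !is.finite(n) || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n)) {
    abort_parameter("need integer counts with 0 <= x <= n, n >= 1")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort_parameter("alpha must be in (0, 1)")
  }
  if (x == 0) return(0)
  if (x == n) return((alpha / 2)^(1 / n))
  qbeta(alpha / 2, x, n - x + 1)
}

#' Evaluate a cohort of classifications against the truth
#'
#' Per spectrum, the assigned probability of the true class is
#' `confidence/100` when the label is correct and `1 - confidence/100` when it
#' is wrong, so the per-spectrum error is its deviation from 1:
#' `e = 1 - confidence/100` if correct, `e = confidence/100` if not. The
#' mean-square error is `mean(e^2)` and the peak signal-to-noise ratio is
#' `10 * log10(1 / MSE)` (peak 1 on the probability scale; e.g. MSE 7.4e-3
#' gives 21.3 dB). A perfect cohort (MSE 0) reports `psnr_db = Inf` with
#' `mse_zero = TRUE`. The 95% lower bound on the correct-identification
#' probability comes from [clopper_pearson_lower].
#'
#' @param predictions data.frame with `label` and `confidence` (percent)
#'   columns, as returned by the cohort classifiers.
#' @param truth character vector of true organ labels.
#' @param alpha error level for the exact binomial bound.
#' @return An object of class `cohort_report`: `n`, `n_correct`, `accuracy`,
#'   `mse`, `psnr_db`, `mse_zero`, `ci_lower_95`.
#' @export
evaluate_cohort <- function(predictions, truth, alpha = 0.05) {
  if (is.null(predictions) || NROW(predictions) == 0L) {
    abort_empty("cannot evaluate an empty cohort")
  }
  if (!all(c("label", "confidence") %in% names(predictions))) {
    abort_validation("predictions must have label and confidence columns")
  }
  truth <- as.character(truth)
  if (length(truth) != nrow(predictions)) {
    abort_validation("predictions and truth must have equal length")
  }
  conf <- predictions$confidence
  if (any(!is.finite(conf)) || any(conf <= 0) || any(conf > 100)) {
    abort_validation("confidence must lie in (0, 100]")
  }
  correct <- as.character(predictions$label) == truth
  e <- ifelse(correct, 1 - conf / 100, conf / 100)
  mse <- mean(e^2)
  mse_zero <- mse == 0
  structure(list(
    n = nrow(predictions),
    n_correct = sum(correct),
    accuracy = mean(correct),
    mse = mse,
    psnr_db = if (mse_zero) Inf else 10 * log10(1 / mse),
    mse_zero = mse_zero,
    ci_lower_95 = clopper_pearson_lower(sum(correct), nrow(predictions), alpha),
    alpha = alpha
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d, correct = %d (accuracy %.4f)\n",
              x$n, x$n_correct, x$accuracy))
  cat(sprintf("  MSE = %.4g, PSNR = %s dB%s\n", x$mse,
              if (x$mse_zero) "Inf" else sprintf("%.1f", x$psnr_db),
              if (x$mse_zero) " (MSE exactly zero)" else ""))
  cat(sprintf("  exact %g%% CI lower bound = %.4f\n", 100 * (1 - x$alpha),
              x$ci_lower_95))
  cat("  note: the exact interval assumes independent observations;\n",
      " repeated spectra from one organ violate this, so the true lower\n",
      " bound is smaller.\n", sep = "")
  invisible(x)
}
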