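# Clinical utility: decision curves, Youden cutoff, confusion-matrix
# metrics and score strata, all with Wilson intervals.

#' Wilson score interval for a binomial proportion
#'
#' Inverts the normal-approximation score test, giving an interval that is
#' always inside \[0, 1\], never collapses at 0 or n successes, and always
#' contains the point estimate. Vectorized over `successes` and `n`.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, `> 0`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `successes`, `n`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @examples
#' wilson_ci(9, 26)
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (any(n <= 0)) {
    rlang::abort("`n` must be positive.", class = "preecv_validation_error")
  }
  if (any(successes < 0 | successes > n)) {
    rlang::abort("`successes` must lie in [0, n].",
                 class = "preecv_validation_error")
  }
  z <- stats::qnorm((1 + level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(successes = successes, n = n, estimate = p,
                 conf.low = pmax(0, center - half),
                 conf.high = pmin(1, center + half))
}

#' Confusion-matrix metrics with Wilson intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from
#' the four confusion counts, each with a Wilson interval on its own
#' denominator. A metric with a zero denominator is reported as `NA`
#' (undefined), never as 0.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts (true/false positives,
#'   false/true negatives) for the rule "treat when score above cutoff".
#' @param level Confidence level.
#' @return A tibble with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate`, `conf.low`, `conf.high`.
#' @examples
#' confusion_metrics(tp = 44, fp = 6, fn = 25, tn = 25)
#' @export
confusion_metrics <- function(tp, fp, fn, tn, level = 0.95) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || anyNA(counts)) {
    rlang::abort("Confusion counts must be non-negative.",
                 class = "preecv_validation_error")
  }
  spec <- tibble::tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv"),
    numerator = c(tp, tn, tp, tn),
    denominator = c(tp + fn, tn + fp, tp + fp, tn + fn)
  )
  ci <- purrr::map2_dfr(spec$numerator, spec$denominator, function(s, d) {
    if (d == 0) {
      tibble::tibble(estimate = NA_real_, conf.low = NA_real_,
                     conf.high = NA_real_)
    } else {
      wilson_ci(s, d, level)[, c("estimate", "conf.low", "conf.high")]
    }
  })
  dplyr::bind_cols(spec, ci)
}

# Confusion counts of the rule "positive if score >= cutoff".
confusion_at_cutoff <- function(scores, outcomes, cutoff) {
  pos <- scores >= cutoff
  list(tp = sum(pos & outcomes == 1), fp = sum(pos & outcomes == 0),
       fn = sum(!pos & outcomes == 1), tn = sum(!pos & outcomes == 0))
}

#' Performance report at a score cutoff
#'
#' Confusion counts and derived metrics (with Wilson intervals) of the
#' dichotomized rule "predict success when score is at least `cutoff`",
#' plus the Youden index J = sensitivity + specificity - 1.
#'
#' @param scores Integer score vector.
#' @param outcomes Binary outcome vector.
#' @param cutoff Integer cutoff.
#' @param level Confidence level for the Wilson intervals.
#' @return A one-row tibble: `cutoff`, `tp`, `fp`, `fn`, `tn`, then for each
#'   of sensitivity/specificity/ppv/npv the estimate and its
#'   `.low`/`.high` Wilson bounds, and `youden_j`.
#' @export
threshold_report <- function(scores, outcomes, cutoff, level = 0.95) {
  outcomes <- check_two_classes(outcomes)
  stopifnot(length(scores) == length(outcomes))
  cc <- confusion_at_cutoff(scores, outcomes, cutoff)
  m <- confusion_metrics(cc$tp, cc$fp, cc$fn, cc$tn, level)
  wide <- tibble::as_tibble(c(
    list(cutoff = cutoff), cc,
    stats::setNames(as.list(m$estimate), m$metric),
    stats::setNames(as.list(m$conf.low), paste0(m$metric, ".low")),
    stats::setNames(as.list(m$conf.high), paste0(m$metric, ".high"))
  ))
  wide$youden_j <- wide$sensitivity + wide$specificity - 1
  wide
}

#' Youden-index cutoff selection
#'
#' Evaluates every integer cutoff c from the minimum observed score to one
#' above the maximum (rule: positive when score >= c) and returns the
#' [threshold_report()] at the cutoff maximizing J = sensitivity +
#' specificity - 1; ties are broken toward the largest cutoff.
#'
#' @inheritParams threshold_report
#' @return A one-row tibble as in [threshold_report()], at the selected
#'   cutoff. The full scan is attached as attribute `"scan"`.
#' @examples
#' cohort <- ecv_score(ecv_fixture_cohort())
#' youden_cutoff(cohort$score, cohort$success)
#' @export
youden_cutoff <- function(scores, outcomes, level = 0.95) {
  outcomes <- check_two_classes(outcomes)
  stopifnot(length(scores) == length(outcomes))
  cutoffs <- seq(min(scores), max(scores) + 1)
  scan <- purrr::map_dfr(cutoffs, ~ threshold_report(scores, outcomes, .x, level))
  best <- max(which(scan$youden_j == max(scan$youden_j)))
  out <- scan[best, ]
  attr(out, "scan") <- scan
  out
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model's predicted probability at each
#' threshold probability t, against the "treat all" and "treat none"
#' policies:
#' \deqn{NB_{model}(t) = TP(t)/n - FP(t)/n \cdot t/(1-t)}
#' where a case is treated when its predicted probability is at least t.
#' Treat-none has net benefit 0 everywhere; treat-all equals
#' `prevalence - (1 - prevalence) * t / (1 - t)`.
#'
#' @param predictions Predicted probabilities (from the logistic score
#'   mapping — net benefit is defined on probability thresholds, not raw
#'   scores).
#' @param outcomes Binary outcome vector.
#' @param thresholds Threshold grid, strictly inside (0, 1); default
#'   0.01 to 0.99 by 0.01.
#' @return A tibble of class `ecv_decision_curve`: `threshold`, `nb_model`,
#'   `nb_treat_all`, `nb_treat_none`. Plot with [plot_decision_curve()].
#' @examples
#' cohort <- ecv_score(ecv_fixture_cohort())
#' fit <- fit_logistic(cohort$score, cohort$success)
#' net_benefit(predict_prob(fit, cohort$score), cohort$success)
#' @export
net_benefit <- function(predictions, outcomes,
                        thresholds = seq(0.01, 0.99, by = 0.01)) {
  outcomes <- as.numeric(coerce_flag(outcomes))
  stopifnot(length(predictions) == length(outcomes))
  if (any(thresholds <= 0 | thresholds >= 1)) {
    rlang::abort("Thresholds must lie strictly inside (0, 1).",
                 class = "preecv_validation_error")
  }
  n <- length(outcomes)
  prev <- mean(outcomes)
  nb <- purrr::map_dbl(thresholds, function(t) {
    treated <- predictions >= t
    sum(treated & outcomes == 1) / n -
      sum(treated & outcomes == 0) / n * t / (1 - t)
  })
  out <- tibble::tibble(
    threshold = thresholds,
    nb_model = nb,
    nb_treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
    nb_treat_none = 0
  )
  class(out) <- c("ecv_decision_curve", class(out))
  out
}

default_strata <- function() {
  tibble::tibble(stratum = c("0-4", "5-8", ">=9"),
                 lo = c(0L, 5L, 9L), hi = c(4L, 8L, 13L))
}

#' Observed success rates across score strata
#'
#' Observed outcome rate with a Wilson interval in each score stratum. The
#' default strata are the prespecified low / intermediate / high bands
#' 0-4, 5-8 and >= 9 points, which partition the achievable 0-13 range.
#'
#' @inheritParams threshold_report
#' @param strata A data frame with columns `stratum` (label), `lo`, `hi`
#'   (inclusive integer bounds). Must be non-overlapping, contiguous and
#'   cover every observed score.
#' @param level Confidence level.
#' @return A tibble with one row per stratum: `stratum`, `lo`, `hi`, `n`,
#'   `successes`, `rate`, `conf.low`, `conf.high`. Empty strata have
#'   `n = 0` and `NA` rate.
#' @examples
#' cohort <- ecv_score(ecv_fixture_cohort())
#' strata_rates(cohort$score, cohort$success)
#' @export
strata_rates <- function(scores, outcomes, strata = default_strata(),
                         level = 0.95) {
  outcomes <- as.numeric(coerce_flag(outcomes))
  stopifnot(length(scores) == length(outcomes))
  strata <- dplyr::as_tibble(strata)
  if (!all(c("stratum", "lo", "hi") %in% names(strata))) {
    rlang::abort("`strata` needs columns stratum, lo, hi.",
                 class = "preecv_config_error")
  }
  strata <- dplyr::arrange(strata, .data$lo)
  if (any(strata$hi < strata$lo) ||
      (nrow(strata) > 1 && any(strata$lo[-1] != strata$hi[-nrow(strata)] + 1))) {
    rlang::abort("Strata must be non-overlapping and contiguous.",
                 class = "preecv_config_error")
  }
  if (any(scores < min(strata$lo) | scores > max(strata$hi))) {
    rlang::abort("Strata do not cover every observed score.",
                 class = "preecv_config_error")
  }
  purrr::pmap_dfr(strata, function(stratum, lo, hi) {
    inside <- scores >= lo & scores <= hi
    n <- sum(inside)
    s <- sum(outcomes[inside])
    if (n == 0) {
      tibble::tibble(stratum = stratum, lo = lo, hi = hi, n = 0L,
                     successes = 0L, rate = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_)
    } else {
      ci <- wilson_ci(s, n, level)
      tibble::tibble(stratum = stratum, lo = lo, hi = hi, n = n,
                     successes = s, rate = ci$estimate,
                     conf.low = ci$conf.low, conf.high = ci$conf.high)
    }
  })
}
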