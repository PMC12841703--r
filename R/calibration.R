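# Discrimination (AUC, DeLong variance) and calibration (logistic
# recalibration, decile bins, LOESS curve).

check_two_classes <- function(outcomes, call = rlang::caller_env()) {
  outcomes <- as.numeric(coerce_flag(outcomes))
  if (anyNA(outcomes)) {
    rlang::abort("`outcomes` must be binary with no missing values.",
                 class = "preecv_validation_error", call = call)
  }
  if (length(unique(outcomes)) < 2) {
    rlang::abort("Both outcome classes must be present.",
                 class = "preecv_degenerate_error", call = call)
  }
  outcomes
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly drawn successful case receives a higher
#' prediction than a randomly drawn unsuccessful one, with ties counted
#' one-half — equivalent to the trapezoidal area under the empirical ROC
#' curve. Computed from midranks, so it depends only on the ordering of the
#' predictions.
#'
#' @param predictions Numeric vector (probabilities or any risk score).
#' @param outcomes Binary vector, same length; both classes required.
#' @return The AUC, a number in \[0, 1\].
#' @examples
#' auc_mann_whitney(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc_mann_whitney <- function(predictions, outcomes) {
  outcomes <- check_two_classes(outcomes)
  stopifnot(length(predictions) == length(outcomes))
  pos <- outcomes == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(predictions, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

# DeLong placement values: for each case, the fraction of the other class
# it outranks (ties one-half).
delong_placements <- function(predictions, outcomes) {
  pos <- outcomes == 1
  x <- predictions[pos]
  y <- predictions[!pos]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with a DeLong (or bootstrap-percentile) confidence interval
#'
#' The DeLong method estimates the AUC sampling variance from the empirical
#' variance of the per-case placement values, giving a Wald interval without
#' distributional assumptions on the predictions. A bootstrap-percentile
#' interval over case resampling is available as an alternative
#' (`method = "bootstrap_percentile"`). The Wald interval is built on the
#' AUC scale and truncated to \[0, 1\] by default; `scale = "logit"`
#' constructs it on the log-odds scale and back-transforms, which respects
#' the bounds without truncation.
#'
#' @inheritParams auc_mann_whitney
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"bootstrap_percentile"`.
#' @param scale CI scale for the DeLong interval: `"auc"` (default) or
#'   `"logit"`.
#' @param n_boot Bootstrap resamples when `method = "bootstrap_percentile"`.
#' @return A one-row tibble: `auc`, `se_delong`, `conf.low`, `conf.high`,
#'   `level`, `method`, `n_pos`, `n_neg`.
#' @examples
#' cohort <- ecv_score(ecv_fixture_cohort())
#' delong_ci(cohort$score, cohort$success)
#' @export
delong_ci <- function(predictions, outcomes, level = 0.95,
                      method = c("delong", "bootstrap_percentile"),
                      scale = c("auc", "logit"), n_boot = 2000) {
  method <- rlang::arg_match(method)
  scale <- rlang::arg_match(scale)
  outcomes <- check_two_classes(outcomes)
  stopifnot(length(predictions) == length(outcomes))
  if (min(sum(outcomes == 1), sum(outcomes == 0)) < 2) {
    rlang::abort("Each outcome class needs at least 2 members for a variance.",
                 class = "preecv_degenerate_error")
  }
  pl <- delong_placements(predictions, outcomes)
  auc <- mean(pl$v10)
  se <- sqrt(stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n)
  z <- stats::qnorm((1 + level) / 2)
  if (method == "delong") {
    if (scale == "auc" || se == 0 || auc <= 0 || auc >= 1) {
      lo <- max(0, auc - z * se)
      hi <- min(1, auc + z * se)
    } else {
      se_logit <- se / (auc * (1 - auc))
      lo <- stats::plogis(stats::qlogis(auc) - z * se_logit)
      hi <- stats::plogis(stats::qlogis(auc) + z * se_logit)
    }
  } else {
    idx <- seq_along(outcomes)
    aucs <- purrr::map_dbl(seq_len(n_boot), function(i) {
      b <- sample(idx, replace = TRUE)
      if (length(unique(outcomes[b])) < 2) return(NA_real_)
      auc_mann_whitney(predictions[b], outcomes[b])
    })
    qs <- stats::quantile(aucs, c((1 - level) / 2, (1 + level) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- qs[1]
    hi <- qs[2]
  }
  tibble::tibble(auc = auc, se_delong = se, conf.low = lo, conf.high = hi,
                 level = level, method = method, n_pos = pl$m, n_neg = pl$n)
}

#' Logistic recalibration: calibration intercept and slope
#'
#' Regresses the observed outcomes on the log-odds of the predictions. The
#' calibration slope is the maximum-likelihood slope of that logistic
#' regression (ideal 1; below 1 indicates predictions too extreme). The
#' calibration intercept — calibration-in-the-large — is the intercept of a
#' logistic model with the prediction log-odds entered as a fixed offset,
#' i.e. with the slope held at 1 (ideal 0; negative means the model
#' overestimates risk on average).
#'
#' @param predictions Probabilities strictly inside (0, 1).
#' @param outcomes Binary vector, both classes present.
#' @return A one-row tibble with `cal_intercept` and `cal_slope`.
#' @examples
#' cohort <- ecv_score(ecv_fixture_cohort())
#' fit <- fit_logistic(cohort$score, cohort$success)
#' recalibrate(predict_prob(fit, cohort$score), cohort$success) # ~ (0, 1)
#' @export
recalibrate <- function(predictions, outcomes) {
  outcomes <- check_two_classes(outcomes)
  stopifnot(length(predictions) == length(outcomes))
  if (any(predictions <= 0 | predictions >= 1)) {
    rlang::abort("Predictions must lie strictly inside (0, 1): logit is undefined at 0/1.",
                 class = "preecv_validation_error")
  }
  lp <- stats::qlogis(predictions)
  slope_fit <- logistic_mle(cbind(1, lp), outcomes)
  intercept_fit <- logistic_mle(matrix(1, length(outcomes)), outcomes, offset = lp)
  tibble::tibble(cal_intercept = intercept_fit$coef[1],
                 cal_slope = slope_fit$coef[2])
}

#' Equal-count calibration bins
#'
#' Groups observations into `n_bins` equal-count bins of predicted risk
#' (deciles by default) and reports the mean prediction and observed outcome
#' proportion per bin — the points of a binned calibration plot. Tied
#' predictions are kept together in one bin, so heavy ties can leave some
#' bins empty; those are returned with `n = 0` and flagged.
#'
#' @inheritParams recalibrate
#' @param n_bins Number of bins (default 10); the cohort must be at least
#'   this large.
#' @return A tibble with one row per bin: `bin`, `n`, `pred_mean`,
#'   `obs_rate`, `empty`.
#' @export
calibration_bins <- function(predictions, outcomes, n_bins = 10) {
  outcomes <- as.numeric(outcomes)
  n <- length(predictions)
  stopifnot(length(outcomes) == n)
  if (n < n_bins) {
    rlang::abort("Fewer observations than bins.",
                 class = "preecv_validation_error")
  }
  r <- rank(predictions, ties.method = "min")
  bin <- ceiling(r * n_bins / n)
  agg <- tibble::tibble(bin = bin, pred = predictions, y = outcomes) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), pred_mean = mean(.data$pred),
                     obs_rate = mean(.data$y), .groups = "drop")
  dplyr::left_join(tibble::tibble(bin = seq_len(n_bins)), agg, by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  empty = .data$n == 0L)
}

#' LOESS-smoothed calibration curve
#'
#' Locally weighted linear regression (degree 1, tricube weights,
#' neighborhood fraction `span`) of the binary outcome on the predicted
#' probability, evaluated on the sorted grid of distinct observed
#' predictions. A well-calibrated model tracks the 45-degree line.
#' Smoothed values are clipped to \[0, 1\].
#'
#' @inheritParams recalibrate
#' @param span Neighborhood fraction in (0, 1\]; default 0.75.
#' @return A tibble with columns `pred` (grid) and `smoothed`.
#' @export
loess_curve <- function(predictions, outcomes, span = 0.75) {
  outcomes <- as.numeric(outcomes)
  if (length(predictions) < 10) {
    rlang::abort("At least 10 observations are required for the LOESS curve.",
                 class = "preecv_validation_error")
  }
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1) {
    rlang::abort("`span` must lie in (0, 1].",
                 class = "preecv_validation_error")
  }
  d <- data.frame(pred = as.numeric(predictions), y = outcomes)
  fit <- stats::loess(y ~ pred, data = d, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- sort(unique(d$pred))
  smoothed <- stats::predict(fit, newdata = data.frame(pred = grid))
  tibble::tibble(pred = grid, smoothed = pmin(1, pmax(0, smoothed)))
}
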