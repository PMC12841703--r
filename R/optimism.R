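# Bootstrap optimism correction (Harrell internal validation) of AUC and
# the two recalibration metrics.

optimism_metrics <- c("auc", "cal_intercept", "cal_slope")

# Evaluate `code` under a fixed seed, leaving the caller's RNG state intact.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

apparent_performance <- function(scores, outcomes) {
  fit <- fit_logistic(scores, outcomes)
  preds <- predict_prob(fit, scores)
  cal <- recalibrate(preds, outcomes)
  c(auc = auc_mann_whitney(preds, outcomes),
    cal_intercept = cal$cal_intercept, cal_slope = cal$cal_slope)
}

#' Bootstrap optimism correction of model performance
#'
#' Internal validation of the score-to-probability model by the bootstrap
#' optimism procedure: in each resample (drawn with replacement, same size
#' as the cohort) the logistic score model is refitted; each performance
#' metric (AUC, calibration intercept, calibration slope) is evaluated both
#' within the resample and — using the resample-fitted model's predictions —
#' on the original cohort. The difference (boot minus test) is that
#' resample's optimism; the corrected metric is the apparent value minus the
#' mean optimism. Apparent calibration of a model evaluated on its own
#' training data is perfect by construction (intercept 0, slope 1), which is
#' exactly why the correction is needed.
#'
#' Resamples whose outcomes collapse to a single class, or in which the
#' refit or recalibration separates, are skipped (never redrawn) and
#' counted by reason.
#'
#' @param cohort A cohort table; a `score` column is added via [ecv_score()]
#'   if absent.
#' @param n_resamples Number of bootstrap resamples (default 2000).
#' @param seed Integer seed; recorded in the report. The global RNG state is
#'   restored on exit.
#' @param level Confidence level for the percentile intervals.
#' @param resample Set `FALSE` to run the degenerate diagnostic mode in
#'   which every "resample" is the original cohort itself; all optimisms are
#'   then exactly zero.
#' @return An object of class `ecv_optimism`:
#'   * `summary`: tibble with one row per metric — `apparent`,
#'     `mean_optimism`, `corrected = apparent - mean_optimism`, `conf.low`/
#'     `conf.high` (percentile interval of the test-performance distribution
#'     shifted to the corrected location) and `pct.low`/`pct.high` (raw
#'     percentile interval of the per-resample corrected values);
#'   * `distributions`: long tibble of per-resample `boot`, `test` and
#'     `optimism` values per metric;
#'   * `n_resamples_requested`, `n_resamples_used`, `skipped` (tibble of
#'     reasons), `seed`, `level`.
#'
#'   `tidy()` returns `summary`; `glance()` the resample bookkeeping.
#' @examples
#' opt <- optimism_correct(ecv_fixture_cohort(), n_resamples = 50, seed = 1)
#' tidy(opt)
#' @export
optimism_correct <- function(cohort, n_resamples = 2000, seed = 1,
                             level = 0.95, resample = TRUE) {
  cohort <- validate_cohort(cohort)
  if (!"score" %in% names(cohort)) cohort <- ecv_score(cohort)
  scores <- cohort$score
  outcomes <- as.numeric(cohort$success)
  check_two_classes(outcomes)
  n <- length(outcomes)

  apparent <- apparent_performance(scores, outcomes)

  skip_reasons <- character(0)
  rows <- with_seed(seed, {
    out <- vector("list", n_resamples)
    for (b in seq_len(n_resamples)) {
      idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
      res <- tryCatch({
        fit_b <- fit_logistic(scores[idx], outcomes[idx])
        preds_boot <- predict_prob(fit_b, scores[idx])
        cal_boot <- recalibrate(preds_boot, outcomes[idx])
        boot <- c(auc = auc_mann_whitney(preds_boot, outcomes[idx]),
                  cal_intercept = cal_boot$cal_intercept,
                  cal_slope = cal_boot$cal_slope)
        preds_test <- predict_prob(fit_b, scores)
        cal_test <- recalibrate(preds_test, outcomes)
        test <- c(auc = auc_mann_whitney(preds_test, outcomes),
                  cal_intercept = cal_test$cal_intercept,
                  cal_slope = cal_test$cal_slope)
        boot <- unname(boot[optimism_metrics])
        test <- unname(test[optimism_metrics])
        tibble::tibble(resample = b, metric = optimism_metrics,
                       boot = boot, test = test, optimism = boot - test)
      },
      preecv_degenerate_error = function(e) "single_class",
      preecv_separation_error = function(e) "separation")
      if (is.character(res)) {
        skip_reasons <- c(skip_reasons, res)
        out[b] <- list(NULL)
      } else {
        out[[b]] <- res
      }
    }
    out
  })
  dist <- dplyr::bind_rows(rows)
  used <- length(unique(dist$resample))
  if (used == 0) {
    rlang::abort("Every bootstrap resample was degenerate; cannot estimate optimism.",
                 class = "preecv_degenerate_error")
  }

  alpha <- (1 - level) / 2
  summary <- dist |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean_optimism = mean(.data$optimism),
      test_lo = stats::quantile(.data$test, alpha, names = FALSE),
      test_hi = stats::quantile(.data$test, 1 - alpha, names = FALSE),
      test_mean = mean(.data$test),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      metric = factor(.data$metric, levels = optimism_metrics),
      apparent = unname(apparent[as.character(.data$metric)]),
      corrected = .data$apparent - .data$mean_optimism,
      conf.low = .data$test_lo - .data$test_mean + .data$corrected,
      conf.high = .data$test_hi - .data$test_mean + .data$corrected
    ) |>
    dplyr::arrange(.data$metric)
  pct <- dist |>
    dplyr::mutate(corrected_b = unname(apparent[.data$metric]) - .data$optimism) |>
    dplyr::group_by(metric = factor(.data$metric, levels = optimism_metrics)) |>
    dplyr::summarise(pct.low = stats::quantile(.data$corrected_b, alpha, names = FALSE),
                     pct.high = stats::quantile(.data$corrected_b, 1 - alpha, names = FALSE),
                     .groups = "drop")
  summary <- summary |>
    dplyr::left_join(pct, by = "metric") |>
    dplyr::mutate(metric = as.character(.data$metric)) |>
    dplyr::select("metric", "apparent", "mean_optimism", "corrected",
                  "conf.low", "conf.high", "pct.low", "pct.high")

  structure(
    list(summary = summary, distributions = dist,
         n_resamples_requested = n_resamples, n_resamples_used = used,
         skipped = dplyr::count(tibble::tibble(reason = skip_reasons),
                                .data$reason, name = "n"),
         seed = as.integer(seed), level = level, n = n),
    class = "ecv_optimism"
  )
}

#' @export
print.ecv_optimism <- function(x, ...) {
  cat(sprintf(
    "Bootstrap optimism correction: %d/%d resamples used (seed %d, n = %d)\n",
    x$n_resamples_used, x$n_resamples_requested, x$seed, x$n))
  if (nrow(x$skipped) > 0) {
    cat("  skipped:",
        paste(sprintf("%s (%d)", x$skipped$reason, x$skipped$n), collapse = ", "),
        "\n")
  }
  print(x$summary)
  invisible(x)
}

#' @rdname optimism_correct
#' @param x An `ecv_optimism` object.
#' @param ... Unused.
#' @export
tidy.ecv_optimism <- function(x, ...) x$summary

#' @rdname optimism_correct
#' @export
glance.ecv_optimism <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_resamples_requested = x$n_resamples_requested,
    n_resamples_used = x$n_resamples_used,
    n_skipped = x$n_resamples_requested - x$n_resamples_used,
    seed = x$seed, level = x$level
  )
}
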