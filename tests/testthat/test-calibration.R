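test_that("AUC handles separation, ties and the worked 4-point example", {
  expect_equal(auc_mann_whitney(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc_mann_whitney(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  preds <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(0, 0, 1, 1)
  expect_equal(auc_mann_whitney(preds, y), 0.75)   # 3 of 4 pairs concordant
  expect_equal(auc_mann_whitney(preds, y), brute_auc(preds, y))
  expect_error(auc_mann_whitney(1:3, c(1, 1, 1)),
               class = "preecv_degenerate_error")
})

test_that("AUC equals exhaustive pair counting on random small datasets", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    preds <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_mann_whitney(preds, y), brute_auc(preds, y))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(12)
  preds <- runif(60)
  y <- rbinom(60, 1, preds)
  base <- auc_mann_whitney(preds, y)
  expect_equal(auc_mann_whitney(exp(preds), y), base)
  expect_equal(auc_mann_whitney(qlogis(preds), y), base)
  expect_equal(auc_mann_whitney(preds^3, y), base)
})

test_that("DeLong interval behaves at the degenerate extremes", {
  d <- delong_ci(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(d$auc, 1.0)
  expect_equal(d$se_delong, 0)
  # symmetric dataset: AUC exactly 0.5, interval centered on it
  d2 <- delong_ci(c(1, 2, 3, 4), c(0, 1, 1, 0))
  expect_equal(d2$auc, 0.5)
  expect_equal(d2$conf.low + d2$conf.high, 1)
  expect_error(delong_ci(1:3, c(0, 1, 1)), class = "preecv_degenerate_error")
})

test_that("DeLong variance agrees with bootstrap and reference implementations", {
  set.seed(13)
  n <- 40
  preds <- runif(n)
  y <- rbinom(n, 1, plogis(3 * (preds - 0.5)))
  while (min(sum(y), n - sum(y)) < 5) y <- rbinom(n, 1, plogis(3 * (preds - 0.5)))
  d <- delong_ci(preds, y)

  boot_aucs <- replicate(10000, {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) NA_real_ else
      auc_mann_whitney(preds[idx], y[idx])
  })
  expect_lt(abs(d$se_delong - sd(boot_aucs, na.rm = TRUE)) / d$se_delong, 0.15)

  skip_if_not_installed("pROC")
  ref <- pROC::roc(y, preds, quiet = TRUE, direction = "<")
  expect_equal(d$auc, as.numeric(pROC::auc(ref)))
  expect_equal(d$se_delong, sqrt(pROC::var(ref, method = "delong")),
               tolerance = 1e-10)
})

test_that("bootstrap-percentile CI variant brackets the point estimate", {
  set.seed(14)
  preds <- runif(80)
  y <- rbinom(80, 1, plogis(2 * (preds - 0.4)))
  d <- delong_ci(preds, y, method = "bootstrap_percentile", n_boot = 500)
  expect_identical(d$method, "bootstrap_percentile")
  expect_true(d$conf.low <= d$auc && d$auc <= d$conf.high)
})

test_that("recalibration of self-fitted predictions is the identity (0, 1)", {
  co <- ecv_score(ecv_fixture_cohort())
  fit <- fit_logistic(co$score, co$success)
  cal <- recalibrate(predict_prob(fit, co$score), co$success)
  expect_equal(cal$cal_intercept, 0, tolerance = 1e-6)
  expect_equal(cal$cal_slope, 1, tolerance = 1e-6)
})

test_that("doubling the prediction log-odds halves the calibration slope", {
  set.seed(15)
  preds <- plogis(rnorm(120))
  y <- rbinom(120, 1, preds)
  base <- recalibrate(preds, y)
  doubled <- recalibrate(plogis(2 * qlogis(preds)), y)
  expect_equal(doubled$cal_slope, base$cal_slope / 2, tolerance = 1e-6)
})

test_that("recalibration rejects constant or boundary predictions", {
  y <- rep(c(0, 1), 10)
  expect_error(recalibrate(rep(0.6, 20), y), class = "preecv_separation_error")
  expect_error(recalibrate(c(0, runif(19)), y),
               class = "preecv_validation_error")
  expect_error(recalibrate(c(1, runif(19)), y),
               class = "preecv_validation_error")
})

test_that("calibration bins are equal-count, tie-safe and cover the cohort", {
  set.seed(16)
  preds <- runif(100)
  y <- rbinom(100, 1, preds)
  bins <- calibration_bins(preds, y, 10)
  expect_identical(nrow(bins), 10L)
  expect_true(all(bins$n == 10))
  expect_identical(sum(bins$n), 100L)
  expect_true(all(diff(bins$pred_mean) > 0))

  tied <- calibration_bins(rep(0.3, 50), rbinom(50, 1, 0.3), 10)
  expect_identical(sum(!tied$empty), 1L)
  expect_identical(sum(tied$n), 50L)

  expect_error(calibration_bins(runif(5), rbinom(5, 1, 0.5), 10),
               class = "preecv_validation_error")
})

test_that("bins track the diagonal for perfectly calibrated data", {
  set.seed(17)
  n <- 20000
  preds <- runif(n)
  y <- rbinom(n, 1, preds)
  bins <- calibration_bins(preds, y, 10)
  err <- abs(bins$obs_rate - bins$pred_mean)
  se3 <- 3 * sqrt(bins$pred_mean * (1 - bins$pred_mean) / bins$n)
  expect_true(all(err <= se3))
})

test_that("LOESS curve is exact on linear data and constant on constants", {
  set.seed(18)
  preds <- runif(40)
  linear <- 0.2 + 0.5 * preds
  curve <- loess_curve(preds, linear)
  expect_equal(curve$smoothed, 0.2 + 0.5 * curve$pred, tolerance = 1e-6)

  const <- loess_curve(preds, rep(1, 40))
  expect_true(all(abs(const$smoothed - 1) < 1e-8))

  expect_error(loess_curve(runif(5), rbinom(5, 1, 0.5)),
               class = "preecv_validation_error")
  expect_error(loess_curve(preds, linear, span = 0),
               class = "preecv_validation_error")
  expect_error(loess_curve(preds, linear, span = 1.5),
               class = "preecv_validation_error")
})

test_that("LOESS value matches a direct tricube weighted least squares", {
  set.seed(19)
  n <- 12
  preds <- runif(n)
  y <- rbinom(n, 1, preds)
  span <- 0.75
  curve <- loess_curve(preds, y, span = span)
  x0 <- sort(preds)[6]
  # independent single-point oracle: tricube weights over the span-fraction
  # neighborhood, then one weighted linear solve
  q <- floor(span * n + 1e-9)
  d <- abs(preds - x0)
  w <- pmax(0, 1 - (d / sort(d)[q])^3)^3
  wls <- lm(y ~ preds, weights = w)
  expect_equal(curve$smoothed[curve$pred == x0],
               min(1, max(0, unname(predict(wls, data.frame(preds = x0))))),
               tolerance = 1e-8)
})
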