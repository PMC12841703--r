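test_that("Wilson interval: boundaries, symmetry and the closed form", {
  lo0 <- wilson_ci(0, 20)
  expect_equal(lo0$conf.low, 0)
  expect_gt(lo0$conf.high, 0)
  hi0 <- wilson_ci(20, 20)
  expect_equal(hi0$conf.high, 1)

  half <- wilson_ci(15, 30)
  expect_equal(half$conf.low + half$conf.high, 1)  # symmetric about 0.5

  w <- wilson_ci(9, 26)
  oracle <- wilson_oracle(9, 26)
  expect_equal(c(w$conf.low, w$conf.high), oracle, tolerance = 1e-10)
  ref <- prop.test(9, 26, correct = FALSE)$conf.int
  expect_equal(c(w$conf.low, w$conf.high), as.numeric(ref), tolerance = 1e-10)
  expect_true(w$conf.low <= w$estimate && w$estimate <= w$conf.high)

  expect_error(wilson_ci(1, 0), class = "preecv_validation_error")
  expect_error(wilson_ci(5, 3), class = "preecv_validation_error")
})

test_that("Wilson interval coverage sits near nominal at n = 30, p = 0.7", {
  # exact coverage by enumeration over the binomial outcome space: at
  # n = 30, p = 0.7 the Wilson interval covers with probability 0.92979,
  # within 2.5 points of nominal; the Monte-Carlo estimate must agree with
  # the enumeration within 3 simulation SEs
  k <- 0:30
  ek <- t(vapply(k, wilson_oracle, numeric(2), n = 30))
  exact <- sum(dbinom(k, 30, 0.7)[ek[, 1] <= 0.7 & 0.7 <= ek[, 2]])
  expect_lt(abs(exact - 0.95), 0.025)

  set.seed(31)
  x <- rbinom(20000, 30, 0.7)
  ci <- wilson_ci(x, 30)
  coverage <- mean(ci$conf.low <= 0.7 & 0.7 <= ci$conf.high)
  expect_lt(abs(coverage - exact), 3 * sqrt(exact * (1 - exact) / 20000))
})

test_that("confusion metrics: published reconstruction, symmetry, undefined cells", {
  # reconstruction from the printed sensitivity/specificity and outcome
  # totals (69 successes, 31 failures at the >=9 cutoff):
  # tp = 44, fn = 25, tn = 25, fp = 6
  m <- confusion_metrics(tp = 44, fp = 6, fn = 25, tn = 25)
  expect_equal(m$estimate[m$metric == "ppv"], 0.88)
  expect_equal(m$estimate[m$metric == "npv"], 0.50)
  expect_equal(m$estimate[m$metric == "sensitivity"], 44 / 69)
  expect_equal(m$estimate[m$metric == "specificity"], 25 / 31)

  sym <- confusion_metrics(25, 25, 25, 25)
  expect_equal(sym$estimate, rep(0.5, 4))

  und <- confusion_metrics(tp = 0, fp = 0, fn = 3, tn = 5)
  expect_true(is.na(und$estimate[und$metric == "ppv"]))
  expect_false(is.na(und$estimate[und$metric == "npv"]))
  expect_error(confusion_metrics(-1, 0, 0, 1),
               class = "preecv_validation_error")
})

test_that("threshold report counts partition the cohort", {
  set.seed(32)
  scores <- sample(0:13, 50, replace = TRUE)
  y <- rbinom(50, 1, plogis(-2 + 0.4 * scores))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  rep9 <- threshold_report(scores, y, 9)
  expect_identical(rep9$tp + rep9$fn, sum(y == 1))
  expect_identical(rep9$fp + rep9$tn, sum(y == 0))
  expect_equal(rep9$youden_j, rep9$sensitivity + rep9$specificity - 1)
  expect_true(rep9$youden_j >= -1 && rep9$youden_j <= 1)
})

test_that("Youden cutoff: separation, worked example, tie toward largest", {
  sep <- youden_cutoff(c(1, 2, 3, 8, 9, 10), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$youden_j, 1)
  expect_identical(as.integer(sep$cutoff), 8L)

  scores <- 1:6
  y <- c(0, 0, 1, 0, 1, 1)
  oracle <- brute_youden(scores, y)
  got <- youden_cutoff(scores, y)
  expect_equal(as.integer(got$cutoff), as.integer(oracle$cutoff))
  expect_equal(got$youden_j, oracle$j)

  # all cutoffs give J = 0: the largest must win
  tie <- youden_cutoff(c(1, 2), c(1, 0))
  expect_identical(as.integer(tie$cutoff), 3L)
})

test_that("Youden cutoff agrees with enumeration on random datasets", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- sample(0:13, n, replace = TRUE)
    y <- rbinom(n, 1, plogis(-1.5 + 0.3 * scores))
    if (length(unique(y)) < 2) next
    oracle <- brute_youden(scores, y)
    got <- youden_cutoff(scores, y)
    expect_equal(as.integer(got$cutoff), as.integer(oracle$cutoff))
    expect_equal(got$youden_j, oracle$j)
  }
})

test_that("outcome independent of score yields near-zero maximal J", {
  set.seed(34)
  scores <- sample(0:13, 4000, replace = TRUE)
  y <- rbinom(4000, 1, 0.5)
  expect_lt(youden_cutoff(scores, y)$youden_j, 0.08)
})

test_that("net benefit: treat-none, closed-form treat-all, perfect model", {
  y <- c(rep(1, 69), rep(0, 31))
  preds <- ifelse(y == 1, 0.9, 0.1)
  dc <- net_benefit(preds, y)
  expect_true(all(dc$nb_treat_none == 0))
  at_half <- dc[abs(dc$threshold - 0.5) < 1e-9, ]
  expect_equal(at_half$nb_treat_all, 0.69 - 0.31, tolerance = 1e-12)
  expect_equal(at_half$nb_treat_all,
               0.69 - 0.31 * 0.5 / (1 - 0.5), tolerance = 1e-12)
  # perfect classifier: nb_model = prevalence wherever 0.1 < t <= 0.9
  inner <- dc$threshold > 0.1 & dc$threshold <= 0.9
  expect_true(all(abs(dc$nb_model[inner] - 0.69) < 1e-12))

  expect_error(net_benefit(preds, y, thresholds = c(0, 0.5)),
               class = "preecv_validation_error")
  expect_error(net_benefit(preds, y, thresholds = c(0.5, 1)),
               class = "preecv_validation_error")
})

test_that("net benefit never exceeds prevalence; equals treat-all under full treatment", {
  set.seed(35)
  y <- rbinom(200, 1, 0.69)
  preds <- runif(200)
  dc <- net_benefit(preds, y)
  expect_true(all(dc$nb_model <= mean(y) + 1e-12))
  # when every prediction clears the threshold, model == treat-all
  dc2 <- net_benefit(rep(0.95, 200), y, thresholds = seq(0.05, 0.9, 0.05))
  expect_equal(dc2$nb_model, dc2$nb_treat_all, tolerance = 1e-12)
})

test_that("strata rates: hand count, empty strata, misconfiguration", {
  out <- strata_rates(c(2, 2, 6, 6, 10, 10), c(0, 1, 1, 1, 1, 1))
  expect_equal(out$rate, c(0.5, 1, 1))
  expect_identical(out$n, c(2L, 2L, 2L))
  expect_identical(sum(out$n), 6L)
  for (i in 1:3) {
    o <- wilson_oracle(out$successes[i], out$n[i])
    expect_equal(c(out$conf.low[i], out$conf.high[i]), o, tolerance = 1e-10)
  }

  one <- strata_rates(c(1, 2, 3), c(1, 0, 1))
  expect_identical(one$n, c(3L, 0L, 0L))
  expect_true(all(is.na(one$rate[2:3])))

  overlapping <- tibble::tibble(stratum = c("a", "b"), lo = c(0L, 3L),
                                hi = c(4L, 13L))
  expect_error(strata_rates(c(1, 5), c(0, 1), overlapping),
               class = "preecv_config_error")
  gap <- tibble::tibble(stratum = c("a", "b"), lo = c(0L, 6L), hi = c(4L, 13L))
  expect_error(strata_rates(c(1, 5), c(0, 1), gap),
               class = "preecv_config_error")
  short <- tibble::tibble(stratum = "a", lo = 0L, hi = 4L)
  expect_error(strata_rates(c(1, 9), c(0, 1), short),
               class = "preecv_config_error")
})

test_that("stratum rates are non-decreasing under a monotone outcome model", {
  co <- generate_cohort(20000, seed = 36, slope = 0.55,
                        target_prevalence = 0.69)
  out <- strata_rates(co$score, co$success)
  expect_true(all(diff(out$rate) > 0))
})
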