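# Synthetic ECV cohorts: Gaussian-copula predictors with the published
# marginal prevalences, latent logistic outcome on the total score.

#' Default predictor marginals
#'
#' Prevalence of each predictor in the overall column of the published
#' baseline table: multiparity 0.55; presentation transverse 0.08 /
#' complete breech 0.16 / frank breech 0.76; non-engagement 0.36; palpable
#' head 0.69; EFW at or above the 10th percentile 0.80; MVP at or above
#' 4 cm 0.86; posterior placenta 0.49; tocolysis 0.65.
#'
#' @return A named list: scalar probabilities for the binary predictors
#'   (given for the score-positive value, e.g. `non_engaged`) and a named
#'   3-vector `presentation` summing to 1.
#' @export
ecv_default_marginals <- function() {
  list(
    multiparous = 0.55,
    presentation = c(transverse = 0.08, complete_breech = 0.16,
                     frank_breech = 0.76),
    non_engaged = 0.36,
    palpable_head = 0.69,
    efw_ge_10th = 0.80,
    mvp_ge_4cm = 0.86,
    placenta_posterior = 0.49,
    tocolysis = 0.65
  )
}

validate_marginals <- function(m) {
  expected <- names(ecv_default_marginals())
  if (!setequal(names(m), expected)) {
    rlang::abort(paste0("Marginals must be named: ",
                        paste(expected, collapse = ", "), "."),
                 class = "preecv_config_error")
  }
  probs <- unlist(m[setdiff(expected, "presentation")])
  if (any(probs <= 0 | probs >= 1)) {
    rlang::abort("All marginal probabilities must lie in (0, 1).",
                 class = "preecv_config_error")
  }
  pres <- m$presentation
  if (length(pres) != 3 || any(pres <= 0) || abs(sum(pres) - 1) > 1e-8) {
    rlang::abort("Presentation marginals must be 3 positive values summing to 1.",
                 class = "preecv_config_error")
  }
  m
}

#' Generate a synthetic ECV cohort
#'
#' Draws predictor profiles whose marginal prevalences match the published
#' overall column (by default; see [ecv_default_marginals()]) and a binary
#' outcome from a latent logistic model on the total score,
#' `P(success) = plogis(intercept + slope * score)`.
#'
#' The clinically linked trio — non-engagement, palpable fetal head and
#' adequate amniotic fluid — is drawn through a Gaussian copula with
#' exchangeable latent correlation `rho`, so their score-positive values
#' cluster as the near-deterministic published margins suggest; all other
#' predictors are independent. Exactly one of `intercept` and
#' `target_prevalence` must be supplied: with `target_prevalence`, the
#' intercept is solved by bisection so that the expected success rate over
#' the realized score distribution matches the target within 1e-6. The
#' default target of 0.69 is the published overall success rate.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @param marginals Predictor marginals, as [ecv_default_marginals()].
#' @param rho Latent exchangeable correlation of the linked trio, in
#'   \[0, 1).
#' @param slope Log-odds of success per score point (default 0.55).
#' @param intercept Log-odds of success at score 0, or `NULL` to solve from
#'   `target_prevalence`.
#' @param target_prevalence Expected success rate to calibrate the
#'   intercept to, or `NULL` when `intercept` is given. Default 0.69.
#' @return A validated cohort tibble of `n` rows with a `score` column.
#'   Attributes `outcome_intercept` and `outcome_slope` record the latent
#'   model actually used.
#' @examples
#' cohort <- generate_cohort(200, seed = 42)
#' mean(cohort$success)
#' @export
generate_cohort <- function(n, seed, marginals = ecv_default_marginals(),
                            rho = 0.6, slope = 0.55, intercept = NULL,
                            target_prevalence = if (is.null(intercept)) 0.69) {
  m <- validate_marginals(marginals)
  if (!is.null(intercept) && !is.null(target_prevalence)) {
    rlang::abort("Supply exactly one of `intercept` and `target_prevalence`.",
                 class = "preecv_config_error")
  }
  if (is.null(intercept) && is.null(target_prevalence)) {
    rlang::abort("Supply one of `intercept` and `target_prevalence`.",
                 class = "preecv_config_error")
  }
  if (!is.null(target_prevalence) &&
      (target_prevalence <= 0 || target_prevalence >= 1)) {
    rlang::abort("`target_prevalence` must lie strictly inside (0, 1).",
                 class = "preecv_config_error")
  }
  if (rho < 0 || rho >= 1) {
    rlang::abort("`rho` must lie in [0, 1).", class = "preecv_config_error")
  }
  stopifnot(n >= 1)

  with_seed(seed, {
    # linked trio via a Gaussian copula: each flag is TRUE when its latent
    # normal falls below the quantile of its marginal, so positive latent
    # correlation clusters the score-positive values together
    sigma <- matrix(rho, 3, 3)
    diag(sigma) <- 1
    z <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(sigma)
    trio_p <- c(m$non_engaged, m$palpable_head, m$mvp_ge_4cm)
    trio <- sweep(z, 2, stats::qnorm(trio_p), "<")

    pres_cut <- cumsum(m$presentation)
    u <- stats::runif(n)
    presentation <- names(m$presentation)[findInterval(u, pres_cut) + 1]

    profiles <- tibble::tibble(
      id = sprintf("s%06d", seq_len(n)),
      parity = ifelse(stats::runif(n) < m$multiparous,
                      "multiparous", "nulliparous"),
      presentation = presentation,
      engaged = !trio[, 1],
      palpable_head = trio[, 2],
      efw_ge_10th = stats::runif(n) < m$efw_ge_10th,
      mvp_ge_4cm = trio[, 3],
      placenta_posterior = stats::runif(n) < m$placenta_posterior,
      tocolysis = stats::runif(n) < m$tocolysis
    )
    profiles <- ecv_score(profiles)

    if (is.null(intercept)) {
      intercept <- solve_intercept(profiles$score, slope, target_prevalence)
    }
    p <- stats::plogis(intercept + slope * profiles$score)
    profiles$success <- stats::runif(n) < p

    out <- validate_cohort(profiles)
    attr(out, "outcome_intercept") <- intercept
    attr(out, "outcome_slope") <- slope
    out
  })
}

# Bisection for the intercept giving the target expected prevalence over
# the realized scores.
solve_intercept <- function(scores, slope, target, tol = 1e-6) {
  f <- function(a) mean(stats::plogis(a + slope * scores)) - target
  lo <- -60
  hi <- 60
  if (f(lo) > 0 || f(hi) < 0) {
    rlang::abort("Target prevalence is unachievable for the given slope.",
                 class = "preecv_config_error")
  }
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  a <- (lo + hi) / 2
  if (abs(f(a)) > tol) {
    rlang::abort("Intercept solve did not reach the prevalence tolerance.",
                 class = "preecv_config_error")
  }
  a
}

#' Coefficient-recovery experiment
#'
#' Repeats generate-score-fit: draws `n_reps` synthetic cohorts from a known
#' latent logistic model, fits the score model to each, and summarizes bias
#' and root-mean-square error of the intercept and slope estimates. Fit
#' failures (degenerate outcomes, separation) are counted, not fatal.
#'
#' @param n Cohort size per replicate.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param intercept,slope True latent model (the explicit-intercept form is
#'   required so that truth is known).
#' @param marginals,rho Passed to [generate_cohort()].
#' @return A list with `estimates` (tibble: `rep`, `intercept`, `slope`,
#'   `failed`), `summary` (tibble: `term`, `truth`, `mean_estimate`,
#'   `bias`, `rmse`) and `n_failed`.
#' @examples
#' recovery_experiment(n = 200, n_reps = 5, seed = 7,
#'                     intercept = -2, slope = 0.55)
#' @export
recovery_experiment <- function(n, n_reps, seed, intercept, slope,
                                marginals = ecv_default_marginals(),
                                rho = 0.6) {
  stopifnot(is.numeric(intercept), is.numeric(slope))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_reps))
  estimates <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cohort <- generate_cohort(n, seed = seeds[r], marginals = marginals,
                              rho = rho, slope = slope,
                              intercept = intercept,
                              target_prevalence = NULL)
    fit <- tryCatch(fit_logistic(cohort$score, cohort$success),
                    preecv_degenerate_error = function(e) NULL,
                    preecv_separation_error = function(e) NULL)
    if (is.null(fit)) {
      tibble::tibble(rep = r, intercept = NA_real_, slope = NA_real_,
                     failed = TRUE)
    } else {
      tibble::tibble(rep = r, intercept = fit$intercept, slope = fit$slope,
                     failed = FALSE)
    }
  })
  ok <- dplyr::filter(estimates, !.data$failed)
  true_vals <- c(intercept = intercept, slope = slope)
  summary <- purrr::map_dfr(c("intercept", "slope"), function(term) {
    est <- ok[[term]]
    tv <- true_vals[[term]]
    tibble::tibble(term = term, truth = tv,
                   mean_estimate = mean(est),
                   bias = mean(est) - tv,
                   rmse = sqrt(mean((est - tv)^2)))
  })
  list(estimates = estimates, summary = summary,
       n_failed = sum(estimates$failed))
}
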