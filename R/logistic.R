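# Univariable logistic model mapping the total score to success probability.
# Fitted by Newton-Raphson (IRLS) with step-halving; the explicit fitter (a)
# exposes the score equations the tests check and (b) raises typed
# degenerate-outcome / separation errors that the bootstrap engine must
# catch and count.

new_logistic_fit <- function(coef, se, loglik, n_iter, converged, n) {
  structure(
    list(intercept = unname(coef[1]),
         slope = if (length(coef) > 1) unname(coef[2]) else NA_real_,
         se_intercept = unname(se[1]),
         se_slope = if (length(se) > 1) unname(se[2]) else NA_real_,
         log_likelihood = loglik, n_iterations = n_iter,
         converged = converged, n = n),
    class = "ecv_logistic"
  )
}

# Core Newton-Raphson maximum-likelihood fit of
#   logit P(y = 1) = offset + X %*% beta
# with step-halving when a step decreases the log-likelihood.
logistic_mle <- function(X, y, offset = NULL, max_iter = 100,
                         tol_score = 1e-8, tol_step = 1e-10,
                         diverge_at = 50) {
  n <- length(y)
  if (is.null(offset)) offset <- rep(0, n)
  if (length(unique(y)) < 2) {
    rlang::abort("Outcomes are all one class; the logistic model is degenerate.",
                 class = "preecv_degenerate_error")
  }
  if (ncol(X) == 2) {
    # perfect separation of a single predictor: the MLE does not exist
    x1 <- X[y == 1, 2]
    x0 <- X[y == 0, 2]
    if (min(x1) > max(x0) || max(x1) < min(x0)) {
      rlang::abort("Predictor perfectly separates the outcome classes; the MLE diverges.",
                   class = "preecv_separation_error")
    }
  }
  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(mean(y)) - mean(offset)
  loglik <- function(b) {
    eta <- offset + drop(X %*% b)
    sum(y * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
  }
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- offset + drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) < tol_score) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    delta <- tryCatch(solve(info, score), error = function(e) {
      rlang::abort("Observed information is singular (separation or constant predictor).",
                   class = "preecv_separation_error")
    })
    # step-halving: never accept a step that lowers the likelihood
    step <- 1
    repeat {
      cand <- beta + step * delta
      if (loglik(cand) >= ll - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    beta <- beta + step * delta
    ll <- loglik(beta)
    if (any(abs(beta) > diverge_at)) {
      rlang::abort(
        "Logistic fit is diverging (|coefficient| > 50): perfect or quasi-separation.",
        class = "preecv_separation_error"
      )
    }
    if (max(abs(step * delta)) < tol_step) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::abort("Logistic fit did not converge in 100 iterations (suspected separation).",
                 class = "preecv_separation_error")
  }
  eta <- offset + drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  se <- tryCatch(sqrt(diag(solve(crossprod(X, X * w)))), error = function(e) {
    rlang::abort("Observed information is singular (separation or constant predictor).",
                 class = "preecv_separation_error")
  })
  list(coef = unname(beta), se = unname(se), loglik = ll, n_iter = iter)
}

#' Fit the score-to-probability logistic model
#'
#' Maximum-likelihood logistic regression of the binary ECV outcome on the
#' total score as the sole predictor: `logit P(success) = intercept +
#' slope * score`. Keeping the prespecified score as the only covariate
#' preserves model simplicity and avoids data-driven refitting of the point
#' weights.
#'
#' @param scores Numeric vector of total scores.
#' @param outcomes Logical or 0/1 vector of outcomes, same length.
#' @return An object of class `ecv_logistic` with elements `intercept`,
#'   `slope` (log-odds per point), `se_intercept`, `se_slope`,
#'   `log_likelihood`, `n_iterations`, `converged`, `n`. Supports
#'   [predict_prob()], `tidy()` and `glance()`.
#' @section Errors: one-class outcomes raise a degenerate-outcome error
#'   (class `preecv_degenerate_error`); non-convergence within 100
#'   Newton-Raphson iterations or a coefficient beyond 50 in absolute value
#'   raises a separation error (class `preecv_separation_error`).
#' @examples
#' fit <- fit_logistic(c(2, 4, 5, 6, 8, 9), c(0, 0, 1, 0, 1, 1))
#' predict_prob(fit, 0:13)
#' @export
fit_logistic <- function(scores, outcomes) {
  outcomes <- as.numeric(coerce_flag(outcomes))
  scores <- as.numeric(scores)
  if (length(scores) != length(outcomes) || length(scores) < 2) {
    rlang::abort("`scores` and `outcomes` must have equal length >= 2.",
                 class = "preecv_validation_error")
  }
  if (anyNA(scores) || anyNA(outcomes)) {
    rlang::abort("`scores` and `outcomes` must not contain missing values.",
                 class = "preecv_validation_error")
  }
  res <- logistic_mle(cbind(1, scores), outcomes)
  new_logistic_fit(res$coef, res$se, res$loglik, res$n_iter, TRUE,
                   length(outcomes))
}

#' Fit the score model directly from a cohort table
#'
#' Convenience wrapper: scores the cohort (if no `score` column is present)
#' and fits [fit_logistic()] of `success` on `score`.
#'
#' @param cohort A cohort table ([validate_cohort()]).
#' @return An `ecv_logistic` fit.
#' @examples
#' fit_score_model(ecv_fixture_cohort())
#' @export
fit_score_model <- function(cohort) {
  cohort <- validate_cohort(cohort)
  if (!"score" %in% names(cohort)) cohort <- ecv_score(cohort)
  fit_logistic(cohort$score, cohort$success)
}

#' Predicted success probability at a score
#'
#' Evaluates the inverse-logit of the fitted linear predictor,
#' `plogis(intercept + slope * score)`.
#'
#' @param fit An `ecv_logistic` fit.
#' @param score Numeric vector of scores.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(fit, score) {
  stopifnot(inherits(fit, "ecv_logistic"))
  if (!isTRUE(fit$converged)) {
    rlang::abort("Cannot predict from a non-converged fit.",
                 class = "preecv_validation_error")
  }
  stats::plogis(fit$intercept + fit$slope * as.numeric(score))
}

#' @export
predict.ecv_logistic <- function(object, score, ...) predict_prob(object, score)

#' @export
print.ecv_logistic <- function(x, ...) {
  cat("Logistic score-to-probability model (n =", x$n, ")\n")
  cat(sprintf("  logit P(success) = %.4f + %.4f * score\n", x$intercept, x$slope))
  cat(sprintf("  SEs: intercept %.4f, slope %.4f; logLik %.3f; %d Newton iterations\n",
              x$se_intercept, x$se_slope, x$log_likelihood, x$n_iterations))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x,object An `ecv_logistic` fit.
#' @param ... Unused.
#' @export
tidy.ecv_logistic <- function(x, ...) {
  z <- c(x$intercept / x$se_intercept, x$slope / x$se_slope)
  tibble::tibble(
    term = c("intercept", "score"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope),
    statistic = z,
    p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' @rdname fit_logistic
#' @export
glance.ecv_logistic <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood, nobs = x$n,
    n_iterations = x$n_iterations, converged = x$converged
  )
}
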