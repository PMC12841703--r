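# PRE-ECV score: eight predictors, additive points, total range 0-13.

#' Predictor columns of the PRE-ECV score
#'
#' The PRE-ECV score combines eight clinical and ultrasonographic predictors
#' of external cephalic version (ECV) success, each assessed immediately
#' before the procedure. A profile tibble must carry one column per
#' predictor:
#'
#' * `parity`: `"multiparous"` or `"nulliparous"`.
#' * `presentation`: `"transverse"`, `"complete_breech"` or `"frank_breech"`.
#' * `engaged`: logical; is the presenting part engaged in the pelvis?
#' * `palpable_head`: logical; is the fetal head palpable abdominally?
#' * `efw_ge_10th`: logical; estimated fetal weight at or above the 10th
#'   percentile for gestational age (percentiles below the 10th score 0).
#' * `mvp_ge_4cm`: logical; maximum vertical amniotic-fluid pocket of at
#'   least 4.0 cm (pockets below 4.0 cm score 0).
#' * `placenta_posterior`: logical; posterior-wall placenta. Non-posterior
#'   locations (anterior, lateral, fundal) must be dichotomized to `FALSE`
#'   by the caller.
#' * `tocolysis`: logical; pharmacologic uterine relaxation given before the
#'   attempt.
#'
#' Every field must be set: a missing value is an input error, never a
#' category.
#'
#' @return `ecv_predictors()` returns the character vector of the eight
#'   predictor column names, in score-table order.
#' @seealso [ecv_score()], [ecv_profile_grid()]
#' @export
ecv_predictors <- function() {
  c("parity", "presentation", "engaged", "palpable_head",
    "efw_ge_10th", "mvp_ge_4cm", "placenta_posterior", "tocolysis")
}

#' Point-breakdown factor names
#'
#' Fixed names of the eight score components, part of the public contract of
#' [ecv_score_breakdown()]. Each component awards 0, 1 or 2 points.
#'
#' @return Character vector of length 8.
#' @export
ecv_factors <- function() {
  c("parity", "fetal_presentation", "non_engagement", "palpable_fetal_head",
    "efw", "mvp", "placental_location", "tocolysis")
}

parity_levels <- c("multiparous", "nulliparous")
presentation_levels <- c("transverse", "complete_breech", "frank_breech")

logical_predictors <- function() {
  setdiff(ecv_predictors(), c("parity", "presentation"))
}

# Validate the eight predictor columns of `data`; errors name the offending
# column and (1-based) row. Returns `data` with predictors coerced to
# canonical types (character enums, logical flags).
validate_profiles <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame of predictor profiles.",
                 class = "preecv_validation_error", call = call)
  }
  missing_cols <- setdiff(ecv_predictors(), names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("Missing predictor column(s): ",
             paste(missing_cols, collapse = ", "), "."),
      class = "preecv_validation_error", call = call
    )
  }
  data <- dplyr::mutate(
    data,
    parity = as.character(.data$parity),
    presentation = as.character(.data$presentation),
    dplyr::across(dplyr::all_of(logical_predictors()), coerce_flag)
  )
  check_enum(data$parity, parity_levels, "parity", call)
  check_enum(data$presentation, presentation_levels, "presentation", call)
  for (col in logical_predictors()) {
    bad <- which(is.na(data[[col]]))
    if (length(bad) > 0) {
      rlang::abort(
        sprintf("Field `%s` is missing or not interpretable as 0/1 in row %d.",
                col, bad[1]),
        class = "preecv_validation_error", call = call
      )
    }
  }
  data
}

coerce_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    out <- rep(NA, length(x))
    out[x %in% c(0, 1)] <- x[x %in% c(0, 1)] == 1
    return(as.logical(out))
  }
  x <- tolower(trimws(as.character(x)))
  dplyr::case_when(
    x %in% c("1", "true", "yes") ~ TRUE,
    x %in% c("0", "false", "no") ~ FALSE,
    .default = NA
  )
}

check_enum <- function(x, levels, field, call) {
  bad <- which(is.na(x) | !(x %in% levels))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("Field `%s` has invalid value %s in row %d (expected one of %s).",
              field,
              if (is.na(x[bad[1]])) "<missing>" else paste0('"', x[bad[1]], '"'),
              bad[1], paste0('"', levels, '"', collapse = ", ")),
      class = "preecv_validation_error", call = call
    )
  }
  invisible(x)
}

#' Compute the PRE-ECV score
#'
#' Adds the additive PRE-ECV total (0-13 points) to a tibble of predictor
#' profiles. Points per factor: multiparity 2; transverse lie 2, complete
#' breech 1, frank breech 0; non-engagement of the presenting part 2;
#' palpable fetal head 2; estimated fetal weight at or above the 10th
#' percentile 1; maximum vertical pocket of at least 4 cm 1; posterior
#' placenta 1; tocolysis 2.
#'
#' @param data A data frame with the eight predictor columns described in
#'   [ecv_predictors()]. Extra columns are passed through untouched.
#' @return `data` as a tibble with an integer `score` column appended (or
#'   replaced).
#' @examples
#' ecv_score(ecv_profile_grid())
#' @export
ecv_score <- function(data) {
  breakdown <- ecv_score_breakdown(data)
  out <- dplyr::as_tibble(data)
  out$score <- breakdown$score
  out
}

#' Per-factor point breakdown of the PRE-ECV score
#'
#' @param data A data frame with the eight predictor columns
#'   ([ecv_predictors()]).
#' @return A tibble with one row per input row: the eight factor columns
#'   named as in [ecv_factors()], each holding the awarded points (0, 1 or
#'   2), and an integer `score` column equal to their sum.
#' @examples
#' ecv_score_breakdown(ecv_profile_grid()[1, ])
#' @export
ecv_score_breakdown <- function(data) {
  data <- validate_profiles(data)
  out <- tibble::tibble(
    parity = ifelse(data$parity == "multiparous", 2L, 0L),
    fetal_presentation = dplyr::case_match(
      data$presentation,
      "transverse" ~ 2L, "complete_breech" ~ 1L, "frank_breech" ~ 0L
    ),
    non_engagement = ifelse(data$engaged, 0L, 2L),
    palpable_fetal_head = ifelse(data$palpable_head, 2L, 0L),
    efw = ifelse(data$efw_ge_10th, 1L, 0L),
    mvp = ifelse(data$mvp_ge_4cm, 1L, 0L),
    placental_location = ifelse(data$placenta_posterior, 1L, 0L),
    tocolysis = ifelse(data$tocolysis, 2L, 0L)
  )
  out$score <- as.integer(rowSums(out))
  out
}

#' Enumerate all possible predictor profiles
#'
#' The predictor domain is finite: two parity levels, three presentations and
#' six binary flags give `2 * 3 * 2^6 * 2 = 384` distinct profiles.
#'
#' @return A 384-row tibble, one row per possible profile.
#' @export
ecv_profile_grid <- function() {
  tidyr::expand_grid(
    parity = parity_levels,
    presentation = presentation_levels,
    engaged = c(FALSE, TRUE),
    palpable_head = c(FALSE, TRUE),
    efw_ge_10th = c(FALSE, TRUE),
    mvp_ge_4cm = c(FALSE, TRUE),
    placenta_posterior = c(FALSE, TRUE),
    tocolysis = c(FALSE, TRUE)
  )
}

#' Achievable score range
#'
#' Computed by scoring every one of the 384 possible profiles, not
#' hard-coded.
#'
#' @return A one-row tibble with integer columns `min` and `max` (0 and 13).
#' @export
ecv_score_bounds <- function() {
  totals <- ecv_score(ecv_profile_grid())$score
  tibble::tibble(min = min(totals), max = max(totals))
}
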