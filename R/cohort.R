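# Cohort tables: CSV read/write, validation, Table-style descriptive summary.

cohort_columns <- function() c("id", ecv_predictors(), "success")

#' Validate an ECV cohort table
#'
#' A cohort is a tibble with one row per ECV attempt: an opaque `id`
#' (unique, non-missing), the eight predictor columns of
#' [ecv_predictors()], and a logical `success` column (immediate conversion
#' to cephalic presentation confirmed by ultrasound). All analytic functions
#' require a non-empty cohort.
#'
#' @param data A data frame.
#' @return The validated cohort as a tibble with canonical column types,
#'   columns ordered `id`, predictors, `success`; extra columns are kept at
#'   the end.
#' @export
validate_cohort <- function(data) {
  if (!is.data.frame(data)) {
    rlang::abort("A cohort must be a data frame.",
                 class = "preecv_validation_error")
  }
  if (nrow(data) == 0) {
    rlang::abort("A cohort must contain at least one record.",
                 class = "preecv_validation_error")
  }
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("Missing cohort column(s): ",
             paste(missing_cols, collapse = ", "), "."),
      class = "preecv_validation_error"
    )
  }
  data <- dplyr::as_tibble(data)
  data$id <- as.character(data$id)
  if (anyNA(data$id)) {
    rlang::abort(sprintf("Field `id` is missing in row %d.",
                         which(is.na(data$id))[1]),
                 class = "preecv_validation_error")
  }
  dup <- which(duplicated(data$id))
  if (length(dup) > 0) {
    rlang::abort(
      sprintf("Field `id` has duplicate value \"%s\" in row %d.",
              data$id[dup[1]], dup[1]),
      class = "preecv_validation_error"
    )
  }
  data$success <- coerce_flag(data$success)
  if (anyNA(data$success)) {
    rlang::abort(
      sprintf("Field `success` is missing or not 0/1 in row %d.",
              which(is.na(data$success))[1]),
      class = "preecv_validation_error"
    )
  }
  data <- validate_profiles(data)
  dplyr::relocate(data, dplyr::all_of(cohort_columns()))
}

#' Read an ECV cohort from CSV
#'
#' The file must carry the columns `id`, `parity`, `presentation`,
#' `engaged`, `palpable_head`, `efw_ge_10th`, `mvp_ge_4cm`,
#' `placenta_posterior`, `tocolysis`, `success`; booleans encoded `1`/`0`,
#' enums as lowercase snake_case strings. Row order is preserved. Malformed
#' cells raise an error naming the row and field.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort tibble.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Cohort file not found: ", path),
                 class = "preecv_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_cohort(raw)
}

#' Write an ECV cohort to CSV
#'
#' The cohort is validated first, so the written file always re-reads to an
#' equal cohort.
#'
#' @param cohort A cohort table ([validate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- dplyr::mutate(
    cohort,
    dplyr::across(dplyr::where(is.logical), as.integer)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Round half away from zero, matching the table-formatting convention.
round_half_up <- function(x, digits = 1) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Descriptive cohort summary stratified by outcome
#'
#' Cross-tabulates each predictor against the ECV outcome, in the layout of
#' a baseline-characteristics table: counts and per-column percentages
#' (rounded half-up to one decimal) for the whole cohort, the successful
#' group and the unsuccessful group.
#'
#' @param cohort A cohort table.
#' @return An object of class `ecv_cohort_summary`: a list with
#'   * `n_total`, `n_success`, `n_failure`: counts;
#'   * `success_rate`: percent successful, one decimal;
#'   * `table`: a tibble with one row per predictor level and columns
#'     `characteristic`, `level`, `n_all`, `pct_all`, `n_success`,
#'     `pct_success`, `n_failure`, `pct_failure`.
#'
#'   `tidy()` returns `table`; `glance()` returns the scalar counts.
#' @examples
#' summarize_cohort(ecv_fixture_cohort())
#' @export
summarize_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  long <- tidyr::pivot_longer(
    dplyr::mutate(cohort, dplyr::across(dplyr::all_of(logical_predictors()),
                                        ~ ifelse(.x, "yes", "no"))),
    cols = dplyr::all_of(ecv_predictors()),
    names_to = "characteristic", values_to = "level"
  )
  level_sets <- list(
    parity = parity_levels,
    presentation = presentation_levels
  )
  levels_tbl <- purrr::map_dfr(ecv_predictors(), function(ch) {
    lv <- level_sets[[ch]] %||% c("yes", "no")
    tibble::tibble(characteristic = ch, level = lv)
  })

  count_group <- function(d, suffix) {
    n_grp <- nrow(d)
    counts <- dplyr::count(
      dplyr::filter(long, .data$id %in% d$id),
      .data$characteristic, .data$level
    )
    out <- dplyr::left_join(levels_tbl, counts,
                            by = c("characteristic", "level"))
    out$n[is.na(out$n)] <- 0L
    out$pct <- if (n_grp > 0) round_half_up(100 * out$n / n_grp, 1) else NA_real_
    names(out)[names(out) == "n"] <- paste0("n_", suffix)
    names(out)[names(out) == "pct"] <- paste0("pct_", suffix)
    out
  }

  tab <- count_group(cohort, "all")
  tab <- dplyr::left_join(tab, count_group(dplyr::filter(cohort, .data$success), "success"),
                          by = c("characteristic", "level"))
  tab <- dplyr::left_join(tab, count_group(dplyr::filter(cohort, !.data$success), "failure"),
                          by = c("characteristic", "level"))

  out <- list(
    n_total = nrow(cohort),
    n_success = sum(cohort$success),
    n_failure = sum(!cohort$success),
    success_rate = round_half_up(100 * mean(cohort$success), 1),
    table = tab
  )
  class(out) <- "ecv_cohort_summary"
  out
}

#' @export
print.ecv_cohort_summary <- function(x, ...) {
  cat(sprintf("ECV cohort: %d attempts, %d successful (%.1f%%), %d unsuccessful\n\n",
              x$n_total, x$n_success, x$success_rate, x$n_failure))
  print(x$table, n = Inf)
  invisible(x)
}

#' @export
tidy.ecv_cohort_summary <- function(x, ...) x$table

#' @export
glance.ecv_cohort_summary <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_success = x$n_success,
                 n_failure = x$n_failure, success_rate = x$success_rate)
}
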