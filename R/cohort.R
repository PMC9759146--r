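#' Load the SeLECTS clinical cohort
#'
#' Reads the packaged 35-subject clinical table (or a user-supplied delimited
#' file with the same columns) and validates it. Each row describes one newly
#' diagnosed, drug-naive pediatric patient: gender, age in years, disease
#' course in months, lifetime seizure count, and a flag marking membership of
#' the cognitively impaired subgroup (full-scale IQ below 80 on the WISC-IV).
#'
#' @param source `NULL` (default) to load the packaged fixture, or a path to a
#'   comma- or tab-delimited file with header
#'   `subject_id,gender,age,course_months,n_seizures,impaired_flag`.
#' @return A tibble of class `meg_cohort` with the six input columns plus
#'   `fsiq_group`, a factor with levels `"FSIQ<80"` and `"FSIQ>80"`.
#' @examples
#' cohort <- load_cohort()
#' table(cohort$fsiq_group)
#' @export
load_cohort <- function(source = NULL) {
  if (is.null(source) || identical(source, "fixture")) {
    source <- system.file("extdata", "selects_cohort.csv", package = "megnet")
  }
  if (!file.exists(source)) abort(paste0("Cohort file not found: ", source))
  cohort <- readr::read_delim(
    source,
    delim = if (grepl("\t", readr::read_lines(source, n_max = 1))) "\t" else ",",
    col_types = readr::cols(
      subject_id = readr::col_integer(),
      gender = readr::col_character(),
      age = readr::col_double(),
      course_months = readr::col_double(),
      n_seizures = readr::col_integer(),
      impaired_flag = readr::col_logical()
    ),
    progress = FALSE
  )
  validate_cohort(cohort)
}

#' Validate a cohort table
#'
#' Checks column presence, unique ids, gender coding, the 6-13 year age
#' range of the inclusion criteria, positive disease course and seizure
#' counts, then attaches the `fsiq_group` factor.
#'
#' @param cohort A data frame with the six cohort columns.
#' @return The validated `meg_cohort` tibble.
#' @export
validate_cohort <- function(cohort) {
  required <- c(
    "subject_id", "gender", "age", "course_months", "n_seizures", "impaired_flag"
  )
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cohort) == 0) abort("Cohort table is empty")
  if (anyNA(cohort[required])) {
    bad <- which(apply(is.na(cohort[required]), 1, any))
    abort(paste0("Malformed cohort row(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(cohort$subject_id)) {
    dup <- cohort$subject_id[duplicated(cohort$subject_id)]
    abort(paste0("Duplicate subject_id: ", paste(unique(dup), collapse = ", ")))
  }
  checks <- list(
    "gender must be F or M" = cohort$gender %in% c("F", "M"),
    "age must be in [6, 13] years (inclusion criteria)" =
      cohort$age >= 6 & cohort$age <= 13,
    "course_months must be positive" = cohort$course_months > 0,
    "n_seizures must be a positive count" = cohort$n_seizures >= 1
  )
  for (msg in names(checks)) {
    if (!all(checks[[msg]])) {
      rows <- cohort$subject_id[!checks[[msg]]]
      abort(paste0(msg, "; offending subject_id: ", paste(rows, collapse = ", ")))
    }
  }
  cohort$fsiq_group <- factor(
    ifelse(cohort$impaired_flag, "FSIQ<80", "FSIQ>80"),
    levels = c("FSIQ<80", "FSIQ>80")
  )
  class(cohort) <- c("meg_cohort", class(cohort))
  cohort
}

#' Summarize clinical variables by cognitive group
#'
#' Computes per-group n, mean and sample standard deviation (n - 1
#' denominator) for the clinical variables, plus an `"all"` row covering the
#' whole cohort. Values are returned unrounded; round at the reporting layer.
#'
#' @param cohort A `meg_cohort` tibble from [load_cohort()].
#' @param variables Clinical variables to summarize.
#' @return A tibble with columns `group`, `variable`, `n`, `mean`, `sd`
#'   (`sd` is `NA` for single-subject groups).
#' @examples
#' summarize_cohort(load_cohort())
#' @export
summarize_cohort <- function(cohort,
                             variables = c("age", "course_months", "n_seizures")) {
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown)) {
    abort(paste0("Unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  long <- cohort |>
    dplyr::select(dplyr::all_of(c("fsiq_group", variables))) |>
    tidyr::pivot_longer(dplyr::all_of(variables),
      names_to = "variable", values_to = "value"
    )
  by_group <- long |>
    dplyr::group_by(group = as.character(.data$fsiq_group), .data$variable)
  overall <- long |>
    dplyr::group_by(group = "all", .data$variable)
  dplyr::bind_rows(
    dplyr::summarise(by_group,
      n = dplyr::n(), mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_, .groups = "drop"
    ),
    dplyr::summarise(overall,
      n = dplyr::n(), mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_, .groups = "drop"
    )
  )
}

#' Summary statistics for one group and variable
#'
#' @param cohort A `meg_cohort` tibble.
#' @param group `"FSIQ<80"`, `"FSIQ>80"` or `"all"`.
#' @param variable One of the clinical variable names.
#' @return A one-row tibble (`group`, `variable`, `n`, `mean`, `sd`).
#' @export
summarize_group <- function(cohort, group, variable) {
  if (!group %in% c("FSIQ<80", "FSIQ>80", "all")) {
    abort(paste0("Unknown group: ", group))
  }
  out <- summarize_cohort(cohort, variables = variable) |>
    dplyr::filter(.data$group == .env$group)
  if (nrow(out) == 0) abort(paste0("Group is empty: ", group))
  out
}

#' Compare the two cognitive groups on a clinical variable
#'
#' Two-sided independent two-sample t-test of the impaired (FSIQ < 80)
#' versus non-impaired (FSIQ > 80) group. The pooled-variance Student form is
#' the default; set `var_equal = FALSE` for the Welch form. When both groups
#' are constant and equal the degenerate result t = 0, p = 1 is returned.
#'
#' @param cohort A `meg_cohort` tibble.
#' @param variable Clinical variable to compare.
#' @param var_equal Use the pooled-variance form (default `TRUE`).
#' @return A one-row tibble: `variable`, `t`, `df`, `p`, `mean_impaired`,
#'   `mean_unimpaired`, `method`.
#' @examples
#' compare_groups_ttest(load_cohort(), "course_months")
#' @export
compare_groups_ttest <- function(cohort, variable, var_equal = TRUE) {
  if (!variable %in% names(cohort)) abort(paste0("Unknown variable: ", variable))
  x <- cohort[[variable]][cohort$impaired_flag]
  y <- cohort[[variable]][!cohort$impaired_flag]
  if (length(x) < 2 || length(y) < 2) {
    abort("Both groups need at least two subjects for a t-test")
  }
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) {
    res <- list(
      statistic = 0, parameter = length(x) + length(y) - 2, p.value = 1,
      method = "degenerate (zero variance, equal means)"
    )
  } else {
    res <- t.test(x, y, var.equal = var_equal)
  }
  tibble::tibble(
    variable = variable,
    t = unname(res$statistic),
    df = unname(res$parameter),
    p = res$p.value,
    mean_impaired = mean(x),
    mean_unimpaired = mean(y),
    method = res$method
  )
}
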