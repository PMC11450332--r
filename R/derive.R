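#' Derive analysis variables from raw phenotypes
#'
#' Computes each individual's mean BMI over ages 75-85 (arithmetic mean of
#' all measures with measurement age in the closed window \[75, 85\]), the
#' binary exposure (1 = overweight, mean BMI in \[25, 30); 0 = normal
#' weight, mean BMI in \[18.5, 25)) and the binary outcome (1 = lifespan
#' at least 85 years, whether observed alive at or beyond 85 or died at
#' 85+; 0 = died before 85). Individuals for whom either variable is
#' undefined, or with any missing covariate, are flagged excluded with a
#' reason code rather than dropped, so exclusion counts can be reported.
#'
#' @param phenotypes tibble with columns `id`, covariates (`sex`, `race`,
#'   `education`, `smoking`, `comorbidity`, `field_center`, `pc1`, `pc2`),
#'   `enrollment_age`, `event_age`, `death` (1 = died at `event_age`,
#'   0 = censored alive at `event_age`) and a `bmi_measures` list-column of
#'   `(age, bmi)` tibbles (as produced by [simulate_cohort()] or
#'   [read_phenotypes()]).
#' @param covariates covariate columns whose completeness is required.
#' @return The input tibble with added columns `mean_bmi_75_85`,
#'   `exposure`, `outcome`, `excluded` and `exclusion_reason`. The
#'   exclusion counts are attached as attribute `exclusion_report`.
#' @export
derive_variables <- function(phenotypes,
                             covariates = c("sex", "race", "education",
                                            "smoking", "comorbidity",
                                            "field_center", "pc1", "pc2")) {
  ph <- tibble::as_tibble(phenotypes)
  needed <- c("id", "enrollment_age", "event_age", "death", "bmi_measures")
  missing_cols <- setdiff(needed, names(ph))
  if (length(missing_cols)) {
    abort(paste0("phenotypes lack columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  contradictory <- !is.na(ph$event_age) & !is.na(ph$enrollment_age) &
    ph$death == 1L & ph$event_age < ph$enrollment_age
  if (any(contradictory)) {
    abort(paste0(
      "death before enrollment for: ",
      paste(head(ph$id[contradictory], 5L), collapse = ", ")
    ))
  }

  mean_bmi <- purrr::map_dbl(ph$bmi_measures, function(mm) {
    if (is.null(mm) || nrow(mm) == 0L) return(NA_real_)
    inw <- mm$age >= 75 & mm$age <= 85
    if (!any(inw)) return(NA_real_)
    mean(mm$bmi[inw])
  })

  exposure <- dplyr::case_when(
    is.na(mean_bmi) ~ NA_integer_,
    mean_bmi >= 25 & mean_bmi < 30 ~ 1L,
    mean_bmi >= 18.5 & mean_bmi < 25 ~ 0L,
    TRUE ~ NA_integer_
  )
  outcome <- dplyr::case_when(
    ph$event_age >= 85 ~ 1L,                   # lived to 85, died or not
    ph$death == 1L & ph$event_age < 85 ~ 0L,   # died before 85
    TRUE ~ NA_integer_                         # censored alive before 85
  )

  cov_missing <- rep(FALSE, nrow(ph))
  for (cv in intersect(covariates, names(ph))) {
    cov_missing <- cov_missing | is.na(ph[[cv]])
  }
  absent <- setdiff(covariates, names(ph))
  if (length(absent)) {
    warn(paste0("covariates not present, ignored: ",
                paste(absent, collapse = ", ")))
  }

  reason <- dplyr::case_when(
    is.na(mean_bmi) ~ "no_bmi_in_window",
    is.na(exposure) ~ "bmi_out_of_range",
    is.na(outcome) ~ "outcome_undetermined",
    cov_missing ~ "missing_covariate",
    TRUE ~ NA_character_
  )

  out <- dplyr::mutate(
    ph,
    mean_bmi_75_85 = mean_bmi,
    exposure = exposure,
    outcome = outcome,
    excluded = !is.na(reason),
    exclusion_reason = reason
  )
  attr(out, "exclusion_report") <- out |>
    dplyr::count(.data$exclusion_reason, name = "n") |>
    dplyr::arrange(.data$exclusion_reason)
  out
}

# Retained (analysis) subset of a derived cohort.
retained <- function(cohort) {
  if (!all(c("exposure", "outcome", "excluded") %in% names(cohort))) {
    abort("cohort must first pass through derive_variables()")
  }
  dplyr::filter(cohort, !.data$excluded)
}
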