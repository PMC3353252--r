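#' @keywords internal
"_PACKAGE"

# Baseline fields measured in mmol/L whose model-scale counterpart is mg/dl,
# keyed by the analyte used for the molar-mass conversion factor.
.field_analyte <- c(
  fpg = "glucose", two_hpg = "glucose", fpg_followup = "glucose",
  hdl = "cholesterol", ldl = "cholesterol",
  triglyceride = "triglyceride"
)

.continuous_fields <- c(
  "age", "fpg", "two_hpg", "sbp", "hdl", "triglyceride", "bmi",
  "waist", "height", "fpg_followup", "ldl", "hip", "creatinine",
  "insulin_resistance"
)

.binary_fields <- c(
  "family_history_t2dm", "diagnosed_t2dm", "physician_dx_followup",
  "outcome_t2dm"
)

#' Unit conversion factors between mmol/L and mg/dl
#'
#' Molar-mass based factors used when a model term is specified on the
#' mg/dl scale but the cohort stores the analyte in mmol/L (glucose
#' 18.0182, cholesterol 38.67, triglyceride 88.57 mg/dl per mmol/L).
#' Override any factor to use laboratory-specific conventions.
#'
#' @param glucose,cholesterol,triglyceride mg/dl per mmol/L.
#' @return Named numeric vector of conversion factors.
#' @export
#' @examples
#' unit_conversion_factors()
unit_conversion_factors <- function(glucose = 18.0182,
                                    cholesterol = 38.67,
                                    triglyceride = 88.57) {
  c(glucose = glucose, cholesterol = cholesterol,
    triglyceride = triglyceride)
}

#' Convert analyte concentrations between mmol/L and mg/dl
#'
#' @param x Numeric vector of concentrations.
#' @param analyte One of `"glucose"`, `"cholesterol"`, `"triglyceride"`.
#' @param from,to Units; one of `"mmol/L"`, `"mg/dl"`.
#' @param factors Conversion factors, see [unit_conversion_factors()].
#' @return Numeric vector in the target unit.  The conversion is a total
#'   function and round-trips exactly up to floating point.
#' @export
#' @examples
#' convert_units(5.35, "glucose", "mmol/L", "mg/dl")
convert_units <- function(x, analyte, from = "mmol/L", to = "mg/dl",
                          factors = unit_conversion_factors()) {
  analyte <- match.arg(analyte, names(factors))
  from <- match.arg(from, c("mmol/L", "mg/dl"))
  to <- match.arg(to, c("mmol/L", "mg/dl"))
  if (from == to) return(x)
  if (from == "mmol/L") x * factors[[analyte]] else x / factors[[analyte]]
}

#' Validate a cohort data frame
#'
#' Checks the structural invariants of a cohort of subject records: a
#' unique `id` column, `sex` in \{male, female\}, `ethnicity` in
#' \{Chinese, Malay, Indian\}, age within \[18, 100\], all continuous
#' measurements strictly positive where present and binary flags in
#' \{0, 1\}.  Missing values (`NA`) are allowed anywhere except `id`.
#'
#' @param cohort A data frame, one row per subject.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  required <- c("id", "age", "sex", "ethnicity")
  miss <- setdiff(required, names(cohort))
  if (length(miss) > 0)
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyNA(cohort$id) || anyDuplicated(cohort$id))
    stop("subject ids must be non-missing and unique")
  bad_sex <- !is.na(cohort$sex) & !cohort$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("sex must be 'male' or 'female'; offending ids: ",
         paste(utils::head(cohort$id[bad_sex], 5), collapse = ", "))
  bad_eth <- !is.na(cohort$ethnicity) &
    !cohort$ethnicity %in% c("Chinese", "Malay", "Indian")
  if (any(bad_eth))
    stop("ethnicity must be Chinese, Malay or Indian; offending ids: ",
         paste(utils::head(cohort$id[bad_eth], 5), collapse = ", "))
  bad_age <- !is.na(cohort$age) & (cohort$age < 18 | cohort$age > 100)
  if (any(bad_age))
    stop("age must lie in [18, 100]; offending ids: ",
         paste(utils::head(cohort$id[bad_age], 5), collapse = ", "))
  for (f in intersect(setdiff(.continuous_fields, "age"), names(cohort))) {
    bad <- !is.na(cohort[[f]]) & cohort[[f]] <= 0
    if (any(bad))
      stop(sprintf("field '%s' must be strictly positive; offending ids: %s",
                   f, paste(utils::head(cohort$id[bad], 5), collapse = ", ")))
  }
  for (f in intersect(.binary_fields, names(cohort))) {
    bad <- !is.na(cohort[[f]]) & !cohort[[f]] %in% c(0, 1)
    if (any(bad))
      stop(sprintf("field '%s' must be 0/1; offending ids: %s",
                   f, paste(utils::head(cohort$id[bad], 5), collapse = ", ")))
  }
  invisible(cohort)
}

#' Read or write a cohort file
#'
#' Cohorts are exchanged as comma-separated text with a header row, one
#' subject per row and missing values as empty cells.
#'
#' @param path File path.
#' @param cohort A validated cohort data frame.
#' @return `read_cohort()` returns a validated cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  cohort$id <- as.character(cohort$id)
  validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Baseline eligibility filter
#'
#' Excludes subjects who already have diabetes at baseline: a prior
#' physician diagnosis, fasting plasma glucose >= 7.0 mmol/L, or 2-hour
#' post-challenge glucose >= 11.1 mmol/L.  Thresholds are inclusive.
#' A subject with no 2hPG measurement is assessed on FPG and diagnosis
#' alone.  The filter is idempotent.
#'
#' @param cohort A cohort data frame with baseline `fpg` (required) and
#'   optionally `two_hpg` and `diagnosed_t2dm` columns.
#' @param fpg_cutoff,two_hpg_cutoff Diagnostic cutoffs in mmol/L.
#' @return A list with elements `eligible` (cohort rows retained) and
#'   `excluded` (removed rows with an added machine-readable
#'   `exclusion_reason` column: `prior_physician_dx`, `baseline_fpg` or
#'   `baseline_2hpg`; the first matching reason in that order).
#' @export
apply_eligibility_filter <- function(cohort, fpg_cutoff = 7.0,
                                     two_hpg_cutoff = 11.1) {
  validate_cohort(cohort)
  if (!"fpg" %in% names(cohort)) stop("cohort must contain baseline 'fpg'")
  dx <- if ("diagnosed_t2dm" %in% names(cohort))
    !is.na(cohort$diagnosed_t2dm) & cohort$diagnosed_t2dm == 1
  else rep(FALSE, nrow(cohort))
  high_fpg <- !is.na(cohort$fpg) & cohort$fpg >= fpg_cutoff
  high_2h <- if ("two_hpg" %in% names(cohort))
    !is.na(cohort$two_hpg) & cohort$two_hpg >= two_hpg_cutoff
  else rep(FALSE, nrow(cohort))
  reason <- rep(NA_character_, nrow(cohort))
  reason[high_2h] <- "baseline_2hpg"
  reason[high_fpg] <- "baseline_fpg"
  reason[dx] <- "prior_physician_dx"
  out <- is.na(reason)
  excluded <- cohort[!out, , drop = FALSE]
  excluded$exclusion_reason <- reason[!out]
  list(eligible = cohort[out, , drop = FALSE], excluded = excluded)
}

#' Define the incident diabetes outcome at follow-up
#'
#' The outcome is 1 when follow-up fasting plasma glucose is
#' >= 7.0 mmol/L or a physician diagnosis was made during follow-up,
#' 0 otherwise, and `NA` when neither piece of information is available
#' (such subjects are candidates for multiple imputation).
#'
#' @param fpg_followup Numeric follow-up FPG in mmol/L (may be `NA`).
#' @param physician_dx 0/1 physician-diagnosis flag (may be `NA`).
#' @param fpg_cutoff Diagnostic cutoff in mmol/L, inclusive.
#' @return Integer vector of 0/1/`NA` outcomes.
#' @export
#' @examples
#' define_outcome(c(7.2, 5.9, 5.9, NA), c(0, 1, 0, NA))
define_outcome <- function(fpg_followup, physician_dx = 0,
                           fpg_cutoff = 7.0) {
  n <- max(length(fpg_followup), length(physician_dx))
  fpg_followup <- rep_len(fpg_followup, n)
  physician_dx <- rep_len(physician_dx, n)
  high <- !is.na(fpg_followup) & fpg_followup >= fpg_cutoff
  dx <- !is.na(physician_dx) & physician_dx == 1
  out <- ifelse(high | dx, 1L, 0L)
  out[is.na(fpg_followup) & is.na(physician_dx)] <- NA_integer_
  # follow-up FPG below cutoff with unknown diagnosis status: still 0 only
  # if the diagnosis flag was observed
  unknown_dx <- !high & is.na(physician_dx) & !is.na(fpg_followup)
  out[unknown_dx] <- 0L
  out
}
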