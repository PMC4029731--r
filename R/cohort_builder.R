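#' Cohort inclusion/exclusion criteria
#'
#' Defaults encode the published retrospective design on 2005-2009 quarterly
#' Medicare claims: patients enter the ALS cohort when their first ALS claim
#' (ICD-9-CM 335.20) falls in Q1 2007-Q4 2009, they carry at least two ALS
#' claims in that window, are 65 or older at the first claim, have at least
#' 8 quarters (2 years) of enrollment before it, and are in the physician
#' office sample. The time-to-diagnosis subcohort further requires the first
#' ALS claim in Q1 2008-Q4 2009 (guaranteeing at least 3 years of prior
#' claims). The comparison cohort is every patient with no motor neuron
#' disease claim at all (the whole 335.* family).
#'
#' Windows are calendar quarter labels (`"2007Q1"`) so the same criteria work
#' for any dataset epoch.
#'
#' @param als_code ICD-9-CM code defining the index (diagnosis) event.
#' @param diagnosis_window Two quarter labels, inclusive.
#' @param ttd_window Two quarter labels, inclusive; must lie inside
#'   `diagnosis_window`.
#' @param min_als_claims Minimum number of claim lines carrying `als_code`.
#' @param min_age Minimum age (whole years) at the diagnosis quarter.
#' @param min_prior_enrollment Minimum whole quarters between enrollment
#'   start and the diagnosis quarter.
#' @param require_office_sample Require the physician-office-sample flag.
#' @param mnd_exclusion_patterns Code patterns excluding a patient from the
#'   comparison cohort.
#' @param count_claims_in_window If `TRUE` (default) only claims inside
#'   `diagnosis_window` count toward `min_als_claims`; if `FALSE`, all claims
#'   count.
#' @param comparison_window Calendar window for comparison-cohort prevalence.
#' @return An object of class `cohort_criteria`.
#' @export
cohort_criteria <- function(als_code = "335.20",
                            diagnosis_window = c("2007Q1", "2009Q4"),
                            ttd_window = c("2008Q1", "2009Q4"),
                            min_als_claims = 2L,
                            min_age = 65L,
                            min_prior_enrollment = 8L,
                            require_office_sample = TRUE,
                            mnd_exclusion_patterns = "335.X",
                            count_claims_in_window = TRUE,
                            comparison_window = c("2008Q1", "2009Q4")) {
  stopifnot(min_als_claims >= 1L)
  dw <- parse_quarter_label(diagnosis_window)
  tw <- parse_quarter_label(ttd_window)
  if (tw[1] < dw[1] || tw[2] > dw[2]) {
    stop("ttd_window must lie inside diagnosis_window", call. = FALSE)
  }
  mnd_exclusion_patterns <- vapply(mnd_exclusion_patterns,
                                   function(p) unclass(parse_code_pattern(p)), "")
  structure(list(
    als_code = normalize_icd9(als_code),
    diagnosis_window = diagnosis_window, ttd_window = ttd_window,
    min_als_claims = as.integer(min_als_claims), min_age = as.integer(min_age),
    min_prior_enrollment = as.integer(min_prior_enrollment),
    require_office_sample = isTRUE(require_office_sample),
    mnd_exclusion_patterns = unname(mnd_exclusion_patterns),
    count_claims_in_window = isTRUE(count_claims_in_window),
    comparison_window = comparison_window
  ), class = "cohort_criteria")
}

# per-patient eligibility facts, computed once; each criterion is a pure
# predicate of these so the final set is independent of application order
cohort_facts <- function(data, criteria) {
  dw <- window_indices(criteria$diagnosis_window, data$epoch_year)
  als <- data$claims[data$claims$code_kind == "dx" &
                       data$claims$code == criteria$als_code, ]
  first_q <- tapply(als$quarter, als$patient_id, min)
  n_claims <- if (criteria$count_claims_in_window) {
    inw <- als[als$quarter >= dw[1] & als$quarter <= dw[2], ]
    tapply(inw$quarter, inw$patient_id, length)
  } else {
    tapply(als$quarter, als$patient_id, length)
  }
  p <- data$patients
  dq <- as.integer(first_q[p$patient_id])
  tibble::tibble(
    patient_id = p$patient_id,
    diagnosis_quarter = dq,
    first_in_window = !is.na(dq) & dq >= dw[1] & dq <= dw[2],
    enough_claims = !is.na(dq) &
      dplyr::coalesce(as.integer(n_claims[p$patient_id]), 0L) >= criteria$min_als_claims,
    old_enough = !is.na(dq) &
      age_at_quarter(p$birth_year, dplyr::coalesce(dq, 0L), data$epoch_year) >= criteria$min_age,
    enrolled_long = !is.na(dq) &
      (dq - p$enrollment_start) >= criteria$min_prior_enrollment,
    office_ok = !criteria$require_office_sample | p$office_sample
  )
}

#' Build the ALS cohort with an attrition table
#'
#' Applies the inclusion criteria in their stated order, recording the number
#' of patients surviving each step (the eligibility funnel). The diagnosis
#' quarter is the quarter of the first ALS claim, fixed before any criterion
#' is evaluated, so the final cohort does not depend on the order in which
#' criteria are applied.
#'
#' @param data A [claims_data()] object.
#' @param criteria A [cohort_criteria()] object.
#' @return An object of class `cohort_result`: a list with `als` (tibble of
#'   `patient_id`, `diagnosis_quarter`), `ttd_ids`, `comparison_ids`,
#'   `attrition` (tibble of `criterion`, `remaining`), and the criteria.
#' @export
build_als_cohort <- function(data, criteria = cohort_criteria()) {
  stopifnot(inherits(data, "claims_data"), inherits(criteria, "cohort_criteria"))
  facts <- cohort_facts(data, criteria)
  keep <- rep(TRUE, nrow(facts))
  attrition <- tibble::tibble(criterion = "all patients", remaining = nrow(facts))
  apply_step <- function(label, flag) {
    keep <<- keep & flag
    attrition <<- dplyr::bind_rows(
      attrition, tibble::tibble(criterion = label, remaining = sum(keep)))
  }
  apply_step(sprintf("first %s claim in %s-%s", criteria$als_code,
                     criteria$diagnosis_window[1], criteria$diagnosis_window[2]),
             facts$first_in_window)
  apply_step(sprintf(">=%d %s claims", criteria$min_als_claims,
                     criteria$als_code), facts$enough_claims)
  apply_step(sprintf("age >=%d at first claim", criteria$min_age),
             facts$old_enough)
  apply_step(sprintf(">=%d quarters enrollment before first claim",
                     criteria$min_prior_enrollment), facts$enrolled_long)
  if (criteria$require_office_sample) {
    apply_step("in physician office sample", facts$office_ok)
  }
  als <- facts[keep, c("patient_id", "diagnosis_quarter")]
  structure(list(
    als = als,
    ttd_ids = character(),
    comparison_ids = build_comparison_cohort(data, criteria),
    attrition = attrition,
    criteria = criteria,
    epoch_year = data$epoch_year
  ), class = "cohort_result")
}

#' Restrict to the time-to-diagnosis subcohort
#'
#' Keeps ALS-cohort patients whose diagnosis quarter falls in the
#' time-to-diagnosis window, guaranteeing a longer pre-diagnosis claims
#' history for symptom lookback.
#'
#' @param result A `cohort_result` from [build_als_cohort()].
#' @param criteria Criteria (defaults to those stored in `result`).
#' @return `result` with `ttd_ids` filled in.
#' @export
build_ttd_cohort <- function(result, criteria = result$criteria) {
  stopifnot(inherits(result, "cohort_result"))
  tw <- window_indices(criteria$ttd_window, result$epoch_year)
  inw <- result$als$diagnosis_quarter >= tw[1] &
    result$als$diagnosis_quarter <= tw[2]
  result$ttd_ids <- result$als$patient_id[inw]
  result$attrition <- dplyr::bind_rows(
    result$attrition,
    tibble::tibble(
      criterion = sprintf("ttd subcohort: first claim in %s-%s",
                          criteria$ttd_window[1], criteria$ttd_window[2]),
      remaining = length(result$ttd_ids)))
  result
}

#' Build the comparison cohort
#'
#' Patients with zero claims matching any motor-neuron-disease exclusion
#' pattern. By construction this set is disjoint from the ALS cohort whenever
#' the exclusion patterns cover the index code.
#'
#' @param data A [claims_data()] object.
#' @param criteria A [cohort_criteria()] object.
#' @return Character vector of patient ids.
#' @export
build_comparison_cohort <- function(data, criteria = cohort_criteria()) {
  dx <- data$claims[data$claims$code_kind == "dx", ]
  mnd <- match_any_pattern(criteria$mnd_exclusion_patterns, dx$code)
  excluded <- unique(dx$patient_id[mnd])
  setdiff(data$patients$patient_id, excluded)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ALS cohort ", nrow(x$als), ", ttd subcohort ",
      length(x$ttd_ids), ", comparison ", length(x$comparison_ids),
      "\n", sep = "")
  print(x$attrition)
  invisible(x)
}
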