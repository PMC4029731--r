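#' Detect the first-symptom quarter for cohort patients
#'
#' Implements the claims-based first-symptom rule: scanning quarters in
#' ascending order from enrollment through the diagnosis quarter inclusive, a
#' quarter marks the first ALS symptom when it contains at least one
#' high-likelihood symptom code, or codes for two distinct moderate-likelihood
#' diagnoses of interest (distinct labels - two claims of the same code do not
#' trigger). The onset category is derived from the union of all symptom
#' definitions matched in the onset quarter: `limb` when all are limb,
#' `bulbar` when all are bulbar, `both` when limb and bulbar co-occur, and
#' `none` when no quarter triggers.
#'
#' @param data A [claims_data()] object.
#' @param cohort A `cohort_result`; onset is called for the time-to-diagnosis
#'   subcohort when it is non-empty, otherwise for the full ALS cohort.
#' @param catalog A [code_catalog()]; only its symptom definitions (the
#'   bulbar/limb rule book) participate.
#' @return Tibble of onset calls: `patient_id`, `onset_quarter` (`NA` when no
#'   trigger), `onset_category` (`limb`/`bulbar`/`both`/`none`),
#'   `ttd_quarters`, `ttd_years`, `trigger_codes`, `trigger_labels`
#'   (`;`-joined).
#' @export
detect_onset <- function(data, cohort, catalog = default_catalog()) {
  stopifnot(inherits(data, "claims_data"), inherits(cohort, "cohort_result"))
  ids <- if (length(cohort$ttd_ids)) cohort$ttd_ids else cohort$als$patient_id
  target <- cohort$als[cohort$als$patient_id %in% ids, ]
  claim_rows <- split(seq_len(nrow(data$claims)), data$claims$patient_id)
  calls <- lapply(seq_len(nrow(target)), function(i) {
    pid <- target$patient_id[i]
    find_first_symptom(
      data$claims[claim_rows[[pid]], ], catalog,
      diagnosis_quarter = target$diagnosis_quarter[i],
      enrollment_start = data$patients$enrollment_start[
        match(pid, data$patients$patient_id)],
      patient_id = pid)
  })
  dplyr::bind_rows(calls)
}

#' Find the first-symptom quarter for one patient
#'
#' @param claims Tibble of the patient's claim lines (`quarter`, `code_kind`,
#'   `code`, and optionally `patient_id`).
#' @param catalog A [code_catalog()].
#' @param diagnosis_quarter Quarter index of the first ALS claim; the scan
#'   includes this quarter, so a time to diagnosis of zero is possible.
#' @param enrollment_start Quarter index at which the scan starts.
#' @param patient_id Identifier echoed into the result.
#' @return One-row onset-call tibble (see [detect_onset()]).
#' @examples
#' cl <- tibble::tibble(quarter = 6L, setting = "outpatient",
#'                      code_kind = "dx", code = "728.87")
#' find_first_symptom(cl, default_catalog(), diagnosis_quarter = 10L,
#'                    enrollment_start = 0L)
#' @export
find_first_symptom <- function(claims, catalog, diagnosis_quarter,
                               enrollment_start = 0L,
                               patient_id = "patient") {
  if (diagnosis_quarter < enrollment_start) {
    stop("diagnosis_quarter precedes enrollment_start", call. = FALSE)
  }
  dx <- claims[claims$code_kind == "dx" &
                 claims$quarter >= enrollment_start &
                 claims$quarter <= diagnosis_quarter, c("quarter", "code")]
  none <- tibble::tibble(
    patient_id = patient_id, onset_quarter = NA_integer_,
    onset_category = "none", ttd_quarters = NA_integer_,
    ttd_years = NA_real_, trigger_codes = "", trigger_labels = "")
  if (nrow(dx) == 0L) return(none)
  dx$code <- normalize_icd9(dx$code)
  hits <- dplyr::inner_join(dx, classify_codes(catalog, dx$code),
                            by = "code", relationship = "many-to-many")
  if (nrow(hits) == 0L) return(none)
  per_q <- dplyr::summarise(
    dplyr::group_by(hits, .data$quarter),
    trigger = any(.data$likelihood == "high") |
      dplyr::n_distinct(.data$label[.data$likelihood == "moderate"]) >= 2L,
    .groups = "drop")
  trig_q <- per_q$quarter[per_q$trigger]
  if (length(trig_q) == 0L) return(none)
  oq <- min(trig_q)
  fired <- dplyr::distinct(hits[hits$quarter == oq,
                                c("code", "label", "likelihood", "category")])
  tibble::tibble(
    patient_id = patient_id, onset_quarter = as.integer(oq),
    onset_category = onset_category_of(fired$category),
    ttd_quarters = as.integer(diagnosis_quarter - oq),
    ttd_years = 0.25 * (diagnosis_quarter - oq),
    trigger_codes = paste(sort(unique(fired$code)), collapse = ";"),
    trigger_labels = paste(unique(fired$label), collapse = ";"))
}

onset_category_of <- function(categories) {
  has_limb <- "limb" %in% categories
  has_bulbar <- "bulbar" %in% categories
  if (has_limb && has_bulbar) "both" else if (has_limb) "limb" else "bulbar"
}

#' Onset category from a triggering definition set
#'
#' @param call A one-row onset-call tibble with a non-empty trigger, or a
#'   character vector of triggering categories (`"limb"`/`"bulbar"`).
#' @return `"limb"`, `"bulbar"`, or `"both"`.
#' @export
classify_onset <- function(call) {
  if (is.character(call)) {
    if (length(call) == 0L) stop("empty trigger set", call. = FALSE)
    return(onset_category_of(match.arg(call, symptom_categories,
                                       several.ok = TRUE)))
  }
  if (!nzchar(call$trigger_labels)) stop("empty trigger set", call. = FALSE)
  call$onset_category
}

#' Time from symptom onset to diagnosis, in years
#'
#' @param onset_quarter,diagnosis_quarter Quarter indices; onset must not
#'   follow diagnosis.
#' @return `0.25 * (diagnosis_quarter - onset_quarter)`.
#' @examples
#' time_to_diagnosis(10, 20) # 2.5
#' @export
time_to_diagnosis <- function(onset_quarter, diagnosis_quarter) {
  if (any(diagnosis_quarter < onset_quarter)) {
    stop("onset_quarter after diagnosis_quarter: corrupt input", call. = FALSE)
  }
  0.25 * (diagnosis_quarter - onset_quarter)
}

#' Summarize onset calls
#'
#' Onset-category proportions and median times to diagnosis. Proportions are
#' reported both over patients with a classified onset (the primary
#' denominator) and over all patients including unclassified ones, since a
#' cohort can contain patients no quarter of whose history triggers the rule.
#'
#' @param calls Onset-call tibble from [detect_onset()].
#' @return List with `n`, `n_classified`, `proportions_pct` (named, whole
#'   percent of classified patients), `proportions_all_pct` (denominator all
#'   patients), `median_ttd_years` (overall, classified patients), and
#'   `median_ttd_by_category`.
#' @export
onset_summary <- function(calls) {
  if (nrow(calls) == 0L) stop("no onset calls to summarize", call. = FALSE)
  cls <- calls[calls$onset_category != "none", ]
  cats <- c("limb", "bulbar", "both")
  counts <- vapply(cats, function(k) sum(cls$onset_category == k), 1L)
  med_by <- vapply(cats, function(k) {
    v <- cls$ttd_years[cls$onset_category == k]
    if (length(v)) median_quarters(v) else NA_real_
  }, 1)
  list(
    n = nrow(calls),
    n_classified = nrow(cls),
    proportions_pct = round_half_up(100 * counts / max(nrow(cls), 1L)),
    proportions_all_pct = round_half_up(100 * counts / nrow(calls)),
    median_ttd_years = if (nrow(cls)) median_quarters(cls$ttd_years) else NA_real_,
    median_ttd_by_category = med_by
  )
}
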