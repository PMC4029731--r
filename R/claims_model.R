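claim_settings <- c("inpatient", "outpatient", "physician_office")
code_kinds <- c("dx", "px")

#' Assemble a quarter-granular claims dataset
#'
#' The container pairs patient enrollment metadata with claim lines, all
#' timed in integer quarter indices under a shared epoch. Claims are sorted
#' by patient and quarter; duplicate identical lines are retained, since a
#' code can legitimately be billed repeatedly.
#'
#' @param patients Tibble with columns `patient_id`, `birth_year`,
#'   `enrollment_start` (quarter index), `death_quarter` (quarter index or
#'   `NA`), `office_sample` (logical).
#' @param claims Tibble with columns `patient_id`, `quarter` (quarter index),
#'   `setting` (`inpatient`/`outpatient`/`physician_office`), `code_kind`
#'   (`dx` for ICD-9-CM diagnoses, `px` for procedure-group identifiers),
#'   `code`.
#' @param epoch_year Calendar year whose Q1 is quarter 0 for this dataset.
#' @return An object of class `claims_data`.
#' @export
claims_data <- function(patients, claims, epoch_year = 2005) {
  patients <- tibble::as_tibble(patients)
  claims <- tibble::as_tibble(claims)
  need_p <- c("patient_id", "birth_year", "enrollment_start", "death_quarter",
              "office_sample")
  need_c <- c("patient_id", "quarter", "setting", "code_kind", "code")
  miss <- setdiff(need_p, names(patients))
  if (length(miss)) stop("patients table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_c, names(claims))
  if (length(miss)) stop("claims table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  bad <- !claims$setting %in% claim_settings
  if (any(bad)) {
    stop("unknown claim setting at claim row ", which(bad)[1], ": \"",
         claims$setting[which(bad)[1]], "\"", call. = FALSE)
  }
  bad <- !claims$code_kind %in% code_kinds
  if (any(bad)) {
    stop("unknown code_kind at claim row ", which(bad)[1], ": \"",
         claims$code_kind[which(bad)[1]], "\"", call. = FALSE)
  }
  orphan <- !claims$patient_id %in% patients$patient_id
  if (any(orphan)) {
    stop("claim row ", which(orphan)[1], " references unknown patient \"",
         claims$patient_id[which(orphan)[1]], "\"", call. = FALSE)
  }
  enroll <- patients$enrollment_start[match(claims$patient_id, patients$patient_id)]
  early <- claims$quarter < enroll
  if (any(early)) {
    stop("claim row ", which(early)[1], " (patient \"",
         claims$patient_id[which(early)[1]],
         "\") predates enrollment start", call. = FALSE)
  }
  if (any(!is.na(patients$death_quarter) &
          patients$death_quarter < patients$enrollment_start)) {
    stop("death_quarter before enrollment_start", call. = FALSE)
  }
  claims$quarter <- as.integer(claims$quarter)
  claims$code <- ifelse(claims$code_kind == "dx",
                        normalize_icd9(claims$code), claims$code)
  claims <- dplyr::arrange(claims, .data$patient_id, .data$quarter)
  structure(list(patients = patients, claims = claims,
                 epoch_year = as.integer(epoch_year)),
            class = "claims_data")
}

#' @export
print.claims_data <- function(x, ...) {
  cat("<claims_data> ", nrow(x$patients), " patients, ", nrow(x$claims),
      " claims, epoch Q1 ", x$epoch_year, "\n", sep = "")
  invisible(x)
}

#' Read a claims dataset from CSV files
#'
#' Claims CSV dialect: header `patient_id,year,quarter,setting,code_kind,code`
#' with settings spelled `inpatient|outpatient|physician_office` and code
#' kinds `dx|px`. Patient metadata CSV: header
#' `patient_id,birth_year,enroll_year,enroll_quarter,death_year,death_quarter,office_sample`
#' with empty death fields allowed and `office_sample` as `TRUE`/`FALSE`.
#' Validation failures (missing column, bad quarter, unknown setting, claim
#' before enrollment) raise an error naming the offending row.
#'
#' @param claims_path Path to the claims CSV.
#' @param patients_path Path to the patient metadata CSV.
#' @param epoch_year Epoch for quarter indexing.
#' @return A [claims_data()] object.
#' @export
read_claims <- function(claims_path, patients_path, epoch_year = 2005) {
  check_header <- function(path, need) {
    have <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
    miss <- setdiff(need, have)
    if (length(miss)) {
      stop(basename(path), ": missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  check_header(claims_path, c("patient_id", "year", "quarter", "setting",
                              "code_kind", "code"))
  check_header(patients_path, c("patient_id", "birth_year", "enroll_year",
                                "enroll_quarter", "death_year",
                                "death_quarter", "office_sample"))
  cl <- readr::read_csv(claims_path, col_types = readr::cols(
    patient_id = readr::col_character(), year = readr::col_integer(),
    quarter = readr::col_integer(), setting = readr::col_character(),
    code_kind = readr::col_character(), code = readr::col_character()
  ))
  pt <- readr::read_csv(patients_path, col_types = readr::cols(
    patient_id = readr::col_character(), birth_year = readr::col_integer(),
    enroll_year = readr::col_integer(), enroll_quarter = readr::col_integer(),
    death_year = readr::col_integer(), death_quarter = readr::col_integer(),
    office_sample = readr::col_logical()
  ))
  bad <- is.na(cl$quarter) | cl$quarter < 1L | cl$quarter > 4L
  if (any(bad)) {
    stop("unparseable quarter at claims line ", which(bad)[1] + 1L,
         call. = FALSE)
  }
  patients <- tibble::tibble(
    patient_id = pt$patient_id,
    birth_year = pt$birth_year,
    enrollment_start = quarter_of(pt$enroll_year, pt$enroll_quarter, epoch_year),
    death_quarter = ifelse(
      is.na(pt$death_year), NA_integer_,
      quarter_of(ifelse(is.na(pt$death_year), 2005L, pt$death_year),
                 ifelse(is.na(pt$death_quarter), 1L, pt$death_quarter),
                 epoch_year)),
    office_sample = pt$office_sample
  )
  claims <- tibble::tibble(
    patient_id = cl$patient_id,
    quarter = quarter_of(cl$year, cl$quarter, epoch_year),
    setting = cl$setting, code_kind = cl$code_kind, code = cl$code
  )
  claims_data(patients, claims, epoch_year)
}

#' Write a claims dataset to CSV files
#'
#' Inverse of [read_claims()]: `read_claims()` on the written files
#' reproduces the dataset.
#'
#' @param data A [claims_data()] object.
#' @inheritParams read_claims
#' @return The two paths, invisibly.
#' @export
write_claims <- function(data, claims_path, patients_path) {
  stopifnot(inherits(data, "claims_data"))
  yq <- quarter_year(data$claims$quarter, data$epoch_year)
  readr::write_csv(tibble::tibble(
    patient_id = data$claims$patient_id, year = yq$year, quarter = yq$quarter,
    setting = data$claims$setting, code_kind = data$claims$code_kind,
    code = data$claims$code
  ), claims_path)
  p <- data$patients
  eyq <- quarter_year(p$enrollment_start, data$epoch_year)
  dead <- !is.na(p$death_quarter)
  dyq <- quarter_year(ifelse(dead, p$death_quarter, 0L), data$epoch_year)
  readr::write_csv(tibble::tibble(
    patient_id = p$patient_id, birth_year = p$birth_year,
    enroll_year = eyq$year, enroll_quarter = eyq$quarter,
    death_year = ifelse(dead, dyq$year, NA_integer_),
    death_quarter = ifelse(dead, dyq$quarter, NA_integer_),
    office_sample = p$office_sample
  ), patients_path)
  invisible(c(claims_path, patients_path))
}

#' Age in whole years at a given quarter
#'
#' Quarter granularity cannot resolve mid-year birthdays, so age is the
#' difference between the quarter's calendar year and the birth year.
#' @noRd
age_at_quarter <- function(birth_year, quarter, epoch_year) {
  quarter_year(quarter, epoch_year)$year - birth_year
}
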