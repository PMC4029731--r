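# shared fixture builders and independent oracles

# one-call constructor for small hand-built datasets:
# claims given as list of c(pid, quarter, code) triples (dx, outpatient)
make_data <- function(patient_ids, claims_rows, birth_year = 1930,
                      enrollment_start = 0L, office_sample = TRUE,
                      epoch_year = 2005) {
  patients <- tibble::tibble(
    patient_id = patient_ids,
    birth_year = rep_len(as.integer(birth_year), length(patient_ids)),
    enrollment_start = rep_len(as.integer(enrollment_start),
                               length(patient_ids)),
    death_quarter = NA_integer_,
    office_sample = rep_len(office_sample, length(patient_ids)))
  claims <- if (length(claims_rows)) {
    dplyr::bind_rows(lapply(claims_rows, function(r) tibble::tibble(
      patient_id = r$pid, quarter = as.integer(r$q),
      setting = if (is.null(r$setting)) "outpatient" else r$setting,
      code_kind = if (is.null(r$kind)) "dx" else r$kind,
      code = r$code)))
  } else {
    tibble::tibble(patient_id = character(), quarter = integer(),
                   setting = character(), code_kind = character(),
                   code = character())
  }
  claims_data(patients, claims, epoch_year)
}

cl_row <- function(pid, q, code, kind = "dx", setting = "outpatient") {
  list(pid = pid, q = q, code = code, kind = kind, setting = setting)
}

# naive per-quarter re-classification oracle for the first-symptom rule:
# loops quarters, classifies every code independently, applies the
# one-high-or-two-distinct-moderate rule literally
oracle_first_symptom <- function(claims, catalog, diagnosis_quarter,
                                 enrollment_start = 0L) {
  for (q in seq(enrollment_start, diagnosis_quarter)) {
    codes <- claims$code[claims$code_kind == "dx" & claims$quarter == q]
    if (!length(codes)) next
    defs <- dplyr::bind_rows(lapply(unique(normalize_icd9(codes)),
                                    function(cd) classify_code(catalog, cd)))
    if (!nrow(defs)) next
    high <- any(defs$likelihood == "high")
    n_mod <- length(unique(defs$label[defs$likelihood == "moderate"]))
    if (high || n_mod >= 2L) {
      cats <- unique(defs$category)
      category <- if (all(cats == "limb")) "limb"
      else if (all(cats == "bulbar")) "bulbar" else "both"
      return(list(onset_quarter = q, onset_category = category))
    }
  }
  list(onset_quarter = NA_integer_, onset_category = "none")
}

# random claim history over the rule-book codes plus noise codes
random_history <- function(catalog, n_claims = 6L, max_quarter = 12L) {
  pool <- c(unlist(lapply(catalog$symptoms$patterns, function(ps) {
    ifelse(endsWith(ps, "X"), paste0(substr(ps, 1, nchar(ps) - 1L), "3"), ps)
  })), "401.9", "250.00", "V04.81", "786.2")
  tibble::tibble(
    patient_id = "P1",
    quarter = sample.int(max_quarter + 1L, n_claims, replace = TRUE) - 1L,
    setting = sample(c("inpatient", "outpatient", "physician_office"),
                     n_claims, replace = TRUE),
    code_kind = "dx",
    code = sample(pool, n_claims, replace = TRUE))
}
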