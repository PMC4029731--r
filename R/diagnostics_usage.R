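#' Distribution of symptom onset lag relative to diagnosis
#'
#' For each listed symptom/diagnosis group, each ALS-cohort patient's lag is
#' `diagnosis_quarter` minus the first quarter (from enrollment through
#' diagnosis) carrying a matching code; patients without the code are omitted
#' from that row. The lag here is anchored on the specific code group, not on
#' the onset rule, so a moderate code alone defines its own symptom's lag.
#' Lags are binned into 0-3, 4-7, 8-11, and 12+ quarters.
#'
#' @param cohort A `cohort_result`.
#' @param data A [claims_data()] object.
#' @param catalog A [code_catalog()].
#' @param symptom_labels Labels of symptom/diagnosis groups in the catalog.
#' @return Tibble `(label, n, mean_quarters, median_quarters, pct_0_3,
#'   pct_4_7, pct_8_11, pct_12plus)`; percentages are whole percent of
#'   contributing patients.
#' @export
symptom_lag_distribution <- function(cohort, data, catalog = default_catalog(),
                                     symptom_labels) {
  rows <- lapply(symptom_labels, function(lbl) {
    g <- catalog_group(catalog, lbl)
    if (g$group_kind != "symptom_or_diagnosis") {
      stop("\"", lbl, "\" is not a symptom/diagnosis group", call. = FALSE)
    }
    lags <- symptom_lags(cohort, data, g)
    if (length(lags) == 0L) {
      return(tibble::tibble(
        label = lbl, n = 0L, mean_quarters = NA_real_,
        median_quarters = NA_real_, pct_0_3 = NA_real_, pct_4_7 = NA_real_,
        pct_8_11 = NA_real_, pct_12plus = NA_real_))
    }
    bins <- c(mean(lags >= 0 & lags <= 3), mean(lags >= 4 & lags <= 7),
              mean(lags >= 8 & lags <= 11), mean(lags >= 12))
    tibble::tibble(
      label = lbl, n = length(lags),
      mean_quarters = mean(lags),
      median_quarters = median_quarters(lags),
      pct_0_3 = round_half_up(100 * bins[1]),
      pct_4_7 = round_half_up(100 * bins[2]),
      pct_8_11 = round_half_up(100 * bins[3]),
      pct_12plus = round_half_up(100 * bins[4]))
  })
  dplyr::bind_rows(rows)
}

# per-patient lag (quarters) from first in-scope claim of the group to dx
symptom_lags <- function(cohort, data, group) {
  cl <- data$claims[group_claim_mask(data$claims, group), ]
  dq <- cohort$als$diagnosis_quarter[match(cl$patient_id, cohort$als$patient_id)]
  ok <- !is.na(dq) & cl$quarter <= dq
  cl <- cl[ok, ]; dq <- dq[ok]
  if (nrow(cl) == 0L) return(integer())
  first_q <- tapply(cl$quarter, cl$patient_id, min)
  dq_of <- cohort$als$diagnosis_quarter[match(names(first_q),
                                              cohort$als$patient_id)]
  as.integer(dq_of - first_q)
}

#' Diagnostic-test utilization and median time to diagnosis
#'
#' Percent of the cohort (or an onset-category subgroup) with at least one
#' matching procedure-group claim in the `lookback` quarters before, and
#' excluding, the diagnosis quarter; and the median time to diagnosis (from
#' first limb/bulbar symptom) among patients who had the test. The median is
#' suppressed as not determined (`nd = TRUE`, `median_ttd_years = NA`) when
#' fewer than `min_n` patients with the test contribute.
#'
#' @param cohort A `cohort_result`.
#' @param data A [claims_data()] object.
#' @param test_group One-row group tibble with `group_kind`
#'   `"diagnostic_test"`.
#' @param onset Onset-call tibble from [detect_onset()] (needed for the
#'   median and for subgroup restriction).
#' @param subgroup Optional onset category (`"limb"`, `"bulbar"`, `"both"`)
#'   restricting the denominator.
#' @param lookback Window length in quarters (default 8).
#' @param min_n Minimum contributing patients for a reportable median
#'   (default 11).
#' @return One-row tibble `(label, subgroup, n, n_with_test, pct_with_test,
#'   median_ttd_years, nd)`.
#' @export
test_utilization <- function(cohort, data, test_group, onset = NULL,
                             subgroup = NULL, lookback = 8L, min_n = 11L) {
  if (test_group$group_kind != "diagnostic_test") {
    stop("\"", test_group$label, "\" is not a diagnostic_test group",
         call. = FALSE)
  }
  base <- cohort$als
  if (length(cohort$ttd_ids)) base <- base[base$patient_id %in% cohort$ttd_ids, ]
  if (!is.null(subgroup)) {
    subgroup <- match.arg(subgroup, c("limb", "bulbar", "both"))
    if (is.null(onset)) stop("subgroup restriction requires onset calls",
                             call. = FALSE)
    keep <- onset$patient_id[onset$onset_category == subgroup]
    base <- base[base$patient_id %in% keep, ]
  }
  cl <- data$claims[group_claim_mask(data$claims, test_group), ]
  dq <- base$diagnosis_quarter[match(cl$patient_id, base$patient_id)]
  inw <- !is.na(dq) & cl$quarter >= dq - lookback & cl$quarter <= dq - 1L
  with_test <- unique(cl$patient_id[inw])
  ttd <- if (is.null(onset)) numeric() else {
    onset$ttd_years[onset$patient_id %in% with_test &
                      onset$onset_category != "none"]
  }
  nd <- length(with_test) < min_n
  tibble::tibble(
    label = test_group$label,
    subgroup = if (is.null(subgroup)) "all" else subgroup,
    n = nrow(base),
    n_with_test = length(with_test),
    pct_with_test = if (nrow(base)) 100 * length(with_test) / nrow(base) else NA_real_,
    median_ttd_years = if (!nd && length(ttd)) median_quarters(ttd) else NA_real_,
    nd = nd)
}

#' Test-utilization table across cohort and onset subgroups
#'
#' One row per diagnostic-test group per denominator (whole cohort, limb
#' subgroup, bulbar subgroup).
#'
#' @inheritParams test_utilization
#' @param catalog A [code_catalog()].
#' @param subgroups Onset categories to report alongside the full cohort.
#' @return Tibble of [test_utilization()] rows.
#' @export
test_utilization_table <- function(cohort, data, catalog = default_catalog(),
                                   onset = NULL,
                                   subgroups = c("limb", "bulbar"),
                                   lookback = 8L, min_n = 11L) {
  tg <- catalog$groups[catalog$groups$group_kind == "diagnostic_test", ]
  rows <- list()
  for (i in seq_len(nrow(tg))) {
    rows[[length(rows) + 1L]] <-
      test_utilization(cohort, data, tg[i, ], onset, NULL, lookback, min_n)
    for (s in subgroups) {
      rows[[length(rows) + 1L]] <-
        test_utilization(cohort, data, tg[i, ], onset, s, lookback, min_n)
    }
  }
  dplyr::bind_rows(rows)
}
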