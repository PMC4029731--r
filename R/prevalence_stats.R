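group_claim_mask <- function(claims, group) {
  if (group$group_kind == "diagnostic_test") {
    claims$code_kind == "px" & claims$code %in% group$patterns[[1]]
  } else {
    claims$code_kind == "dx" & match_any_pattern(group$patterns[[1]], claims$code)
  }
}

#' Pre-diagnosis prevalence of a code group in the ALS cohort
#'
#' Percent of ALS-cohort patients with at least one claim matching the group
#' in the lookback window, the `lookback` quarters ending the quarter before
#' diagnosis (the diagnosis quarter itself is excluded). The unrounded
#' percentage is returned; round only for display.
#'
#' @param cohort A `cohort_result` from [build_als_cohort()].
#' @param data A [claims_data()] object.
#' @param group One-row group tibble ([code_group()] / [catalog_group()]).
#' @param lookback Window length in quarters (default 8, i.e. 2 years).
#' @return Percent in `[0, 100]`.
#' @export
pre_diagnosis_prevalence <- function(cohort, data, group, lookback = 8L) {
  stopifnot(lookback >= 1L)
  if (nrow(cohort$als) == 0L) stop("empty ALS cohort", call. = FALSE)
  cl <- data$claims[group_claim_mask(data$claims, group), ]
  dq <- cohort$als$diagnosis_quarter[match(cl$patient_id, cohort$als$patient_id)]
  inw <- !is.na(dq) & cl$quarter >= dq - lookback & cl$quarter <= dq - 1L
  100 * length(unique(cl$patient_id[inw])) / nrow(cohort$als)
}

#' Prevalence of a code group in the comparison cohort
#'
#' Percent of comparison-cohort patients with at least one matching claim
#' inside a fixed calendar window (no per-patient anchoring; the comparison
#' cohort has no index event).
#'
#' @inheritParams pre_diagnosis_prevalence
#' @param window Two quarter labels, inclusive (default the criteria's
#'   comparison window).
#' @return Percent in `[0, 100]`.
#' @export
comparison_prevalence <- function(cohort, data, group,
                                  window = cohort$criteria$comparison_window) {
  ids <- cohort$comparison_ids
  if (length(ids) == 0L) stop("empty comparison cohort", call. = FALSE)
  w <- window_indices(window, data$epoch_year)
  cl <- data$claims[group_claim_mask(data$claims, group), ]
  inw <- cl$patient_id %in% ids & cl$quarter >= w[1] & cl$quarter <= w[2]
  100 * length(unique(cl$patient_id[inw])) / length(ids)
}

#' Prevalence rate ratio
#'
#' ALS-cohort pre-diagnosis percentage divided by comparison-cohort
#' percentage, computed on unrounded percentages. A zero comparison
#' percentage with a positive ALS percentage yields `Inf` with attribute
#' `undefined = TRUE`; 0/0 yields 0, also flagged. Display with one decimal,
#' rounded half up (see [format_ratio()]).
#'
#' @param pre_als_pct,medicare_pct Percentages in `[0, 100]`.
#' @return Nonnegative ratio (possibly `Inf`), with attribute `undefined`
#'   when the denominator is zero.
#' @examples
#' prevalence_ratio(27, 7) # 3.857..., displays as 3.9
#' @export
prevalence_ratio <- function(pre_als_pct, medicare_pct) {
  if (pre_als_pct < 0 || medicare_pct < 0) {
    stop("percentages must be nonnegative", call. = FALSE)
  }
  if (medicare_pct == 0) {
    out <- if (pre_als_pct > 0) Inf else 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  pre_als_pct / medicare_pct
}

#' @rdname prevalence_ratio
#' @param ratio A ratio from [prevalence_ratio()].
#' @export
format_ratio <- function(ratio) {
  if (is.infinite(ratio)) return("Inf")
  formatC(round_half_up(ratio, 1), format = "f", digits = 1)
}

#' Keep the reportable prevalence rows
#'
#' The published tables report code groups with a pre-diagnosis prevalence of
#' at least `min_prevalence` percent in the ALS cohort OR a prevalence ratio
#' of at least `min_ratio`, ordered by descending ratio (stable for ties).
#' Idempotent.
#'
#' @param rows Tibble with `pre_als_pct` and `prevalence_ratio` columns.
#' @param min_prevalence,min_ratio Inclusive thresholds.
#' @return Filtered, re-ordered tibble.
#' @export
filter_reported_rows <- function(rows, min_prevalence = 10, min_ratio = 5) {
  keep <- rows$pre_als_pct >= min_prevalence |
    rows$prevalence_ratio >= min_ratio
  out <- rows[keep, ]
  out[order(-out$prevalence_ratio), ]
}

#' Median of quarter-valued durations
#'
#' Standard median with midpoint interpolation for even counts; on durations
#' that are multiples of 0.25 years this can land between quarters (e.g.
#' `c(2.75, 3.0)` gives 2.875, displayed 2.88).
#'
#' @param values Non-empty numeric vector (years, multiples of 0.25).
#' @return The median (unrounded; round to 2 decimals for display).
#' @export
median_quarters <- function(values) {
  if (length(values) == 0L) stop("median of empty vector", call. = FALSE)
  stats::median(values)
}

#' Full prevalence table for all symptom/diagnosis groups
#'
#' One row per symptom/diagnosis group in the catalog: pre-diagnosis ALS
#' prevalence, comparison prevalence, and their ratio (unrounded, plus
#' display-rounded columns).
#'
#' @inheritParams pre_diagnosis_prevalence
#' @param catalog A [code_catalog()].
#' @param window Comparison window (quarter labels).
#' @param onset Optional onset-call tibble; when supplied, a
#'   `median_ttd_years` column is added per group, the median time to
#'   diagnosis (from first limb/bulbar symptom) among patients with the group
#'   in-window.
#' @return Tibble `(symptom_group, label, pre_als_pct, medicare_pct,
#'   prevalence_ratio, pre_als_pct_display, medicare_pct_display,
#'   ratio_display[, median_ttd_years])`.
#' @export
prevalence_table <- function(cohort, data, catalog = default_catalog(),
                             lookback = 8L,
                             window = cohort$criteria$comparison_window,
                             onset = NULL) {
  gs <- catalog$groups[catalog$groups$group_kind == "symptom_or_diagnosis", ]
  rows <- lapply(seq_len(nrow(gs)), function(i) {
    g <- gs[i, ]
    pre <- pre_diagnosis_prevalence(cohort, data, g, lookback)
    med <- comparison_prevalence(cohort, data, g, window)
    tibble::tibble(
      symptom_group = g$symptom_group, label = g$label,
      pre_als_pct = pre, medicare_pct = med,
      prevalence_ratio = as.numeric(prevalence_ratio(pre, med)))
  })
  out <- dplyr::bind_rows(rows)
  out$pre_als_pct_display <- round_half_up(out$pre_als_pct)
  out$medicare_pct_display <- round_half_up(out$medicare_pct)
  out$ratio_display <- vapply(out$prevalence_ratio, format_ratio, "")
  if (!is.null(onset)) {
    out$median_ttd_years <- vapply(seq_len(nrow(gs)), function(i) {
      g <- gs[i, ]
      cl <- data$claims[group_claim_mask(data$claims, g), ]
      dq <- cohort$als$diagnosis_quarter[match(cl$patient_id,
                                               cohort$als$patient_id)]
      inw <- !is.na(dq) & cl$quarter >= dq - lookback & cl$quarter <= dq - 1L
      with_g <- unique(cl$patient_id[inw])
      v <- onset$ttd_years[onset$patient_id %in% with_g &
                             onset$onset_category != "none"]
      if (length(v)) median_quarters(v) else NA_real_
    }, 1)
  }
  out
}
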