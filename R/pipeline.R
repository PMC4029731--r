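#' Run the full diagnostic-pathway pipeline
#'
#' Executes cohort construction, onset calling, prevalence rate ratios, lag
#' distributions, and test-utilization tabulation on one dataset, logging
#' per-stage counts to `message()`. All stages are deterministic, so fixed
#' inputs yield identical outputs.
#'
#' @param data A [claims_data()] object.
#' @param catalog A [code_catalog()].
#' @param criteria A [cohort_criteria()].
#' @param lookback Lookback window in quarters for prevalence and test
#'   utilization.
#' @param min_prevalence,min_ratio Reporting thresholds for the prevalence
#'   table (see [filter_reported_rows()]).
#' @param nd_min_n Minimum contributing patients for a reportable
#'   test-utilization median.
#' @param lag_symptoms Symptom-group labels for the lag table.
#' @param quiet Suppress per-stage messages.
#' @return List of class `als_report`: `cohort` (the `cohort_result`),
#'   `attrition`, `onset` (calls), `onset_summary`, `prevalence` (filtered
#'   table), `prevalence_full`, `lag`, `tests`.
#' @export
run_pipeline <- function(data, catalog = default_catalog(),
                         criteria = cohort_criteria(), lookback = 8L,
                         min_prevalence = 10, min_ratio = 5, nd_min_n = 11L,
                         lag_symptoms = c("Muscle weakness (generalized)",
                                          "Gait abnormality",
                                          "Difficulty in walking",
                                          "Lack of coordination",
                                          "Speech disturbance",
                                          "Voice resonance disorder",
                                          "Dysphagia"),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[alsclaims] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("cohort", {
    r <- build_ttd_cohort(build_als_cohort(data, criteria))
    say("cohort: ", nrow(r$als), " ALS, ", length(r$ttd_ids),
        " ttd, ", length(r$comparison_ids), " comparison patients")
    r
  })
  onset <- stage("onset", {
    o <- detect_onset(data, cohort, catalog)
    say("onset: ", sum(o$onset_category != "none"), "/", nrow(o),
        " patients classified")
    o
  })
  osum <- stage("onset-summary", onset_summary(onset))
  prev_full <- stage("prevalence", {
    p <- prevalence_table(cohort, data, catalog, lookback,
                          criteria$comparison_window, onset = onset)
    say("prevalence: ", nrow(p), " groups tabulated")
    p
  })
  prev <- filter_reported_rows(prev_full, min_prevalence, min_ratio)
  lag <- stage("lag", symptom_lag_distribution(cohort, data, catalog,
                                               lag_symptoms))
  tests <- stage("tests", test_utilization_table(cohort, data, catalog,
                                                 onset, lookback = lookback,
                                                 min_n = nd_min_n))
  structure(list(
    cohort = cohort, attrition = cohort$attrition, onset = onset,
    onset_summary = osum, prevalence = prev, prevalence_full = prev_full,
    lag = lag, tests = tests
  ), class = "als_report")
}

#' @export
print.als_report <- function(x, ...) {
  s <- x$onset_summary
  cat("<als_report>\n")
  cat("  ALS cohort ", nrow(x$cohort$als), ", ttd subcohort ",
      length(x$cohort$ttd_ids), ", comparison ",
      length(x$cohort$comparison_ids), "\n", sep = "")
  cat("  onset mix (% of classified): ",
      paste(names(s$proportions_pct), s$proportions_pct, sep = " ",
            collapse = ", "), "\n", sep = "")
  cat("  median ttd (years): overall ", s$median_ttd_years, "; ",
      paste(names(s$median_ttd_by_category), s$median_ttd_by_category,
            sep = " ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a report bundle as CSV files
#'
#' Writes `attrition.csv`, `onset.csv`, `onset_summary.csv`,
#' `prevalence.csv`, `lag.csv`, and `tests.csv` under `dir`.
#'
#' @param report An `als_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Named paths, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "als_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- report$onset_summary
  onset_sum <- tibble::tibble(
    category = c(names(s$proportions_pct), "overall"),
    pct_of_classified = c(unname(s$proportions_pct), 100),
    pct_of_all = c(unname(s$proportions_all_pct),
                   round_half_up(100 * s$n_classified / s$n)),
    median_ttd_years = c(unname(s$median_ttd_by_category),
                         s$median_ttd_years))
  paths <- c(attrition = "attrition.csv", onset = "onset.csv",
             onset_summary = "onset_summary.csv",
             prevalence = "prevalence.csv", lag = "lag.csv",
             tests = "tests.csv")
  paths <- vapply(paths, function(p) file.path(dir, p), "")
  readr::write_csv(report$attrition, paths[["attrition"]])
  readr::write_csv(report$onset, paths[["onset"]])
  readr::write_csv(onset_sum, paths[["onset_summary"]])
  readr::write_csv(report$prevalence, paths[["prevalence"]])
  readr::write_csv(report$lag, paths[["lag"]])
  readr::write_csv(report$tests, paths[["tests"]])
  invisible(paths)
}
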