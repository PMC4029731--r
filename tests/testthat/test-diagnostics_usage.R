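catalog <- default_catalog()
sensory <- catalog_group(catalog, "Sensory nerve conduction test")

als_cohort_with <- function(extra_rows, n = 4) {
  ids <- LETTERS[seq_len(n)]
  rows <- unlist(lapply(ids, function(id) {
    list(cl_row(id, 13, "335.20"), cl_row(id, 13, "335.20"))
  }), recursive = FALSE)
  d <- make_data(c(ids, "Z"), c(rows, extra_rows))
  list(data = d, cohort = build_als_cohort(d))
}

test_that("symptom lags bin by quarters from first code to diagnosis", {
  # planted first occurrences at lags 0, 1, 1, 2 quarters before diagnosis
  x <- als_cohort_with(list(
    cl_row("A", 13, "787.2"), cl_row("B", 12, "787.2"),
    cl_row("C", 12, "787.2"), cl_row("C", 13, "787.2"), # first occurrence wins
    cl_row("D", 11, "787.2")))
  row <- symptom_lag_distribution(x$cohort, x$data, catalog, "Dysphagia")
  expect_equal(row$n, 4L)
  expect_equal(row$mean_quarters, 1.0)
  expect_equal(row$median_quarters, 1.0)
  expect_equal(c(row$pct_0_3, row$pct_4_7, row$pct_8_11, row$pct_12plus),
               c(100, 0, 0, 0))
})

test_that("a 12-quarter lag lands in the open top bin", {
  x <- als_cohort_with(list(cl_row("A", 1, "787.2")))
  row <- symptom_lag_distribution(x$cohort, x$data, catalog, "Dysphagia")
  expect_equal(row$pct_12plus, 100)
  expect_equal(row$n, 1L)
})

test_that("lag bins equal a brute-force histogram on random lags", {
  set.seed(401)
  n <- 40
  ids <- sprintf("L%02d", seq_len(n))
  lags <- sample(0:13, n, replace = TRUE)
  rows <- unlist(lapply(seq_len(n), function(i) list(
    cl_row(ids[i], 13, "335.20"), cl_row(ids[i], 13, "335.20"),
    cl_row(ids[i], 13L - lags[i], "728.87"))), recursive = FALSE)
  d <- make_data(ids, rows)
  cohort <- build_als_cohort(d)
  row <- symptom_lag_distribution(cohort, d, catalog,
                                  "Muscle weakness (generalized)")
  brute <- table(cut(lags, c(-1, 3, 7, 11, Inf)))
  expect_equal(row$n, n)
  expect_equal(c(row$pct_0_3, row$pct_4_7, row$pct_8_11, row$pct_12plus),
               unname(floor(100 * as.vector(brute) / n + 0.5)))
  expect_equal(row$mean_quarters, mean(lags))
  expect_equal(row$median_quarters, median(lags))
  expect_error(symptom_lag_distribution(cohort, d, catalog, "no such group"),
               "unknown analysis group")
})

test_that("test utilization counts in-window procedure claims once", {
  x <- als_cohort_with(list(
    cl_row("A", 7, "NCT_SENSORY", kind = "px"),
    cl_row("A", 8, "NCT_SENSORY", kind = "px"))) # same patient, counts once
  row <- test_utilization(x$cohort, x$data, sensory, min_n = 1)
  expect_equal(row$pct_with_test, 25)
  expect_equal(row$n_with_test, 1L)
  # a test claim in the diagnosis quarter is outside the window
  y <- als_cohort_with(list(cl_row("A", 13, "NCT_SENSORY", kind = "px")))
  expect_equal(test_utilization(y$cohort, y$data, sensory,
                                min_n = 1)$pct_with_test, 0)
})

test_that("small contributing subgroups are marked not determined", {
  x <- als_cohort_with(list(cl_row("A", 7, "NCT_SENSORY", kind = "px"),
                            cl_row("A", 6, "728.87")))
  onset <- detect_onset(x$data, x$cohort)
  nd <- test_utilization(x$cohort, x$data, sensory, onset, min_n = 11)
  expect_true(nd$nd)
  expect_true(is.na(nd$median_ttd_years))
  ok <- test_utilization(x$cohort, x$data, sensory, onset, min_n = 1)
  expect_false(ok$nd)
  expect_equal(ok$median_ttd_years, 0.25 * (13 - 6))
})

test_that("subgroup counts add up to the cohort count", {
  cfg <- simulation_config(seed = 55, n_als = 80, n_background = 50)
  pop <- simulate_population(cfg)
  cohort <- build_ttd_cohort(build_als_cohort(pop$data,
                                              simulation_criteria(cfg)))
  onset <- detect_onset(pop$data, cohort)
  whole <- test_utilization(cohort, pop$data, sensory, onset)
  parts <- vapply(c("limb", "bulbar", "both"), function(s) {
    test_utilization(cohort, pop$data, sensory, onset, subgroup = s)$n_with_test
  }, 1L)
  unclassified <- whole$n_with_test - sum(parts)
  n_none <- sum(onset$onset_category == "none")
  expect_gte(unclassified, 0L)
  expect_lte(unclassified, n_none)
  expect_equal(sum(vapply(c("limb", "bulbar", "both"), function(s) {
    test_utilization(cohort, pop$data, sensory, onset, subgroup = s)$n
  }, 1L)) + n_none, whole$n)
})

test_that("planted utilization differences by onset type are recovered", {
  set.seed(77)
  cfg <- simulation_config(seed = 660, n_als = 250, n_background = 10)
  pop <- simulate_population(cfg)
  cohort <- build_ttd_cohort(build_als_cohort(pop$data,
                                              simulation_criteria(cfg)))
  onset <- detect_onset(pop$data, cohort)
  throat <- catalog_group(catalog, "Exam of throat and/or upper gastrointestinal tract")
  limb <- test_utilization(cohort, pop$data, throat, onset, subgroup = "limb")
  bulbar <- test_utilization(cohort, pop$data, throat, onset,
                             subgroup = "bulbar", min_n = 1)
  # planted 15% (limb) vs 48% (bulbar); each within 3 binomial SE
  se_l <- 100 * sqrt(0.15 * 0.85 / limb$n)
  se_b <- 100 * sqrt(0.48 * 0.52 / bulbar$n)
  expect_lt(abs(limb$pct_with_test - 15), 3 * se_l)
  expect_lt(abs(bulbar$pct_with_test - 48), 3 * se_b)
  expect_gt(bulbar$pct_with_test, limb$pct_with_test)
})
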