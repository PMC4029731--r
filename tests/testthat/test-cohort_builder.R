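# a hand-built population in which each patient fails exactly one criterion
mini_population <- function() {
  rows <- list(
    # P1: fully eligible, first ALS claim 2008Q2 (quarter 13)
    cl_row("P1", 4, "728.87"), cl_row("P1", 13, "335.20"),
    cl_row("P1", 14, "335.20"),
    # P2: only one ALS claim
    cl_row("P2", 13, "335.20"),
    # P3: first ALS claim 2006Q3 (quarter 6), before the diagnosis window
    cl_row("P3", 6, "335.20"), cl_row("P3", 13, "335.20"),
    cl_row("P3", 14, "335.20"),
    # P4: eligible claims but too young
    cl_row("P4", 13, "335.20"), cl_row("P4", 14, "335.20"),
    # P5: enrolled too recently (enrollment quarter 9, diagnosis 13)
    cl_row("P5", 13, "335.20"), cl_row("P5", 14, "335.20"),
    # P6: not in the physician office sample
    cl_row("P6", 13, "335.20"), cl_row("P6", 14, "335.20"),
    # P7: background patient, never any motor neuron disease code
    cl_row("P7", 13, "724.2"),
    # P8: other motor neuron disease code only (335.21)
    cl_row("P8", 13, "335.21"))
  d <- make_data(paste0("P", 1:8), rows)
  d$patients$birth_year[4] <- 1948L # age 60 at 2008
  d$patients$enrollment_start[5] <- 9L
  d$patients$office_sample[6] <- FALSE
  claims_data(d$patients, d$claims)
}

test_that("each inclusion criterion excludes exactly its designed patient", {
  res <- build_ttd_cohort(build_als_cohort(mini_population()))
  expect_equal(res$als$patient_id, "P1")
  expect_equal(res$als$diagnosis_quarter, 13L)
  expect_equal(res$ttd_ids, "P1")
  # comparison excludes every patient with any 335.* claim, including P8
  expect_setequal(res$comparison_ids, "P7")
  expect_equal(res$attrition$remaining[1], 8L)
  expect_true(all(diff(res$attrition$remaining) <= 0))
})

test_that("the time-to-diagnosis window splits the cohort as planted", {
  # 30 patients diagnosed inside 2008Q1-2009Q4, 20 diagnosed in 2007
  ids <- sprintf("T%02d", 1:50)
  dq <- c(rep(13L, 30), rep(9L, 20))
  rows <- unlist(lapply(seq_along(ids), function(i) {
    list(cl_row(ids[i], dq[i], "335.20"), cl_row(ids[i], dq[i], "335.20"))
  }), recursive = FALSE)
  res <- build_ttd_cohort(build_als_cohort(make_data(ids, rows)))
  expect_equal(nrow(res$als), 50L)
  expect_equal(length(res$ttd_ids), 30L)
  expect_setequal(res$ttd_ids, ids[1:30])
  expect_equal(res$als$diagnosis_quarter[match("T40", res$als$patient_id)], 9L)
})

test_that("cohort membership matches an independent per-patient re-check", {
  cfg <- simulation_config(seed = 11, n_als = 50, n_background = 120)
  pop <- simulate_population(cfg)
  criteria <- simulation_criteria(cfg)
  res <- build_als_cohort(pop$data, criteria)
  expect_setequal(res$als$patient_id, pop$truth$patient_id)
  expect_equal(length(res$comparison_ids), 120L)

  # oracle: evaluate every criterion independently, per patient, from raw rows
  dw <- parse_quarter_label(criteria$diagnosis_window, pop$data$epoch_year)
  for (pid in sample(pop$data$patients$patient_id, 30)) {
    cl <- pop$data$claims[pop$data$claims$patient_id == pid, ]
    p <- pop$data$patients[pop$data$patients$patient_id == pid, ]
    als <- cl[cl$code_kind == "dx" & cl$code == "335.20", ]
    eligible <- nrow(als) > 0 &&
      min(als$quarter) >= dw[1] && min(als$quarter) <= dw[2] &&
      sum(als$quarter >= dw[1] & als$quarter <= dw[2]) >= 2 &&
      (pop$data$epoch_year + min(als$quarter) %/% 4 - p$birth_year) >= 65 &&
      (min(als$quarter) - p$enrollment_start) >= 8 &&
      p$office_sample
    expect_equal(pid %in% res$als$patient_id, eligible, label = pid)
  }
})

test_that("attrition is monotone and the final set is order-independent", {
  cfg <- simulation_config(seed = 12, n_als = 40, n_background = 60)
  pop <- simulate_population(cfg)
  # corrupt some patients so several criteria actually bite
  pop$data$patients$birth_year[1:5] <- 1950L
  pop$data$patients$office_sample[6:10] <- FALSE
  criteria <- simulation_criteria(cfg)
  res <- build_als_cohort(pop$data, criteria)
  expect_true(all(diff(res$attrition$remaining) <= 0))
  expect_equal(nrow(res$als), 30L)
  # order independence: the surviving set is the intersection of independent
  # predicates, so demanding office sample first must not change membership
  no_office <- cohort_criteria(
    diagnosis_window = criteria$diagnosis_window,
    require_office_sample = FALSE)
  relaxed <- build_als_cohort(pop$data, no_office)
  with_office <- relaxed$als$patient_id[
    pop$data$patients$office_sample[
      match(relaxed$als$patient_id, pop$data$patients$patient_id)]]
  expect_setequal(res$als$patient_id, with_office)
})

test_that("claim-count restriction to the diagnosis window is switchable", {
  # two ALS claims, but only one inside the window
  rows <- list(cl_row("A", 6, "335.20"), cl_row("A", 13, "335.20"))
  d <- make_data("A", rows)
  strict <- build_als_cohort(d) # first claim at quarter 6: outside window
  expect_equal(nrow(strict$als), 0L)
  # first claim in-window but second claim outside it
  rows2 <- list(cl_row("B", 13, "335.20"), cl_row("B", 13, "724.2"))
  d2 <- make_data("B", rows2)
  expect_equal(nrow(build_als_cohort(d2)$als), 0L)
  d3 <- make_data("C", list(cl_row("C", 13, "335.20"),
                            cl_row("C", 14, "335.20")))
  expect_equal(nrow(build_als_cohort(d3)$als), 1L)
})

test_that("cohorts nest and never overlap", {
  cfg <- simulation_config(seed = 13, n_als = 30, n_background = 50)
  pop <- simulate_population(cfg)
  res <- build_ttd_cohort(build_als_cohort(pop$data, simulation_criteria(cfg)))
  expect_true(all(res$ttd_ids %in% res$als$patient_id))
  expect_length(intersect(res$comparison_ids, res$als$patient_id), 0L)
  expect_true(all(res$als$patient_id %in% pop$data$patients$patient_id))
})
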