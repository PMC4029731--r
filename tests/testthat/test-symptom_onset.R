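catalog <- default_catalog()

test_that("a single high-likelihood code defines the first-symptom quarter", {
  cl <- tibble::tibble(patient_id = "A", quarter = 6L, setting = "outpatient",
                       code_kind = "dx", code = "728.87")
  call <- find_first_symptom(cl, catalog, diagnosis_quarter = 10L)
  expect_equal(call$onset_quarter, 6L)
  expect_equal(call$onset_category, "limb")
  expect_equal(call$ttd_quarters, 4L)
  expect_equal(call$ttd_years, 1.0)
  expect_match(call$trigger_labels, "Muscle weakness")
})

test_that("two distinct moderate diagnoses in one quarter are required", {
  cl <- dplyr::bind_rows(
    tibble::tibble(patient_id = "A", quarter = 4L, setting = "outpatient",
                   code_kind = "dx", code = "719.4"),
    tibble::tibble(patient_id = "A", quarter = 5L, setting = "outpatient",
                   code_kind = "dx", code = c("719.4", "729.5")))
  call <- find_first_symptom(cl, catalog, diagnosis_quarter = 8L)
  expect_equal(call$onset_quarter, 5L) # the lone moderate at Q4 cannot fire
  expect_equal(call$onset_category, "limb")
  # two claims of the same moderate code never trigger
  rep_cl <- tibble::tibble(patient_id = "A", quarter = 4L,
                           setting = "outpatient", code_kind = "dx",
                           code = c("719.4", "719.4"))
  none <- find_first_symptom(rep_cl, catalog, diagnosis_quarter = 8L)
  expect_equal(none$onset_category, "none")
  expect_true(is.na(none$onset_quarter))
})

test_that("onset category reflects the union of definitions in the quarter", {
  cl <- tibble::tibble(patient_id = "A", quarter = 3L, setting = "inpatient",
                       code_kind = "dx", code = c("728.87", "784.3"))
  call <- find_first_symptom(cl, catalog, diagnosis_quarter = 5L)
  expect_equal(call$onset_category, "both")
  bulbar <- find_first_symptom(
    tibble::tibble(patient_id = "A", quarter = 3L, setting = "inpatient",
                   code_kind = "dx", code = "787.2"), catalog, 5L)
  expect_equal(bulbar$onset_category, "bulbar")
  expect_equal(classify_onset(c("limb", "bulbar")), "both")
  expect_equal(classify_onset(c("limb", "limb")), "limb")
  expect_error(classify_onset(character()), "empty trigger")
  expect_error(classify_onset(none_call <- find_first_symptom(
    tibble::tibble(patient_id = "A", quarter = integer(),
                   setting = character(), code_kind = character(),
                   code = character()), catalog, 5L)), "empty trigger")
})

test_that("the diagnosis quarter itself can carry the first symptom", {
  cl <- tibble::tibble(patient_id = "A", quarter = 7L, setting = "outpatient",
                       code_kind = "dx", code = "781.2")
  call <- find_first_symptom(cl, catalog, diagnosis_quarter = 7L)
  expect_equal(call$onset_quarter, 7L)
  expect_equal(call$ttd_years, 0.0)
})

test_that("time to diagnosis is a quarter count scaled to years", {
  expect_equal(time_to_diagnosis(10, 20), 2.5)
  expect_equal(time_to_diagnosis(7, 7), 0.0)
  expect_error(time_to_diagnosis(9, 8), "corrupt")
})

test_that("onset calls are stable under claim addition after onset and
           removal of non-triggering claims", {
  set.seed(101)
  for (i in 1:40) {
    cl <- random_history(catalog, n_claims = 8, max_quarter = 10)
    base <- find_first_symptom(cl, catalog, diagnosis_quarter = 10L)
    if (!is.na(base$onset_quarter)) {
      # append claims strictly after onset
      extra <- tibble::tibble(
        patient_id = "P1", quarter = base$onset_quarter + 1L,
        setting = "outpatient", code_kind = "dx", code = "787.2")
      again <- find_first_symptom(dplyr::bind_rows(cl, extra), catalog, 10L)
      expect_identical(again, base)
    }
    # drop one claim that never matches any definition
    noise <- which(vapply(cl$code, function(cd)
      nrow(classify_code(catalog, cd)) == 0L, TRUE))
    if (length(noise)) {
      thinned <- find_first_symptom(cl[-noise[1], ], catalog, 10L)
      expect_identical(thinned, base)
    }
  }
})

test_that("onset detection equals the brute-force per-quarter oracle", {
  set.seed(202)
  for (i in 1:120) {
    cl <- random_history(catalog, n_claims = sample(1:10, 1),
                         max_quarter = 12)
    got <- find_first_symptom(cl, catalog, diagnosis_quarter = 12L)
    want <- oracle_first_symptom(cl, catalog, 12L)
    expect_equal(got$onset_quarter, want$onset_quarter, label = paste("run", i))
    expect_equal(got$onset_category, want$onset_category,
                 label = paste("run", i))
  }
})

test_that("onset summaries report both denominators and quarter medians", {
  calls <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:100),
    onset_quarter = 1L,
    onset_category = c(rep("limb", 74), rep("bulbar", 17), rep("both", 8),
                       "none"),
    ttd_quarters = c(rep(10L, 74), rep(5L, 17), rep(1L, 8), NA),
    ttd_years = c(rep(2.5, 74), rep(1.25, 17), rep(0.25, 8), NA),
    trigger_codes = "x", trigger_labels = "x")
  s <- onset_summary(calls)
  expect_equal(s$n, 100L)
  expect_equal(s$n_classified, 99L)
  # classified-denominator proportions: 74/99, 17/99, 8/99 in whole percent
  expect_equal(unname(s$proportions_pct), c(75, 17, 8))
  expect_equal(unname(s$proportions_all_pct), c(74, 17, 8))
  expect_equal(unname(s$median_ttd_by_category), c(2.5, 1.25, 0.25))
  expect_equal(median_quarters(c(1.0, 1.5)), 1.25)
  expect_equal(onset_summary(calls[1:10, ])$median_ttd_years, 2.5)
})
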