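#' Default background (comparison-cohort) period prevalences, percent
#'
#' Eight-quarter period prevalence targets per symptom/diagnosis group for
#' simulated comparison patients, matching the general-Medicare column of the
#' published prevalence tables. Converted to per-quarter Bernoulli rates
#' inside the generator via `r = 1 - (1 - p)^(1/8)` so the planted
#' period prevalence over any 8-quarter window equals the target.
#'
#' @return Named numeric vector (percent).
#' @export
default_background_rates <- function() {
  c("Speech disturbance" = 2, "Voice resonance disorder" = 1,
    "Muscle weakness (generalized)" = 5, "Lack of coordination" = 3,
    "Dysphagia" = 7, "Hereditary and idiopathic peripheral neuropathies" = 10,
    "Cervicalgia" = 5, "Gait abnormality/difficulty walking" = 11,
    "Transient cerebral ischemia" = 5, "Loss of weight" = 6, "Stroke" = 4,
    "Lumbago/backache" = 27, "Malaise and fatigue" = 32,
    "Syncope and collapse" = 14, "Pain in limb" = 27,
    "Esophageal reflux" = 21, "Constipation" = 10,
    "Pulmonary collapse/failure" = 12, "Dizziness and giddiness" = 8,
    "Swelling in limb" = 8, "Respiratory difficulties" = 49,
    "Hypothyroidism" = 22, "Nausea, vomiting, etc." = 9, "Pain in joint" = 26,
    "Bronchitis" = 14, "Chronic airway obstruction" = 17,
    "Acute upper respiratory infection" = 11,
    "Chronic inflammatory demyelinating polyneuropathy" = 0.5,
    "Myopathy (including myopathy with weakness)" = 0.5,
    "Unspecified disease of spinal cord" = 0.5,
    "Cervical/thoracic or lumbar spondylosis with myelopathy" = 1,
    "Atrophy, muscular disuse" = 1)
}

#' Default ALS pre-diagnosis symptom prevalences, percent
#'
#' Probability that a simulated ALS patient carries at least one claim for
#' the group in the 8 quarters before diagnosis, matching the ALS-cohort
#' column of the published prevalence tables. By default only groups whose
#' codes cannot fire the onset rule are planted (see
#' [simulation_config()]'s `als_background_groups`).
#'
#' @return Named numeric vector (percent).
#' @export
default_als_symptom_rates <- function() {
  c("Speech disturbance" = 24, "Voice resonance disorder" = 15,
    "Muscle weakness (generalized)" = 30, "Lack of coordination" = 13,
    "Dysphagia" = 27, "Hereditary and idiopathic peripheral neuropathies" = 35,
    "Cervicalgia" = 18, "Gait abnormality/difficulty walking" = 32,
    "Transient cerebral ischemia" = 13, "Loss of weight" = 17, "Stroke" = 11,
    "Lumbago/backache" = 52, "Malaise and fatigue" = 56,
    "Syncope and collapse" = 26, "Pain in limb" = 44,
    "Esophageal reflux" = 31, "Constipation" = 15,
    "Pulmonary collapse/failure" = 17, "Dizziness and giddiness" = 12,
    "Swelling in limb" = 11, "Respiratory difficulties" = 62,
    "Hypothyroidism" = 27, "Nausea, vomiting, etc." = 11,
    "Pain in joint" = 31, "Bronchitis" = 18, "Chronic airway obstruction" = 19,
    "Acute upper respiratory infection" = 12,
    "Chronic inflammatory demyelinating polyneuropathy" = 2,
    "Myopathy (including myopathy with weakness)" = 8,
    "Unspecified disease of spinal cord" = 5,
    "Cervical/thoracic or lumbar spondylosis with myelopathy" = 6,
    "Atrophy, muscular disuse" = 5)
}

#' Default diagnostic-test utilization probabilities by onset category
#'
#' Probability of at least one procedure-group claim in the 8 quarters before
#' diagnosis, per test and onset category, matching the published
#' test-utilization table (the `both` category uses the whole-cohort column).
#'
#' @return Tibble `(label, limb, bulbar, both)` with probabilities in percent.
#' @export
default_test_probabilities <- function() {
  tibble::tribble(
    ~label, ~limb, ~bulbar, ~both,
    "Sensory nerve conduction test", 41, 30, 38,
    "Motor nerve conduction test with F-wave", 30, 18, 26,
    "Motor nerve conduction test without F-wave", 24, 18, 23,
    "MRI of neck and spine without dye", 29, 15, 25,
    "CT scans (head or brain) with/without contrast material", 43, 19, 39,
    "MRI of brain with/without dye", 29, 28, 28,
    "Limb electromyography (2 extremities and related paraspinal areas)", 22, 12, 19,
    "Limb electromyography (1 extremity and related paraspinal areas)", 18, 10, 16,
    "Exam of throat and/or upper gastrointestinal tract", 15, 48, 22)
}

#' Configure the synthetic claims generator
#'
#' The generator emulates the structure of the source data: quarterly claim
#' bundles, an index ALS diagnosis (335.20), onset-consistent symptom codes
#' planted with per-category lead times before the index event, elevated
#' pre-diagnosis symptom rates in ALS patients, background code rates in
#' comparison patients, and diagnostic-test procedure claims. Defaults plant
#' the study conditions reported for the source cohort: a 74/17/8 limb /
#' bulbar / both onset mix and per-category median lead times of 10, 5, and 1
#' quarters (2.5, 1.25, and 0.25 years).
#'
#' Lead times are geometric (memoryless, one parameter per category),
#' parameterized by their target median; the simulation spans Q1 2000-Q4 2009
#' so pre-diagnosis histories are long enough that truncation of lead times
#' at enrollment is rare.
#'
#' @param seed Integer RNG seed; the same seed yields byte-identical output.
#' @param n_als,n_background Patient counts.
#' @param onset_mix Probabilities for categories limb/bulbar/both
#'   (renormalized to sum to 1).
#' @param lead_median_quarters Named target medians (quarters) of the
#'   geometric lead-time distributions per onset category.
#' @param background_rates Named 8-quarter period prevalences (percent) per
#'   group for comparison patients; see [default_background_rates()].
#' @param als_symptom_rates Named pre-diagnosis prevalences (percent) per
#'   group for ALS patients; see [default_als_symptom_rates()].
#' @param als_background_groups Which groups from `als_symptom_rates` are
#'   planted in ALS patients: `"onset_safe"` (default) plants only groups
#'   whose codes cannot fire the onset rule, so planted onsets stay exactly
#'   recoverable; `"all"` plants every group, adding false-trigger pressure
#'   on the onset rule; `"none"` disables planting.
#' @param test_probabilities Tibble as [default_test_probabilities()]
#'   (percent).
#' @param epoch_year,horizon_end Simulation epoch (Q1 of `epoch_year` is
#'   quarter 0) and last simulated quarter label.
#' @param diagnosis_window Calendar window (quarter labels) for index events.
#' @param birth_year_range Inclusive range for sampled birth years.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_als = 300L,
                              n_background = 3000L,
                              onset_mix = c(limb = 74, bulbar = 17, both = 8),
                              lead_median_quarters = c(limb = 10, bulbar = 5,
                                                       both = 1),
                              background_rates = default_background_rates(),
                              als_symptom_rates = default_als_symptom_rates(),
                              als_background_groups = c("onset_safe", "all",
                                                        "none"),
                              test_probabilities = default_test_probabilities(),
                              epoch_year = 2000L,
                              horizon_end = "2009Q4",
                              diagnosis_window = c("2007Q1", "2009Q4"),
                              birth_year_range = c(1920L, 1938L)) {
  stopifnot(n_als >= 0L, n_background >= 0L)
  if (any(onset_mix < 0) || sum(onset_mix) <= 0) {
    stop("onset_mix must be nonnegative with positive sum", call. = FALSE)
  }
  onset_mix <- onset_mix[c("limb", "bulbar", "both")] / sum(onset_mix)
  if (anyNA(onset_mix)) {
    stop("onset_mix needs named limb, bulbar, both entries", call. = FALSE)
  }
  if (any(background_rates < 0 | background_rates > 100) ||
      any(als_symptom_rates < 0 | als_symptom_rates > 100)) {
    stop("rates must be percentages in [0, 100]", call. = FALSE)
  }
  if (any(lead_median_quarters < 0)) {
    stop("lead-time medians must be nonnegative", call. = FALSE)
  }
  dw <- parse_quarter_label(diagnosis_window, epoch_year)
  hz <- parse_quarter_label(horizon_end, epoch_year)
  if (dw[2] > hz || dw[1] > dw[2]) {
    stop("diagnosis window must lie inside the simulation horizon",
         call. = FALSE)
  }
  if (dw[1] < 8L) {
    stop("infeasible config: diagnosis window starts less than 8 quarters ",
         "after the simulation horizon start, leaving too little enrollment ",
         "history", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_als = as.integer(n_als),
    n_background = as.integer(n_background), onset_mix = onset_mix,
    lead_median_quarters = lead_median_quarters,
    background_rates = background_rates,
    als_symptom_rates = als_symptom_rates,
    als_background_groups = match.arg(als_background_groups),
    test_probabilities = test_probabilities,
    epoch_year = as.integer(epoch_year), horizon_end = horizon_end,
    diagnosis_window = diagnosis_window,
    birth_year_range = as.integer(birth_year_range)
  ), class = "simulation_config")
}

# geometric success probability whose median equals m quarters
geom_p_for_median <- function(m) 1 - 2^(-1 / (m + 0.5))

# one concrete code for a pattern ("784.5X" -> "784.51"); exact patterns
# stand for themselves
concretize_pattern <- function(pattern) {
  ifelse(endsWith(pattern, "X"),
         paste0(substr(pattern, 1, nchar(pattern) - 1L), "1"), pattern)
}

onset_plant_codes <- list(
  limb = c("728.87", "781.2", "719.7", "781.3"),
  bulbar = c("787.2", "784.51", "784.41"))

#' Cohort criteria matching a simulation's windows
#'
#' @param config A [simulation_config()].
#' @return A [cohort_criteria()] whose diagnosis window equals the
#'   simulation's; other thresholds keep their defaults.
#' @export
simulation_criteria <- function(config) {
  cohort_criteria(diagnosis_window = config$diagnosis_window)
}

#' Simulate a claims population with known ground truth
#'
#' ALS patients receive: enrollment at the simulation horizon start (at least
#' 8 quarters before any possible index event), a diagnosis quarter uniform
#' in the diagnosis window, a planted onset quarter at `diagnosis - lead`
#' (truncated at enrollment) carrying one high-likelihood code of the planted
#' category (a limb and a bulbar code for `both`), planted pre-diagnosis
#' symptom-group claims, two index-code (335.20) claims in the diagnosis
#' quarter, and diagnostic-test procedure claims. Background patients receive
#' per-quarter Bernoulli draws of symptom-group claims and never carry a
#' 335.* code.
#'
#' @param config A [simulation_config()].
#' @param catalog Catalog supplying group code lists (default
#'   [default_catalog()]).
#' @return List of class `als_simulation`: `data` (a [claims_data()]),
#'   `truth` (tibble `patient_id, category, diagnosis_quarter, onset_quarter,
#'   lead_quarters, onset_codes`), and `config`.
#' @export
simulate_population <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ep <- config$epoch_year
  dw <- parse_quarter_label(config$diagnosis_window, ep)
  hz <- parse_quarter_label(config$horizon_end, ep)
  n_q <- hz + 1L
  settings <- c("inpatient", "outpatient", "physician_office")

  group_of <- function(lbl) catalog_group(catalog, lbl)
  # concrete code options per group, resolved once
  group_codes <- function(lbl) concretize_pattern(group_of(lbl)$patterns[[1]])
  draw_codes <- function(options, n) {
    if (length(options) == 1L) rep(options, n) else
      sample(options, n, replace = TRUE)
  }

  claims <- list()
  add_claims <- function(pid, quarter, code_kind, code) {
    n <- length(quarter)
    if (n == 0L) return()
    claims[[length(claims) + 1L]] <<- tibble::tibble(
      patient_id = pid, quarter = as.integer(quarter),
      setting = sample(settings, n, replace = TRUE),
      code_kind = code_kind, code = code)
  }

  # ---- ALS patients -----------------------------------------------------
  truth <- NULL
  if (config$n_als > 0L) {
    ids <- sprintf("ALS%04d", seq_len(config$n_als))
    cat_draw <- sample(names(config$onset_mix), config$n_als, replace = TRUE,
                       prob = config$onset_mix)
    dq <- sample(seq(dw[1], dw[2]), config$n_als, replace = TRUE)
    lead_for <- function(categ) {
      m <- config$lead_median_quarters[[if (categ == "both") "both" else categ]]
      stats::rgeom(1L, geom_p_for_median(m))
    }
    plant <- lapply(seq_len(config$n_als), function(i) {
      categ <- cat_draw[i]
      lead <- lead_for(categ)
      oq <- max(0L, dq[i] - lead)
      codes <- switch(categ,
        limb = sample(onset_plant_codes$limb, 1L),
        bulbar = sample(onset_plant_codes$bulbar, 1L),
        both = c(sample(onset_plant_codes$limb, 1L),
                 sample(onset_plant_codes$bulbar, 1L)))
      list(category = categ, dq = dq[i], oq = oq, codes = codes)
    })
    for (i in seq_len(config$n_als)) {
      p <- plant[[i]]
      add_claims(ids[i], rep(p$oq, length(p$codes)), "dx", p$codes)
      add_claims(ids[i], rep(p$dq, 2L), "dx", rep("335.20", 2L))
    }
    # planted pre-diagnosis symptom claims
    rates <- config$als_symptom_rates
    if (config$als_background_groups == "none") rates <- rates[0]
    if (config$als_background_groups == "onset_safe") {
      safe <- !vapply(names(rates), group_overlaps_onset, TRUE,
                      catalog = catalog)
      rates <- rates[safe]
    }
    for (lbl in names(rates)) {
      hit <- which(stats::runif(config$n_als) < rates[[lbl]] / 100)
      if (!length(hit)) next
      q <- dq[hit] - sample(8L, length(hit), replace = TRUE)
      add_claims(ids[hit], q, "dx", draw_codes(group_codes(lbl), length(hit)))
    }
    # diagnostic-test procedure claims
    tp <- config$test_probabilities
    for (j in seq_len(nrow(tp))) {
      g <- group_of(tp$label[j])
      pr <- vapply(cat_draw, function(k) tp[[k]][j] / 100, 1)
      hit <- which(stats::runif(config$n_als) < pr)
      if (!length(hit)) next
      q <- dq[hit] - sample(8L, length(hit), replace = TRUE)
      add_claims(ids[hit], q, "px", rep(g$patterns[[1]][1], length(hit)))
    }
    truth <- tibble::tibble(
      patient_id = ids,
      category = vapply(plant, function(p) p$category, ""),
      diagnosis_quarter = vapply(plant, function(p) as.integer(p$dq), 1L),
      onset_quarter = vapply(plant, function(p) as.integer(p$oq), 1L),
      lead_quarters = vapply(plant, function(p) as.integer(p$dq - p$oq), 1L),
      onset_codes = vapply(plant, function(p) paste(p$codes, collapse = ";"), ""))
  } else {
    truth <- tibble::tibble(
      patient_id = character(), category = character(),
      diagnosis_quarter = integer(), onset_quarter = integer(),
      lead_quarters = integer(), onset_codes = character())
  }

  # ---- background patients ---------------------------------------------
  bg_ids <- if (config$n_background > 0L) {
    sprintf("BG%05d", seq_len(config$n_background))
  } else character()
  for (lbl in names(config$background_rates)) {
    r <- 1 - (1 - config$background_rates[[lbl]] / 100)^(1 / 8)
    if (r <= 0 || config$n_background == 0L) next
    draws <- stats::runif(config$n_background * n_q) < r
    if (!any(draws)) next
    idx <- which(draws) - 1L
    pid <- bg_ids[idx %/% n_q + 1L]
    q <- idx %% n_q
    add_claims(pid, q, "dx", draw_codes(group_codes(lbl), length(pid)))
  }

  patients <- tibble::tibble(
    patient_id = c(if (config$n_als > 0L) sprintf("ALS%04d",
                                                  seq_len(config$n_als)),
                   bg_ids),
    birth_year = sample(seq(config$birth_year_range[1],
                            config$birth_year_range[2]),
                        config$n_als + config$n_background, replace = TRUE),
    enrollment_start = 0L,
    death_quarter = NA_integer_,
    office_sample = TRUE)

  cl <- if (length(claims)) dplyr::bind_rows(claims) else tibble::tibble(
    patient_id = character(), quarter = integer(), setting = character(),
    code_kind = character(), code = character())
  structure(list(
    data = claims_data(patients, cl, epoch_year = ep),
    truth = truth, config = config
  ), class = "als_simulation")
}

#' @export
print.als_simulation <- function(x, ...) {
  cat("<als_simulation> ", x$config$n_als, " ALS + ", x$config$n_background,
      " background patients, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated population as CSV fixtures
#'
#' Emits `claims.csv` and `patients.csv` in the [read_claims()] dialect plus
#' `truth.csv` with the planted ground truth.
#'
#' @param population An `als_simulation` from [simulate_population()].
#' @param dir Output directory (created if missing).
#' @return Named paths, invisibly.
#' @export
write_fixture <- function(population, dir) {
  stopifnot(inherits(population, "als_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(claims = file.path(dir, "claims.csv"),
             patients = file.path(dir, "patients.csv"),
             truth = file.path(dir, "truth.csv"))
  write_claims(population$data, paths[["claims"]], paths[["patients"]])
  readr::write_csv(population$truth, paths[["truth"]])
  invisible(paths)
}
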