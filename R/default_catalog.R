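#' The default ALS symptom and analysis-group catalog
#'
#' Encodes the published rule book for claims-based ALS first-symptom
#' detection: each diagnosis of interest with its likelihood tier (high
#' likelihood: a single code marks the first-symptom quarter; moderate: two
#' distinct moderate diagnoses in one quarter are required), its onset
#' category (bulbar or limb), and its ICD-9-CM code family patterns.
#'
#' Also included are the analysis groups used in the reporting tables:
#' symptom/diagnosis groups (bulbar, limb, nerve, respiratory, other) with
#' ICD-9-CM code lists, and diagnostic-test groups keyed by opaque
#' procedure-group identifiers. The diagnosis-code lists for reporting groups
#' encode the standard ICD-9-CM codes for each printed symptom name.
#'
#' @return A [code_catalog()].
#' @examples
#' cat <- default_catalog()
#' classify_code(cat, "729.5") # Pain in limb, moderate, limb
#' @export
default_catalog <- function() {
  symptoms <- list(
    # -- bulbar, high likelihood ------------------------------------------
    symptom_definition("Developmental speech, language disorder", "high",
                       "bulbar", "Speech", "315.39"),
    symptom_definition("Speech and language deficits", "high", "bulbar",
                       "Speech", c("438.1X", "784.3", "784.4X", "784.5X")),
    symptom_definition("Dysphagia", "high", "bulbar", "Speech",
                       c("787.2", "438.82")),
    symptom_definition("Disturbance, salivary secretion", "high", "bulbar",
                       "Swallowing", "527.7"),
    symptom_definition("Salivary gland disorder", "high", "bulbar",
                       "Swallowing", "527.8"),
    symptom_definition("Pain, throat", "high", "bulbar", "Swallowing", "784.1"),
    # -- limb, high likelihood --------------------------------------------
    symptom_definition("Atrophy, muscular disuse", "high", "limb",
                       "Muscle strength", "728.2"),
    symptom_definition("Muscle weakness (generalized)", "high", "limb",
                       "Muscle strength", "728.87"),
    symptom_definition("Difficulty walking", "high", "limb", "Gait", "719.7"),
    symptom_definition("Gait abnormality", "high", "limb", "Gait", "781.2"),
    symptom_definition("Lack of coordination", "high", "limb", "Gait", "781.3"),
    symptom_definition("Cramping", "high", "limb",
                       "Involuntary muscle movement", "729.82"),
    symptom_definition("Spasm", "high", "limb",
                       "Involuntary muscle movement", "728.85"),
    symptom_definition("Twitching/fasciculation", "high", "limb",
                       "Involuntary muscle movement", "781.0"),
    symptom_definition("Myopathy (including myopathy with weakness)", "high",
                       "limb", "Myopathy", "359.X"),
    # -- limb, moderate likelihood ----------------------------------------
    symptom_definition("Pain in joint", "moderate", "limb", "Pain", "719.4"),
    symptom_definition("Pain in limb", "moderate", "limb", "Pain", "729.5"),
    symptom_definition("Disorder of muscle and/or ligament", "moderate",
                       "limb", "Other", "728.X")
  )

  sg <- function(label, symptom_group, patterns) {
    code_group(label, "symptom_or_diagnosis", symptom_group, patterns)
  }
  tg <- function(label, ids) code_group(label, "diagnostic_test", patterns = ids)

  groups <- list(
    # symptom/diagnosis groups reported at >10% pre-diagnosis frequency
    sg("Speech disturbance", "bulbar", "784.5X"),
    sg("Voice resonance disorder", "bulbar", "784.4X"),
    sg("Muscle weakness (generalized)", "limb", "728.87"),
    sg("Lack of coordination", "limb", "781.3"),
    sg("Dysphagia", "bulbar", c("787.2", "438.82")),
    sg("Hereditary and idiopathic peripheral neuropathies", "nerve", "356.X"),
    sg("Cervicalgia", "nerve", "723.1"),
    sg("Gait abnormality/difficulty walking", "limb", c("781.2", "719.7")),
    sg("Gait abnormality", "limb", "781.2"),
    sg("Difficulty in walking", "limb", "719.7"),
    sg("Transient cerebral ischemia", "other", "435.X"),
    sg("Loss of weight", "other", "783.21"),
    sg("Stroke", "other", c("434.X", "436")),
    sg("Lumbago/backache", "other", c("724.2", "724.5")),
    sg("Malaise and fatigue", "other", "780.7X"),
    sg("Syncope and collapse", "other", "780.2"),
    sg("Pain in limb", "limb", "729.5"),
    sg("Esophageal reflux", "other", "530.81"),
    sg("Constipation", "other", "564.0X"),
    sg("Pulmonary collapse/failure", "respiratory", c("518.0", "518.8X")),
    sg("Dizziness and giddiness", "other", "780.4"),
    sg("Swelling in limb", "other", "729.81"),
    sg("Respiratory difficulties", "respiratory", "786.0X"),
    sg("Hypothyroidism", "other", "244.X"),
    sg("Nausea, vomiting, etc.", "other", "787.0X"),
    sg("Pain in joint", "limb", "719.4"),
    sg("Bronchitis", "respiratory", c("466.0", "490", "491.X")),
    sg("Chronic airway obstruction", "respiratory", "496"),
    sg("Acute upper respiratory infection", "respiratory", "465.X"),
    # rarer diagnoses with large rate ratios
    sg("Chronic inflammatory demyelinating polyneuropathy", "nerve", "357.81"),
    sg("Myopathy (including myopathy with weakness)", "nerve", "359.X"),
    sg("Unspecified disease of spinal cord", "nerve", "336.9"),
    sg("Cervical/thoracic or lumbar spondylosis with myelopathy", "nerve",
       c("721.1", "721.41", "721.42")),
    sg("Atrophy, muscular disuse", "limb", "728.2"),
    # diagnostic-test groups (opaque procedure-group identifiers)
    tg("Sensory nerve conduction test", "NCT_SENSORY"),
    tg("Motor nerve conduction test with F-wave", "NCT_MOTOR_F"),
    tg("Motor nerve conduction test without F-wave", "NCT_MOTOR_NOF"),
    tg("MRI of neck and spine without dye", "MRI_NECK_SPINE"),
    tg("CT scans (head or brain) with/without contrast material", "CT_HEAD_BRAIN"),
    tg("MRI of brain with/without dye", "MRI_BRAIN"),
    tg("Limb electromyography (2 extremities and related paraspinal areas)",
       "EMG_LIMB_2"),
    tg("Limb electromyography (1 extremity and related paraspinal areas)",
       "EMG_LIMB_1"),
    tg("Exam of throat and/or upper gastrointestinal tract", "EXAM_THROAT_UGI")
  )

  code_catalog(symptoms, groups)
}

#' Write a catalog to a structured text (YAML) file
#'
#' The on-disk form is a YAML document with `symptoms` and `groups` lists so
#' users can ship their own rule sets; [read_catalog()] restores an identical
#' catalog.
#'
#' @param catalog A [code_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "code_catalog"))
  sy <- lapply(seq_len(nrow(catalog$symptoms)), function(i) {
    r <- catalog$symptoms[i, ]
    list(label = r$label, likelihood = r$likelihood, category = r$category,
         subgroup = r$subgroup, patterns = as.list(r$patterns[[1]]))
  })
  gr <- lapply(seq_len(nrow(catalog$groups)), function(i) {
    r <- catalog$groups[i, ]
    out <- list(label = r$label, group_kind = r$group_kind,
                patterns = as.list(r$patterns[[1]]))
    if (!is.na(r$symptom_group)) out$symptom_group <- r$symptom_group
    out
  })
  yaml::write_yaml(list(symptoms = sy, groups = gr), path)
  invisible(path)
}

#' Read a catalog from a structured text (YAML) file
#'
#' @param path File written by [write_catalog()] (or hand-authored in the
#'   same form).
#' @return A validated [code_catalog()].
#' @export
read_catalog <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$symptoms) || is.null(doc$groups)) {
    stop("catalog file must contain 'symptoms' and 'groups' lists: ", path,
         call. = FALSE)
  }
  symptoms <- lapply(doc$symptoms, function(s) {
    symptom_definition(s$label, s$likelihood, s$category, s$subgroup,
                       unlist(s$patterns))
  })
  groups <- lapply(doc$groups, function(g) {
    code_group(g$label, g$group_kind, g$symptom_group, unlist(g$patterns))
  })
  code_catalog(symptoms, groups)
}
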