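#' ICD-9-CM code normalization
#'
#' Claims extracts commonly omit the decimal point in diagnosis codes.
#' Normalization upper-cases, trims, and inserts the dot after the third
#' character for numeric and V codes ("7872" -> "787.2", "V431" -> "V43.1")
#' and after the fourth for E codes ("E8261" -> "E826.1"); codes that already
#' carry a dot, or are too short to need one, pass through unchanged.
#'
#' @param code Character vector of ICD-9-CM code strings.
#' @return Normalized dotted code strings.
#' @export
normalize_icd9 <- function(code) {
  x <- toupper(trimws(as.character(code)))
  undotted <- !grepl(".", x, fixed = TRUE)
  num <- undotted & grepl("^[0-9]{4,}X?$", x)
  x[num] <- sub("^([0-9]{3})", "\\1.", x[num])
  vcode <- undotted & grepl("^V[0-9]{3,}X?$", x)
  x[vcode] <- sub("^(V[0-9]{2})", "\\1.", x[vcode])
  ecode <- undotted & grepl("^E[0-9]{4,}X?$", x)
  x[ecode] <- sub("^(E[0-9]{3})", "\\1.", x[ecode])
  x
}

#' Parse and validate an ICD-9-CM code pattern
#'
#' A pattern is either an exact dotted code ("728.87") or a family pattern
#' ending in a single "X" wildcard ("438.1X", "359.X"). The wildcard stands
#' for any completion of the prefix, covering fourth- and fifth-digit
#' expansions of a code family. "X" may appear only once and only as the
#' final character.
#'
#' @param text Pattern string; undotted input is normalized first.
#' @return A normalized pattern string (class `icd9_pattern`).
#' @examples
#' parse_code_pattern("438.1X")
#' parse_code_pattern("7872") # "787.2"
#' @export
parse_code_pattern <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("code pattern must be a single non-empty string", call. = FALSE)
  }
  x <- normalize_icd9(text)
  # bare 3-digit families ("359X") normalize to dotted families ("359.X")
  x <- sub("^([0-9]{3}|V[0-9]{2}|E[0-9]{3})X$", "\\1.X", x)
  n_x <- lengths(regmatches(x, gregexpr("X", x, fixed = TRUE)))
  if (n_x > 1L || (n_x == 1L && substring(x, nchar(x)) != "X")) {
    stop("malformed code pattern (wildcard X must be single and final): \"",
         text, "\"", call. = FALSE)
  }
  if (!grepl("^[EV0-9][0-9.]*X?$", x) || x %in% c("X", ".X")) {
    stop("malformed code pattern: \"", text, "\"", call. = FALSE)
  }
  structure(x, class = "icd9_pattern")
}

#' Match ICD-9-CM codes against a pattern
#'
#' Exact patterns match only the identical normalized code string; a wildcard
#' pattern matches any code that begins with the pattern's prefix (the text
#' before "X"), so "359.X" matches "359.1" and "359.12" but not "358.1".
#'
#' @param pattern A single pattern (string or [parse_code_pattern()] result).
#' @param code Character vector of codes, normalized with [normalize_icd9()].
#' @return Logical vector, one element per code.
#' @export
pattern_matches <- function(pattern, code) {
  p <- unclass(parse_code_pattern(pattern))
  code <- normalize_icd9(code)
  if (endsWith(p, "X")) {
    startsWith(code, substr(p, 1L, nchar(p) - 1L))
  } else {
    code == p
  }
}

match_any_pattern <- function(patterns, code) {
  out <- rep(FALSE, length(code))
  for (p in patterns) out <- out | pattern_matches(p, code)
  out
}

#' Do two code patterns share any concrete code?
#'
#' Used to decide whether an analysis code group can fire the onset rule:
#' exact vs exact requires equality, wildcard prefixes overlap when one is a
#' prefix of the other (interpreting an exact pattern as its full string).
#' @noRd
patterns_overlap <- function(a, b) {
  a <- unclass(parse_code_pattern(a)); b <- unclass(parse_code_pattern(b))
  wa <- endsWith(a, "X"); wb <- endsWith(b, "X")
  pa <- if (wa) substr(a, 1L, nchar(a) - 1L) else a
  pb <- if (wb) substr(b, 1L, nchar(b) - 1L) else b
  if (!wa && !wb) return(a == b)
  if (wa && !wb) return(startsWith(b, pa))
  if (!wa && wb) return(startsWith(a, pb))
  startsWith(pa, pb) || startsWith(pb, pa)
}

symptom_likelihoods <- c("high", "moderate")
symptom_categories <- c("bulbar", "limb")
symptom_groups <- c("bulbar", "limb", "nerve", "respiratory", "other")
group_kinds <- c("symptom_or_diagnosis", "diagnostic_test")

#' Construct a symptom definition (one diagnosis-of-interest row)
#'
#' @param label Human-readable diagnosis-of-interest name, unique in a catalog.
#' @param likelihood `"high"` or `"moderate"` likelihood that the code marks a
#'   first ALS symptom.
#' @param category `"bulbar"` or `"limb"` onset category.
#' @param subgroup Free-text subgrouping (e.g. "Speech", "Gait").
#' @param patterns Character vector of ICD-9-CM patterns (non-empty).
#' @return A one-row tibble usable in [code_catalog()].
#' @export
symptom_definition <- function(label, likelihood, category, subgroup, patterns) {
  likelihood <- match.arg(likelihood, symptom_likelihoods)
  category <- match.arg(category, symptom_categories)
  if (length(patterns) < 1L) {
    stop("symptom definition \"", label, "\" needs at least one pattern",
         call. = FALSE)
  }
  patterns <- vapply(patterns, function(p) unclass(parse_code_pattern(p)), "")
  tibble::tibble(
    label = as.character(label), likelihood = likelihood, category = category,
    subgroup = as.character(subgroup), patterns = list(unname(patterns))
  )
}

#' Construct an analysis code group (a reporting-table row)
#'
#' Symptom/diagnosis groups carry ICD-9-CM diagnosis patterns and a symptom
#' group (bulbar, limb, nerve, respiratory, other); diagnostic-test groups are
#' keyed by opaque procedure-group identifiers carried on procedure claims,
#' since real procedure coding systems are licensed and group membership is
#' all the analysis needs.
#'
#' @param label Group name, unique in a catalog.
#' @param group_kind `"symptom_or_diagnosis"` or `"diagnostic_test"`.
#' @param symptom_group Required iff `group_kind = "symptom_or_diagnosis"`.
#' @param patterns ICD-9-CM patterns (symptom groups) or procedure-group
#'   identifiers (test groups).
#' @return A one-row tibble usable in [code_catalog()].
#' @export
code_group <- function(label, group_kind, symptom_group = NULL, patterns) {
  group_kind <- match.arg(group_kind, group_kinds)
  if (group_kind == "symptom_or_diagnosis") {
    if (is.null(symptom_group)) {
      stop("symptom_group is required for symptom_or_diagnosis groups",
           call. = FALSE)
    }
    symptom_group <- match.arg(symptom_group, symptom_groups)
    patterns <- vapply(patterns, function(p) unclass(parse_code_pattern(p)), "")
  } else {
    if (!is.null(symptom_group)) {
      stop("symptom_group must be absent for diagnostic_test groups",
           call. = FALSE)
    }
    symptom_group <- NA_character_
    patterns <- as.character(patterns)
  }
  if (length(patterns) < 1L) {
    stop("code group \"", label, "\" needs at least one pattern", call. = FALSE)
  }
  tibble::tibble(
    label = as.character(label), group_kind = group_kind,
    symptom_group = symptom_group, patterns = list(unname(patterns))
  )
}

#' Assemble and validate a code catalog
#'
#' A catalog holds the onset rule book (symptom definitions, each high or
#' moderate likelihood and bulbar or limb) and the analysis groups used for
#' prevalence, lag, and test-utilization tables.
#'
#' @param symptoms Tibble of [symptom_definition()] rows.
#' @param groups Tibble of [code_group()] rows.
#' @return An object of class `code_catalog`.
#' @seealso [default_catalog()], [classify_code()], [read_catalog()]
#' @export
code_catalog <- function(symptoms, groups) {
  symptoms <- dplyr::bind_rows(symptoms)
  groups <- dplyr::bind_rows(groups)
  if (anyDuplicated(symptoms$label)) {
    stop("duplicate symptom definition labels: ",
         paste(unique(symptoms$label[duplicated(symptoms$label)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(groups$label)) {
    stop("duplicate analysis group labels: ",
         paste(unique(groups$label[duplicated(groups$label)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(symptoms = symptoms, groups = groups), class = "code_catalog")
}

#' @export
print.code_catalog <- function(x, ...) {
  cat("<code_catalog> ", nrow(x$symptoms), " symptom definitions (",
      sum(x$symptoms$likelihood == "high"), " high, ",
      sum(x$symptoms$likelihood == "moderate"), " moderate), ",
      nrow(x$groups), " analysis groups\n", sep = "")
  invisible(x)
}

#' Classify an ICD-9-CM code against a catalog's symptom definitions
#'
#' Returns every symptom definition with at least one matching pattern, in
#' catalog order; a code can legitimately match several definitions (e.g. a
#' specific high-likelihood code inside a broader moderate family).
#'
#' @param catalog A [code_catalog()].
#' @param code A single ICD-9-CM code string.
#' @return Tibble of matching symptom-definition rows (zero rows if none).
#' @examples
#' classify_code(default_catalog(), "787.2") # Dysphagia, high, bulbar
#' @export
classify_code <- function(catalog, code) {
  stopifnot(inherits(catalog, "code_catalog"), length(code) == 1L)
  code <- normalize_icd9(code)
  hit <- vapply(catalog$symptoms$patterns,
                function(ps) any(match_any_pattern(ps, code)), TRUE)
  catalog$symptoms[hit, ]
}

#' Classify many codes at once
#'
#' Long-format version of [classify_code()]: one output row per
#' (code, matching definition) pair, for vectorized onset detection.
#' @noRd
classify_codes <- function(catalog, codes) {
  codes <- unique(normalize_icd9(codes))
  defs <- catalog$symptoms
  out <- lapply(seq_len(nrow(defs)), function(i) {
    m <- match_any_pattern(defs$patterns[[i]], codes)
    if (!any(m)) return(NULL)
    tibble::tibble(code = codes[m], label = defs$label[i],
                   likelihood = defs$likelihood[i], category = defs$category[i])
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(code = character(), label = character(),
                          likelihood = character(), category = character())
  }
  out
}

#' Look up an analysis group by label
#' @param catalog A [code_catalog()].
#' @param label Group label as printed in the reporting tables.
#' @return One-row tibble for the group.
#' @export
catalog_group <- function(catalog, label) {
  g <- catalog$groups[catalog$groups$label == label, ]
  if (nrow(g) != 1L) stop("unknown analysis group: \"", label, "\"", call. = FALSE)
  g
}

#' Can an analysis group's codes fire the symptom-onset rule?
#'
#' TRUE when any of the group's diagnosis patterns shares a concrete code with
#' any symptom-definition pattern in the catalog. Diagnostic-test groups never
#' overlap (procedure claims are not classified).
#'
#' @param catalog A [code_catalog()].
#' @param label Analysis-group label.
#' @return Logical scalar.
#' @export
group_overlaps_onset <- function(catalog, label) {
  g <- catalog_group(catalog, label)
  if (g$group_kind == "diagnostic_test") return(FALSE)
  any(vapply(g$patterns[[1]], function(gp) {
    any(vapply(catalog$symptoms$patterns, function(ps) {
      any(vapply(ps, patterns_overlap, TRUE, b = gp))
    }, TRUE))
  }, TRUE))
}
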