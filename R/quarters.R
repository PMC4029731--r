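#' Calendar-quarter arithmetic
#'
#' Claims in the source data carry only a calendar quarter of service, never a
#' date, so the whole package counts time in integer quarters relative to an
#' epoch (quarter 0). The default epoch is Q1 2005, the start of the study
#' data; analyses of synthetic data may use an earlier epoch to carry longer
#' pre-diagnosis histories.
#'
#' @param year Calendar year (integer).
#' @param q Quarter within the year, 1 to 4.
#' @param epoch_year Calendar year whose Q1 is quarter index 0.
#' @return Integer quarter index (`quarter_of`), or its inverse.
#' @examples
#' quarter_of(2005, 1) # 0
#' quarter_of(2009, 4) # 19
#' quarter_year(19)    # year 2009, quarter 4
#' @export
quarter_of <- function(year, q, epoch_year = 2005) {
  if (any(is.na(year)) || any(is.na(q))) {
    stop("year and quarter must not be missing", call. = FALSE)
  }
  if (any(q < 1L | q > 4L | q != as.integer(q))) {
    stop("quarter must be an integer in 1..4, got: ",
         paste(unique(q[q < 1 | q > 4]), collapse = ", "), call. = FALSE)
  }
  as.integer(4L * (as.integer(year) - as.integer(epoch_year)) + as.integer(q) - 1L)
}

#' @rdname quarter_of
#' @param index Integer quarter index.
#' @export
quarter_year <- function(index, epoch_year = 2005) {
  index <- as.integer(index)
  tibble::tibble(
    year = epoch_year + index %/% 4L,
    quarter = index %% 4L + 1L
  )
}

#' @rdname quarter_of
#' @export
quarter_label <- function(index, epoch_year = 2005) {
  yq <- quarter_year(index, epoch_year)
  sprintf("%dQ%d", yq$year, yq$quarter)
}

#' Parse a quarter label such as "2007Q1"
#'
#' @param label Character vector of labels in `<year>Q<quarter>` form.
#' @inheritParams quarter_of
#' @return Integer quarter indices under the given epoch.
#' @export
parse_quarter_label <- function(label, epoch_year = 2005) {
  m <- regmatches(label, regexec("^\\s*([0-9]{4})[Qq]([1-4])\\s*$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed quarter label: ", paste(label[bad], collapse = ", "),
         " (expected e.g. \"2007Q1\")", call. = FALSE)
  }
  vapply(m, function(x) quarter_of(as.integer(x[2]), as.integer(x[3]), epoch_year), 1L)
}

#' Convert a window of quarter labels to an inclusive index range
#' @noRd
window_indices <- function(window, epoch_year) {
  idx <- parse_quarter_label(window, epoch_year)
  if (length(idx) != 2L || idx[1] > idx[2]) {
    stop("window must be two quarter labels in increasing order", call. = FALSE)
  }
  idx
}

#' Round half away from zero
#'
#' Display rounding used throughout (prevalence ratios to one decimal, medians
#' to two): 1.75 rounds to 1.8, unlike base `round()`'s round-half-even.
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
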