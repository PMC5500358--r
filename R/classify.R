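#' Classify conscription general-ability (IQ) scores
#'
#' Scores from the written enrolment test are on the standard-nine
#' ("STANINE") scale 1-9; men without a test carry the letter grades A
#' (assumed above average), B (assumed average) or C (assumed below
#' average). Scores 1-2 and grade C are classified as low IQ (85 or below),
#' 3-7 and grade B as average (85-115), and 8-9 and grade A as high (above
#' 115).
#'
#' @param iq_raw vector of raw scores: integers 1-9, letters "A"/"B"/"C",
#'   or `NA` for missing. Numeric and character input are both accepted.
#' @return A factor with levels `low`, `average`, `high`; `NA` where the
#'   raw score is missing.
#' @examples
#' classify_iq(c(2, 5, 9, NA))
#' classify_iq(c("A", "B", "C"))
#' @export
classify_iq <- function(iq_raw) {
  x <- toupper(trimws(as.character(iq_raw)))
  x[!is.na(x) & x == ""] <- NA
  ok <- is.na(x) | x %in% c(as.character(1:9), "A", "B", "C")
  if (!all(ok)) {
    stop(
      "malformed IQ score(s): ",
      paste(unique(x[!ok]), collapse = ", ")
    )
  }
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "2", "C")] <- "low"
  out[x %in% c("3", "4", "5", "6", "7", "B")] <- "average"
  out[x %in% c("8", "9", "A")] <- "high"
  factor(out, levels = c("low", "average", "high"))
}

#' Convert STANINE scores to IQ-equivalent points
#'
#' The STANINE scale has mean 5 and standard deviation 2; the IQ-equivalent
#' scale has mean 100 and standard deviation 15. The unique linear map
#' matching both moments is `100 + (s - 5) * 15 / 2`, so the low/average
#' boundary (score 2.5 between scores 2 and 3) falls at roughly IQ 85 and
#' the average/high boundary near 115.
#'
#' @param s integer STANINE scores in 1-9.
#' @return Numeric IQ-equivalent points.
#' @examples
#' stanine_to_iq(c(3, 5, 7)) # 85 100 115
#' @export
stanine_to_iq <- function(s) {
  if (any(is.na(s)) || !is.numeric(s) ||
    any(s != round(s)) || any(s < 1 | s > 9)) {
    stop("STANINE scores must be integers in 1..9")
  }
  100 + (s - 5) * 15 / 2
}

#' Classify enrolment mental-health scores
#'
#' The examining physician scores mental health 1-7 or 9: a score of 9
#' means no mental health problem was discovered, scores 1-7 grade the
#' severity of a discovered problem, and the score 8 is not applied on this
#' scale (its presence signals malformed input).
#'
#' @param mental_raw vector of scores in `{1..7, 9}` or `NA` for missing.
#' @return A factor with levels `none`, `problems`; `NA` where missing.
#' @examples
#' classify_mental(c(9, 6, NA))
#' @export
classify_mental <- function(mental_raw) {
  x <- suppressWarnings(as.numeric(as.character(mental_raw)))
  chr <- trimws(as.character(mental_raw))
  x[!is.na(chr) & chr == ""] <- NA
  is_missing <- is.na(mental_raw) | (!is.na(chr) & chr == "")
  if (any(!is_missing & is.na(x))) {
    stop("malformed mental-health score(s)")
  }
  if (any(!is.na(x) & x == 8)) {
    stop("mental-health score 8 is not applied on this scale")
  }
  if (any(!is.na(x) & !(x %in% c(1:7, 9)))) {
    stop("mental-health scores must be in {1..7, 9}")
  }
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x == 9] <- "none"
  out[!is.na(x) & x <= 7] <- "problems"
  factor(out, levels = c("none", "problems"))
}

#' Six-group IQ-by-mental-health classification
#'
#' Crosses [classify_iq()] and [classify_mental()] into the six covariate
#' groups used throughout: the reference group is average IQ with no mental
#' health problems.
#'
#' @param iq_raw,mental_raw raw scores as in the classifiers above.
#' @return A factor with six levels, reference level `"average.none"`;
#'   `NA` where either score is missing.
#' @export
classify_group <- function(iq_raw, mental_raw) {
  iq <- classify_iq(iq_raw)
  mh <- classify_mental(mental_raw)
  lev <- group_levels()
  out <- ifelse(is.na(iq) | is.na(mh), NA_character_,
    paste(as.character(iq), as.character(mh), sep = ".")
  )
  factor(out, levels = lev)
}

group_levels <- function() {
  c(
    "average.none", "low.none", "high.none",
    "average.problems", "low.problems", "high.problems"
  )
}
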