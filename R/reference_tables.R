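#' Published transition tabulation for the national conscript cohort
#'
#' Transition counts between the eight life-course states for the 918 888
#' Norwegian men born 1950-1980 whose benefit episodes were observed in the
#' 1992-2008 registry window, as published in tabulated form. Rows are the
#' seven transient from-states; columns are the eight to-states plus a
#' final "censored" column counting men alive and at risk in that state at
#' the end of follow-up. Same-state cells (e.g. sick leave to sick leave)
#' count recorded back-to-back re-episodes of the same benefit.
#'
#' The tabulation is distributed with the package as a validation input:
#' summing its cells reproduces the published totals (3 921 004 transitions
#' overall, of which 12 607 into death) and exercises the same counting
#' conventions as [count_transitions()].
#'
#' @return An integer matrix, 7 rows by 9 columns, with dimnames.
#' @examples
#' sum(conscript_transition_counts()[, 1:8])
#' @export
conscript_transition_counts <- function() {
  labels <- state_space()$labels
  m <- rbind(
    c(0, 1657895, 45865, 48607, 3736, 20314, 28421, 10860, 729891),
    c(1595592, 133909, 53398, 48325, 559, 3309, 454, 726, 105714),
    c(101605, 983, 2009, 962, 3816, 9351, 175, 85, 288),
    c(82070, 130, 0, 14381, 1320, 5164, 93, 81, 10566),
    c(1153, 68, 148, 84, 0, 7930, 7, 23, 191),
    c(7729, 307, 75, 26, 37, 0, 1404, 819, 45265),
    c(26487, 317, 32, 51, 0, 46, 53, 13, 5)
  )
  storage.mode(m) <- "integer"
  dimnames(m) <- list(from = labels[1:7], to = c(labels, "censored"))
  m
}

#' Published enrolment health-score distribution
#'
#' Counts of men per score value for the seven health variables assessed at
#' military enrolment (N = 918 888). Scores 1 and 2 are published merged;
#' score 8 is not used on these scales; 9 means no impairment.
#'
#' @return An integer matrix, one row per variable, columns
#'   `1&2, 3, 4, 5, 6, 7, 9, missing`.
#' @export
enrolment_score_counts <- function() {
  m <- rbind(
    mental_health = c(6660, 6998, 2755, 2804, 5102, 9561, 576414, 308594),
    physical_health = c(10104, 10300, 7630, 11060, 20638, 33839, 516700, 308617),
    arm = c(1009, 6450, 1069, 1732, 2888, 4587, 591358, 309795),
    hand = c(1082, 6397, 1136, 1712, 3065, 4860, 590846, 309790),
    walking = c(2335, 7279, 2702, 5447, 12383, 27247, 551814, 309681),
    back = c(2127, 6940, 2486, 4583, 13574, 26440, 553037, 309701),
    skin = c(1273, 6427, 2095, 3130, 6332, 12671, 577164, 309796)
  )
  storage.mode(m) <- "integer"
  colnames(m) <- c("1&2", "3", "4", "5", "6", "7", "9", "missing")
  m
}

#' Published general-ability score distribution
#'
#' Counts of men per raw general-ability score: STANINE 1-9 where a written
#' test was taken (838 158 men) and letter grades A/B/C where it was not
#' (25 211 men). Feeding the `score` column through [classify_iq()] and
#' summing `n` reproduces the published combined low/average/high group
#' sizes.
#'
#' @return A data frame with columns `score` (character) and `n` (integer).
#' @examples
#' tab <- iq_score_counts()
#' tapply(tab$n, classify_iq(tab$score), sum)
#' @export
iq_score_counts <- function() {
  data.frame(
    score = c(as.character(1:9), "C", "B", "A"),
    n = c(
      15709L, 37614L, 75441L, 134404L, 172954L, 163404L, 125059L,
      75018L, 38555L, 3769L, 20318L, 1124L
    ),
    stringsAsFactors = FALSE
  )
}
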