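#' State space of the benefit-registry multi-state model
#'
#' The full model has eight states: employment (1), sick leave (2),
#' vocational rehabilitation (3), medical rehabilitation (4), time limited
#' disability benefits (5), disability benefits (6), emigrated (7) and dead
#' (8). Death is the single absorbing state. For mean-time and regression
#' analyses the three rehabilitation/time-limited states (3, 4, 5) are merged
#' into a single "time limited benefits" state, giving a six-state space.
#'
#' @param merged logical; return the merged six-state space instead of the
#'   full eight-state space.
#' @return An object of class `state_space`: a list with integer `codes`,
#'   character `labels`, the `absorbing` code, and `merge_map`, an integer
#'   vector mapping the eight full-model codes onto the merged codes.
#' @examples
#' state_space()
#' state_space(merged = TRUE)$labels
#' @export
state_space <- function(merged = FALSE) {
  full_labels <- c(
    "employment", "sick leave", "vocational rehabilitation",
    "medical rehabilitation", "time limited disability benefits",
    "disability benefits", "emigrated", "dead"
  )
  merged_labels <- c(
    "employment", "sick leave", "time limited benefits",
    "disability benefits", "emigrated", "dead"
  )
  merge_map <- c(1L, 2L, 3L, 3L, 3L, 4L, 5L, 6L)
  if (merged) {
    sp <- list(
      codes = seq_along(merged_labels), labels = merged_labels,
      absorbing = 6L, merge_map = NULL, merged = TRUE
    )
  } else {
    sp <- list(
      codes = 1:8, labels = full_labels,
      absorbing = 8L, merge_map = merge_map, merged = FALSE
    )
  }
  class(sp) <- "state_space"
  sp
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf(
    "<state_space> %d states (%s), absorbing = %d (%s)\n",
    length(x$codes), if (x$merged) "merged" else "full",
    x$absorbing, x$labels[x$absorbing]
  ))
  invisible(x)
}

n_states <- function(space) length(space$codes)

transient_states <- function(space) setdiff(space$codes, space$absorbing)

#' Validate an episode table
#'
#' An episode table has one row per benefit/registry spell with columns
#' `person_id`, `state`, `start_age` and `end_age` (decimal years). Episodes
#' of one person must not overlap, must have positive length, and an episode
#' in the absorbing state can have no successor.
#'
#' @param episodes data frame of episodes.
#' @param space a [state_space()].
#' @return The episodes, sorted by person and start age, invisibly usable.
#' @export
validate_episodes <- function(episodes, space = state_space()) {
  req <- c("person_id", "state", "start_age", "end_age")
  miss <- setdiff(req, names(episodes))
  if (length(miss)) {
    stop("episode table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (!all(episodes$state %in% space$codes)) {
    stop("episode state codes outside the state space")
  }
  if (any(episodes$start_age >= episodes$end_age)) {
    stop("episodes must have start_age < end_age")
  }
  o <- order(episodes$person_id, episodes$start_age)
  episodes <- episodes[o, , drop = FALSE]
  same <- episodes$person_id[-1] == episodes$person_id[-nrow(episodes)]
  if (nrow(episodes) > 1) {
    overlap <- same &
      episodes$start_age[-1] < episodes$end_age[-nrow(episodes)] - 1e-12
    if (any(overlap)) {
      bad <- unique(episodes$person_id[-1][overlap])
      stop(
        "overlapping episodes for person(s): ",
        paste(utils::head(bad, 5), collapse = ", ")
      )
    }
    after_abs <- same &
      episodes$state[-nrow(episodes)] == space$absorbing
    if (any(after_abs)) {
      stop("episodes recorded after the absorbing state")
    }
  }
  rownames(episodes) <- NULL
  episodes
}

#' Merge a processed cohort onto the six-state space
#'
#' Relabels events and at-risk intervals of a processed cohort (see
#' [episodes_to_process()]) through the merge map of the full state space.
#' Transitions between the three time-limited states become same-state
#' events: they are kept in the event stream for bookkeeping but the
#' surrounding at-risk intervals are fused, so they contribute no intensity.
#' Total transition count is conserved.
#'
#' @param processed an object of class `msm_process`.
#' @return A new `msm_process` on the merged six-state space.
#' @export
merge_states <- function(processed) {
  stopifnot(inherits(processed, "msm_process"))
  if (isTRUE(processed$space$merged)) {
    stop("cohort is already on the merged state space")
  }
  map <- processed$space$merge_map
  ev <- processed$events
  ev$from <- map[ev$from]
  ev$to <- map[ev$to]
  out <- rebuild_from_events(
    events = ev,
    first_state = map[processed$first_state],
    windows = processed$windows,
    space = state_space(merged = TRUE)
  )
  out
}
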