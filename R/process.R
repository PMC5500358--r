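#' Observation windows on the age axis
#'
#' Registry data are observed in a fixed calendar window (default
#' 1992-2008), so a man born in year `b` is observed between ages
#' `max(age_min, cal_start - b)` and `min(age_max, cal_end - b)`: cohorts
#' born before 1972 enter late (delayed entry), cohorts born after 1972 are
#' censored young, and each man contributes a different age span with at
#' most `cal_end - cal_start` years of follow-up.
#'
#' @param covariates data frame with columns `person_id` and `birth_year`.
#' @param calendar_window integer calendar years `c(start, end)`.
#' @param age_range ages `c(min, max)` delimiting the analysis.
#' @return A data frame `person_id`, `entry_age`, `exit_age`; persons with
#'   an empty window are dropped.
#' @export
observation_windows <- function(covariates,
                                calendar_window = c(1992, 2008),
                                age_range = c(20, 58)) {
  entry <- pmax(age_range[1], calendar_window[1] - covariates$birth_year)
  exit <- pmin(age_range[2], calendar_window[2] - covariates$birth_year)
  keep <- exit > entry
  data.frame(
    person_id = covariates$person_id[keep],
    entry_age = entry[keep], exit_age = exit[keep]
  )
}

#' Convert benefit episodes to a counting process
#'
#' Turns per-person benefit spells into transition events and at-risk
#' intervals on the age axis. Time gaps where no benefit is registered are
#' filled with employment spells, so every person's at-risk intervals tile
#' the observation window exactly. Intervals are half-open `[start, end)`:
#' a transition at time t closes one interval and opens the next at t.
#' Back-to-back episodes of the same state are recorded as same-state
#' events in the event stream (registry re-episodes) but leave the at-risk
#' interval unbroken, since a j-to-j intensity is undefined. A spell in the
#' absorbing state contributes a transition into it at its start and ends
#' observation; persons entering the window mid-spell enter the risk set in
#' that spell's state (delayed entry).
#'
#' @param episodes episode table (see [validate_episodes()]); states are
#'   benefit states, employment spells may be included explicitly or left
#'   as gaps.
#' @param windows per-person observation windows from
#'   [observation_windows()], or a data frame with columns `person_id`,
#'   `entry_age`, `exit_age`.
#' @param space a [state_space()].
#' @param employment_state state code used to fill unregistered gaps.
#' @return An object of class `msm_process`: list with `events`
#'   (`person_id`, `time`, `from`, `to`), `intervals` (`person_id`,
#'   `state`, `entry`, `exit`, `exit_reason`), `windows`, `first_state`,
#'   `space`, `n_persons`.
#' @export
episodes_to_process <- function(episodes, windows, space = state_space(),
                                employment_state = 1L) {
  episodes <- validate_episodes(episodes, space)
  tol <- 1e-9
  win_ids <- windows$person_id
  ep_split <- split(
    episodes[c("state", "start_age", "end_age")],
    factor(episodes$person_id, levels = win_ids)
  )

  first_state <- integer(length(win_ids))
  ev_pid <- vector("list", length(win_ids))
  ev_time <- vector("list", length(win_ids))
  ev_from <- vector("list", length(win_ids))
  ev_to <- vector("list", length(win_ids))

  for (i in seq_along(win_ids)) {
    entry <- windows$entry_age[i]
    exit <- windows$exit_age[i]
    ep <- ep_split[[i]]
    # clip to the observation window
    if (nrow(ep)) {
      keep <- ep$end_age > entry + tol & ep$start_age < exit - tol
      # absorbing spell starting at/after exit is unobserved; one starting
      # before entry means the person was never at risk in the window
      abs_before <- ep$state == space$absorbing & ep$start_age <= entry + tol
      if (any(abs_before)) {
        first_state[i] <- NA_integer_
        next
      }
      ep <- ep[keep, , drop = FALSE]
      ep$start_age <- pmax(ep$start_age, entry)
      ep$end_age <- pmin(ep$end_age, exit)
    }
    if (!nrow(ep)) {
      first_state[i] <- employment_state
      next
    }
    # spell sequence with employment gap-filling
    st <- integer(0)
    t0 <- numeric(0)
    cursor <- entry
    for (r in seq_len(nrow(ep))) {
      if (ep$start_age[r] > cursor + tol) {
        st <- c(st, employment_state)
        t0 <- c(t0, cursor)
        cursor <- ep$start_age[r]
      }
      st <- c(st, ep$state[r])
      t0 <- c(t0, ep$start_age[r])
      cursor <- ep$end_age[r]
      if (ep$state[r] == space$absorbing) break
    }
    if (st[length(st)] != space$absorbing && cursor < exit - tol) {
      st <- c(st, employment_state)
      t0 <- c(t0, cursor)
    }
    first_state[i] <- st[1]
    if (length(st) > 1) {
      ev_pid[[i]] <- rep(win_ids[i], length(st) - 1)
      ev_time[[i]] <- t0[-1]
      ev_from[[i]] <- st[-length(st)]
      ev_to[[i]] <- st[-1]
    }
  }

  keep_person <- !is.na(first_state)
  events <- data.frame(
    person_id = unlist(ev_pid), time = unlist(ev_time),
    from = unlist(ev_from), to = unlist(ev_to)
  )
  if (!nrow(events)) {
    events <- data.frame(
      person_id = win_ids[0], time = numeric(0),
      from = integer(0), to = integer(0)
    )
  }
  rebuild_from_events(
    events = events[events$person_id %in% win_ids[keep_person], , drop = FALSE],
    first_state = stats::setNames(
      first_state[keep_person], win_ids[keep_person]
    ),
    windows = windows[keep_person, , drop = FALSE],
    space = space
  )
}

# Rebuild at-risk intervals (and a consistent event stream) from a
# first-state vector plus per-person events in time order. `from` columns
# are recomputed from the running state so spliced event streams stay
# coherent. Shared by episodes_to_process, merge_states and
# filter_rare_transitions.
rebuild_from_events <- function(events, first_state, windows, space) {
  ids <- windows$person_id
  ev_split <- split(
    events[c("time", "to")],
    factor(events$person_id, levels = ids)
  )
  iv_pid <- vector("list", length(ids))
  iv_state <- vector("list", length(ids))
  iv_entry <- vector("list", length(ids))
  iv_exit <- vector("list", length(ids))
  iv_reason <- vector("list", length(ids))
  out_from <- vector("list", length(ids))

  for (i in seq_along(ids)) {
    ev <- ev_split[[i]]
    entry <- windows$entry_age[i]
    exit <- windows$exit_age[i]
    cur <- first_state[[i]]
    seg <- entry
    ns <- integer(0)
    ne <- numeric(0)
    nx <- numeric(0)
    nr <- character(0)
    frm <- integer(0)
    absorbed <- FALSE
    if (nrow(ev)) {
      o <- order(ev$time)
      for (r in o) {
        t <- ev$time[r]
        k <- ev$to[r]
        frm <- c(frm, cur)
        if (k == cur) next # same-state re-episode: interval unbroken
        if (t > seg) {
          ns <- c(ns, cur)
          ne <- c(ne, seg)
          nx <- c(nx, t)
          nr <- c(nr, "transition")
        }
        cur <- k
        seg <- t
        if (k == space$absorbing) {
          absorbed <- TRUE
          break
        }
      }
    }
    if (!absorbed && exit > seg) {
      ns <- c(ns, cur)
      ne <- c(ne, seg)
      nx <- c(nx, exit)
      nr <- c(nr, "censored")
    }
    iv_pid[[i]] <- rep(ids[i], length(ns))
    iv_state[[i]] <- ns
    iv_entry[[i]] <- ne
    iv_exit[[i]] <- nx
    iv_reason[[i]] <- nr
    out_from[[i]] <- frm
  }

  ev_out <- events
  if (nrow(ev_out)) {
    o <- order(match(ev_out$person_id, ids), ev_out$time)
    ev_out <- ev_out[o, , drop = FALSE]
    from_vec <- unlist(out_from)
    if (length(from_vec) != nrow(ev_out)) {
      stop("events recorded after absorption; corrupt input")
    }
    ev_out$from <- from_vec
    rownames(ev_out) <- NULL
  }
  intervals <- data.frame(
    person_id = unlist(iv_pid),
    state = unlist(iv_state),
    entry = unlist(iv_entry),
    exit = unlist(iv_exit),
    exit_reason = unlist(iv_reason)
  )
  structure(
    list(
      events = ev_out, intervals = intervals, windows = windows,
      first_state = first_state, space = space,
      n_persons = length(ids)
    ),
    class = "msm_process"
  )
}

#' @export
print.msm_process <- function(x, ...) {
  cat(sprintf(
    "<msm_process> %d persons, %d events, %d at-risk intervals (%d states)\n",
    x$n_persons, nrow(x$events), nrow(x$intervals), length(x$space$codes)
  ))
  invisible(x)
}

#' Tabulate transitions and censorings
#'
#' Cell (j, k) counts recorded j-to-k events, including same-state
#' re-episodes on the diagonal; the final `censored` column counts at-risk
#' intervals closed by the end of observation ("alive and at risk").
#' There are no counts out of the absorbing state.
#'
#' @param processed an `msm_process` object.
#' @return An integer matrix, transient from-states by
#'   (all states + censored), with attribute `n_persons`.
#' @export
count_transitions <- function(processed) {
  stopifnot(inherits(processed, "msm_process"))
  space <- processed$space
  tr <- transient_states(space)
  ev <- processed$events
  m <- table(
    factor(ev$from, levels = tr),
    factor(ev$to, levels = space$codes)
  )
  cens <- processed$intervals[processed$intervals$exit_reason == "censored", ]
  cc <- table(factor(cens$state, levels = tr))
  out <- cbind(unclass(m), censored = as.integer(cc))
  storage.mode(out) <- "integer"
  dimnames(out) <- list(
    from = space$labels[tr],
    to = c(space$labels, "censored")
  )
  attr(out, "n_persons") <- processed$n_persons
  out
}

#' Remove rare transitions from a processed cohort
#'
#' Transition pairs observed fewer than `min_count` times are removed from
#' the event stream. A removed event is spliced out: the person is treated
#' as remaining in the current state and the spell continues as if the
#' transition had not occurred, so a later transition out of the
#' spliced-over state is re-attributed to the current effective state (and
#' dropped if it would only return the person to it).
#'
#' @param processed an `msm_process` object.
#' @param min_count minimum number of events for a pair to be retained
#'   (default 10; pairs with exactly `min_count` events are kept).
#' @return A list: `processed`, the rebuilt cohort, and `removed`, a data
#'   frame of the removed (from, to, count) pairs.
#' @export
filter_rare_transitions <- function(processed, min_count = 10L) {
  stopifnot(inherits(processed, "msm_process"))
  if (min_count < 1) stop("min_count must be at least 1")
  counts <- count_transitions(processed)
  nst <- length(processed$space$codes)
  cmat <- counts[, seq_len(nst), drop = FALSE]
  idx <- which(cmat > 0 & cmat < min_count, arr.ind = TRUE)
  tr <- transient_states(processed$space)
  removed <- data.frame(
    from = tr[idx[, 1]], to = processed$space$codes[idx[, 2]],
    count = cmat[idx]
  )
  removed <- removed[order(removed$from, removed$to), , drop = FALSE]
  rownames(removed) <- NULL
  if (!nrow(removed)) {
    return(list(processed = processed, removed = removed))
  }
  rm_key <- paste(removed$from, removed$to)

  ids <- processed$windows$person_id
  ev <- processed$events
  ev_split <- split(
    ev[c("time", "from", "to")],
    factor(ev$person_id, levels = ids)
  )
  keep_pid <- vector("list", length(ids))
  keep_time <- vector("list", length(ids))
  keep_to <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    e <- ev_split[[i]]
    if (!nrow(e)) next
    o <- order(e$time)
    cur <- processed$first_state[[i]]
    kt <- numeric(0)
    kk <- integer(0)
    for (r in o) {
      k <- e$to[r]
      if (paste(cur, k) %in% rm_key) next
      if (k == cur && e$from[r] != e$to[r]) next # splice artifact
      kt <- c(kt, e$time[r])
      kk <- c(kk, k)
      if (k != cur) cur <- k
    }
    keep_pid[[i]] <- rep(ids[i], length(kt))
    keep_time[[i]] <- kt
    keep_to[[i]] <- kk
  }
  new_ev <- data.frame(
    person_id = unlist(keep_pid), time = unlist(keep_time),
    from = NA_integer_, to = unlist(keep_to)
  )
  out <- rebuild_from_events(
    events = new_ev, first_state = processed$first_state,
    windows = processed$windows, space = processed$space
  )
  list(processed = out, removed = removed)
}
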