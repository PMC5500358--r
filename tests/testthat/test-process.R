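test_that("gap filling yields the hand-enumerated event list on the toy cohort", {
  pr <- toy_process()
  # person 1: employment -> sick at 25, sick -> employment at 26
  e1 <- pr$events[pr$events$person_id == 1, ]
  expect_equal(e1$time, c(25, 26))
  expect_equal(e1$from, c(1L, 2L))
  expect_equal(e1$to, c(2L, 1L))
  i1 <- pr$intervals[pr$intervals$person_id == 1, ]
  expect_equal(nrow(i1), 3)
  expect_equal(i1$state, c(1L, 2L, 1L))
  expect_equal(i1$exit_reason, c("transition", "transition", "censored"))
  # person 2 dies at 30: final event into state 8, nothing afterwards
  e2 <- pr$events[pr$events$person_id == 2, ]
  expect_equal(e2$to[length(e2$to)], 8L)
  expect_equal(e2$time[length(e2$time)], 30)
  i2 <- pr$intervals[pr$intervals$person_id == 2, ]
  expect_equal(max(i2$exit), 30)
  expect_false(any(i2$state == 8))
  # person 3 enters late, mid-spell: first state is the observed spell state
  expect_equal(unname(pr$first_state[["3"]]), 3L)
  i3 <- pr$intervals[pr$intervals$person_id == 3, ]
  expect_equal(i3$entry[1], 25)
})

test_that("at-risk intervals tile each observation window exactly", {
  co <- generate_cohort(default_config(300), seed = 21)
  pr <- episodes_to_process(co$episodes, co$windows)
  iv <- split(pr$intervals, pr$intervals$person_id)
  for (pid in names(iv)) {
    d <- iv[[pid]]
    d <- d[order(d$entry), ]
    w <- pr$windows[pr$windows$person_id == as.integer(pid), ]
    expect_equal(d$entry[1], w$entry_age, tolerance = 1e-9)
    if (nrow(d) > 1) {
      expect_equal(d$entry[-1], d$exit[-nrow(d)], tolerance = 1e-9)
    }
    # last interval ends at the window exit unless the person died
    died <- any(pr$events$person_id == as.integer(pid) &
      pr$events$to == 8L)
    if (!died) expect_equal(d$exit[nrow(d)], w$exit_age, tolerance = 1e-9)
  }
})

test_that("transition counts match events plus censorings row-wise", {
  co <- generate_cohort(default_config(300), seed = 22)
  pr <- episodes_to_process(co$episodes, co$windows)
  ct <- count_transitions(pr)
  expect_true(all(ct >= 0))
  expect_equal(sum(ct[, 1:8]), nrow(pr$events))
  expect_equal(
    sum(ct[, "censored"]),
    sum(pr$intervals$exit_reason == "censored")
  )
  # row sums: every event or censoring out of state j is accounted for
  for (j in 1:7) {
    expect_equal(
      unname(rowSums(ct)[j]),
      sum(pr$events$from == j) +
        sum(pr$intervals$state == j &
          pr$intervals$exit_reason == "censored")
    )
  }
  # toy cohort: employment<->sick transitions as enumerated by hand
  tc <- count_transitions(toy_process())
  expect_equal(unname(tc["employment", "sick leave"]), 2L)
  expect_equal(unname(tc["sick leave", "employment"]), 2L)
})

test_that("overlapping or malformed episodes are rejected", {
  ep <- data.frame(
    person_id = c(1L, 1L), state = c(2L, 3L),
    start_age = c(25, 25.5), end_age = c(26, 27)
  )
  expect_error(
    episodes_to_process(ep, data.frame(
      person_id = 1L, entry_age = 20, exit_age = 36
    )),
    "overlap"
  )
  expect_error(
    validate_episodes(data.frame(
      person_id = 1L, state = 2L, start_age = 26, end_age = 25
    )),
    "start_age < end_age"
  )
})

test_that("same-state re-episodes are counted but leave intervals unbroken", {
  ep <- data.frame(
    person_id = c(1L, 1L), state = c(2L, 2L),
    start_age = c(24, 25), end_age = c(25, 27)
  )
  pr <- episodes_to_process(ep, data.frame(
    person_id = 1L, entry_age = 20, exit_age = 30
  ))
  ct <- count_transitions(pr)
  expect_equal(unname(ct["sick leave", "sick leave"]), 1L)
  iv <- pr$intervals[pr$intervals$person_id == 1, ]
  # one employment, one fused sick spell, one trailing employment
  expect_equal(iv$state, c(1L, 2L, 1L))
  expect_equal(iv$entry, c(20, 24, 27))
})

test_that("rare-transition filtering respects the threshold boundary", {
  # 10 persons with sick episodes (kept), 9 with vocational (removed)
  n_sick <- 10
  n_voc <- 9
  ep <- rbind(
    data.frame(
      person_id = 1:n_sick, state = 2L, start_age = 25, end_age = 26
    ),
    data.frame(
      person_id = n_sick + (1:n_voc), state = 3L,
      start_age = 25, end_age = 26
    )
  )
  win <- data.frame(
    person_id = 1:(n_sick + n_voc), entry_age = 20, exit_age = 30
  )
  pr <- episodes_to_process(ep, win)
  out <- filter_rare_transitions(pr, min_count = 10)
  expect_true(all(paste(out$removed$from, out$removed$to) %in%
    c("1 3", "3 1")))
  expect_equal(sort(unique(out$removed$count)), 9)
  ct <- count_transitions(out$processed)
  expect_equal(unname(ct["employment", "sick leave"]), 10L)
  expect_equal(unname(ct["employment", "vocational rehabilitation"]), 0L)
  # spliced persons are employed throughout: single censored interval
  iv <- out$processed$intervals
  voc_person <- iv[iv$person_id == n_sick + 1, ]
  expect_equal(nrow(voc_person), 1)
  expect_equal(voc_person$state, 1L)
  expect_equal(voc_person$exit - voc_person$entry, 10)
  expect_error(filter_rare_transitions(pr, min_count = 0), "at least 1")
})

test_that("merging onto six states conserves transitions and fuses intervals", {
  co <- generate_cohort(default_config(300), seed = 23)
  pr <- episodes_to_process(co$episodes, co$windows)
  m <- merge_states(pr)
  expect_equal(nrow(m$events), nrow(pr$events))
  expect_equal(length(m$space$codes), 6)
  # transitions within {3,4,5} become same-state in the merged stream
  map <- pr$space$merge_map
  within <- sum(map[pr$events$from] == map[pr$events$to] &
    pr$events$from != pr$events$to)
  expect_equal(
    sum(m$events$from == m$events$to) -
      sum(pr$events$from == pr$events$to),
    within
  )
  # merged intervals still tile the windows
  tl <- tapply(m$intervals$exit - m$intervals$entry, m$intervals$person_id, sum)
  tl0 <- tapply(
    pr$intervals$exit - pr$intervals$entry, pr$intervals$person_id, sum
  )
  expect_equal(tl, tl0, tolerance = 1e-9)
})
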