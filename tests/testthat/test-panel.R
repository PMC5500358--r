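make_cov <- function(ids, iq = 5, mental = 9) {
  data.frame(
    person_id = ids, iq_raw = iq, mental_raw = mental,
    phys_health = 9, arm = 9, hand = 9, walking = 9, back = 9, skin = 9,
    bmi = 23, birth_year = 1980
  )
}

test_that("panel rows and indicators follow the occupancy rule", {
  # person employed throughout: all-zero sick-leave indicator
  win <- data.frame(person_id = 1L, entry_age = 20, exit_age = 28)
  ep <- data.frame(
    person_id = integer(0), state = integer(0),
    start_age = numeric(0), end_age = numeric(0)
  )
  pr <- episodes_to_process(ep, win)
  pan <- build_panel(pr, make_cov(1L), outcome_state = 2, ages = 20:58)
  expect_equal(pan$age, 20:27)
  expect_equal(pan$y, rep(0L, 8))
  # disability from 34.5 onward: zero through the age-33 row, one from 34
  win2 <- data.frame(person_id = 1L, entry_age = 30, exit_age = 38)
  ep2 <- data.frame(
    person_id = 1L, state = 6L, start_age = 34.5, end_age = 38
  )
  pr2 <- episodes_to_process(ep2, win2)
  pan2 <- build_panel(pr2, make_cov(1L), outcome_state = 6, ages = 20:58)
  expect_equal(pan2$age, 30:37)
  expect_equal(pan2$y, c(rep(0L, 4), rep(1L, 4)))
})

test_that("panel row count equals hand-counted observed years on a toy cohort", {
  # five persons with different windows; outcome sick leave
  win <- data.frame(
    person_id = 1:5,
    entry_age = c(20, 20, 25.5, 20, 33),
    exit_age = c(28, 24, 30, 26, 36)
  )
  ep <- data.frame(
    person_id = c(1L, 4L), state = c(2L, 2L),
    start_age = c(22.2, 21), end_age = c(22.9, 23)
  )
  pr <- episodes_to_process(ep, win)
  pan <- build_panel(pr, make_cov(1:5), outcome_state = 2, ages = 20:58)
  # hand count: 8 + 4 + 5 (ages 25..29) + 6 + 3 = 26 rows
  expect_equal(nrow(pan), 26)
  expect_equal(sum(pan$y[pan$person_id == 1]), 1) # year 22 only
  expect_equal(sum(pan$y[pan$person_id == 4]), 2) # years 21 and 22
})

test_that("death terminates other panels but extends its own with ones", {
  win <- data.frame(person_id = 1L, entry_age = 20, exit_age = 30)
  ep <- data.frame(
    person_id = 1L, state = 8L, start_age = 24.5, end_age = 30
  )
  pr <- episodes_to_process(ep, win)
  pan_d <- build_panel(pr, make_cov(1L), outcome_state = 8, ages = 20:58)
  expect_equal(pan_d$age, 20:29)
  expect_equal(pan_d$y, c(rep(0L, 4), rep(1L, 6)))
  pan_s <- build_panel(pr, make_cov(1L), outcome_state = 2, ages = 20:58)
  expect_equal(max(pan_s$age), 24) # partial death year kept, nothing after
})

test_that("years fully abroad are excluded from other outcomes", {
  win <- data.frame(person_id = 1L, entry_age = 20, exit_age = 30)
  ep <- data.frame(
    person_id = 1L, state = 7L, start_age = 23, end_age = 26
  )
  pr <- episodes_to_process(ep, win)
  pan_s <- build_panel(pr, make_cov(1L), outcome_state = 2, ages = 20:58)
  expect_equal(pan_s$age, c(20:22, 26:29))
  pan_e <- build_panel(pr, make_cov(1L), outcome_state = 7, ages = 20:58)
  expect_equal(pan_e$age, 20:29)
  # emigration covers [23, 26): years 23, 24, 25 occupied, year 26 not
  expect_equal(sum(pan_e$y), 3)
})

test_that("persons with missing IQ or mental scores are excluded", {
  win <- data.frame(person_id = 1:2, entry_age = 20, exit_age = 25)
  ep <- data.frame(
    person_id = integer(0), state = integer(0),
    start_age = numeric(0), end_age = numeric(0)
  )
  pr <- episodes_to_process(ep, win)
  cov <- make_cov(1:2)
  cov$iq_raw[2] <- NA
  pan <- build_panel(pr, cov, outcome_state = 2, ages = 20:58)
  expect_equal(unique(pan$person_id), 1L)
})
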