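test_that("an empty time span gives the identity matrix", {
  co <- generate_cohort(cfg_constant(50), seed = 41)
  H <- nelson_aalen(episodes_to_process(co$episodes, co$windows))
  P <- aalen_johansen(H, 23, 23)
  expect_equal(unclass(P), diag(8), ignore_attr = TRUE)
  expect_error(aalen_johansen(H, 25, 23), "t1")
})

test_that("two-state reduction equals one minus Kaplan-Meier everywhere", {
  skip_if_not_installed("survival")
  co <- generate_cohort(
    cfg_two_state(500, birth_years = c(1960L, 1980L)),
    seed = 42
  )
  pr <- episodes_to_process(co$episodes, co$windows)
  H <- nelson_aalen(pr)
  iv <- pr$intervals
  status <- as.integer(iv$exit_reason == "transition")
  km <- survival::survfit(
    survival::Surv(iv$entry, iv$exit, status) ~ 1
  )
  ts <- km$time[km$n.event > 0]
  surv <- km$surv[km$n.event > 0]
  for (s in seq_along(ts)) {
    P <- aalen_johansen(H, 20, ts[s])
    expect_equal(P[1, 8], 1 - surv[s], tolerance = 1e-12)
    expect_equal(P[1, 1], surv[s], tolerance = 1e-12)
  }
})

test_that("matrix product agrees with a brute-force forward recursion", {
  co <- generate_cohort(cfg_constant(80), seed = 43)
  pr <- episodes_to_process(co$episodes, co$windows)
  H <- nelson_aalen(pr)
  # oracle: rebuild increments by brute force, multiply factors in a loop
  pairs <- unique(H$inc[c("from", "to")])
  steps <- list()
  for (r in seq_len(nrow(pairs))) {
    j <- pairs$from[r]
    k <- pairs$to[r]
    o <- brute_force_na(pr$events, pr$intervals, j, k)
    o$dh <- diff(c(0, o$H))
    steps[[r]] <- data.frame(time = o$time, from = j, to = k, dh = o$dh)
  }
  steps <- do.call(rbind, steps)
  P_or <- diag(8)
  for (t in sort(unique(steps$time))) {
    M <- diag(8)
    st <- steps[steps$time == t, ]
    for (r in seq_len(nrow(st))) {
      M[st$from[r], st$to[r]] <- M[st$from[r], st$to[r]] + st$dh[r]
      M[st$from[r], st$from[r]] <- M[st$from[r], st$from[r]] - st$dh[r]
    }
    P_or <- P_or %*% M
  }
  P <- aalen_johansen(H, 20, max(H$times))
  expect_equal(unclass(P), P_or, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("every transition matrix is row-stochastic with unit absorbing row", {
  co <- generate_cohort(default_config(400), seed = 44)
  H <- nelson_aalen(episodes_to_process(co$episodes, co$windows))
  for (t2 in c(25, 32, 45, 57.9)) {
    P <- aalen_johansen(H, 20, t2)
    expect_lt(max(abs(rowSums(unclass(P)) - 1)), 1e-10)
    expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
    expect_equal(unname(P[8, ]), c(rep(0, 7), 1))
  }
})

test_that("occupation curves start at the weights and conserve mass", {
  co <- generate_cohort(default_config(300), seed = 45)
  H <- nelson_aalen(episodes_to_process(co$episodes, co$windows))
  occ <- occupation_probabilities(H, 20, grid = c(20, 30, 40))
  expect_equal(unname(occ$Qgrid[1, ]), c(1, rep(0, 7)))
  expect_lt(max(abs(rowSums(occ$Q) - 1)), 1e-10)
  expect_true(all(diff(occ$Q[, 8]) >= -1e-12)) # dead is non-decreasing
  # no events: curve stays at the weights
  win <- data.frame(person_id = 1:4, entry_age = 20, exit_age = 25)
  ep <- data.frame(
    person_id = integer(0), state = integer(0),
    start_age = numeric(0), end_age = numeric(0)
  )
  H0 <- nelson_aalen(episodes_to_process(ep, win))
  occ0 <- occupation_probabilities(H0, 20, grid = c(21, 24))
  expect_equal(unname(occ0$Qgrid[2, ]), c(1, rep(0, 7)))
  w <- c(0.5, 0.5, rep(0, 6))
  occw <- occupation_probabilities(H0, 20, weights = w, grid = 23)
  expect_equal(unname(occw$Qgrid[1, ]), w)
  expect_error(
    occupation_probabilities(H0, 20, weights = rep(1, 8)),
    "probability vector"
  )
})

test_that("restricted means integrate step curves exactly", {
  # constant curve: all mass in employment over [20, 45]
  win <- data.frame(person_id = 1:3, entry_age = 20, exit_age = 45)
  ep <- data.frame(
    person_id = integer(0), state = integer(0),
    start_age = numeric(0), end_age = numeric(0)
  )
  H0 <- nelson_aalen(episodes_to_process(ep, win))
  occ0 <- occupation_probabilities(H0, 20)
  E <- restricted_mean_times(occ0, 20, 45)
  expect_equal(unname(E[1]), 25)
  expect_equal(unname(sum(E)), 25)
  expect_error(restricted_mean_times(occ0, 30, 30), "smaller")
  # single step: death of the only person at 30 gives rectangle areas
  ep1 <- data.frame(
    person_id = 1L, state = 8L, start_age = 30, end_age = 45
  )
  win1 <- data.frame(person_id = 1L, entry_age = 20, exit_age = 45)
  H1 <- nelson_aalen(episodes_to_process(ep1, win1))
  E1 <- restricted_mean_times(occupation_probabilities(H1, 20), 20, 45)
  expect_equal(unname(E1[8]), 15)
  expect_equal(unname(E1[1]), 10)
})

test_that("restricted means equal the person-year tally without censoring", {
  co <- generate_cohort(cfg_constant(400), seed = 46)
  pr <- episodes_to_process(co$episodes, co$windows)
  H <- nelson_aalen(pr)
  E <- restricted_mean_times(occupation_probabilities(H, 20), 20, 28)
  expect_equal(unname(sum(E)), 8, tolerance = 1e-9)
  n <- pr$n_persons
  iv <- pr$intervals
  tally <- sapply(1:8, function(s) {
    sum(pmin(iv$exit[iv$state == s], 28) -
      pmin(iv$entry[iv$state == s], 28)) / n
  })
  # dead person-years: window end minus death age
  dth <- pr$events$time[pr$events$to == 8]
  tally[8] <- sum(28 - dth) / n
  expect_equal(as.numeric(E), tally, tolerance = 1e-9)
})

test_that("occupation estimates approach the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  n <- 3000
  co <- generate_cohort(cfg_constant(n), seed = 47)
  H <- nelson_aalen(episodes_to_process(co$episodes, co$windows))
  lam <- cfg_generator_matrix(cfg_constant(n))
  for (t in c(24, 28)) {
    Qhat <- occupation_probabilities(H, 20, grid = t)$Qgrid[1, ]
    Qtrue <- as.numeric(
      (c(1, rep(0, 7)) %*% as.matrix(Matrix::expm(lam * (t - 20))))
    )
    se <- sqrt(pmax(Qtrue * (1 - Qtrue), 1e-12) / n)
    on <- Qtrue > 1e-6
    expect_true(all(abs(Qhat[on] - Qtrue[on]) <= 3 * se[on] + 1e-8))
  }
})
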