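test_that("pure death model matches its exponential closed form", {
  lambda <- 0.08
  n <- 4000
  cfg <- cfg_two_state(n, lambda = lambda, birth_years = c(1980L, 1980L))
  co <- generate_cohort(cfg, seed = 81)
  # empirical P(dead by t) vs 1 - exp(-lambda (t - 20))
  for (t in c(23, 26, 28)) {
    p_true <- 1 - exp(-lambda * (t - 20))
    p_hat <- mean(!is.na(co$truth$death_age) & co$truth$death_age <= t)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 3 * se + 1e-9)
  }
})

test_that("window arithmetic follows birth year and the calendar span", {
  cfg <- cfg_two_state(200, lambda = 0, birth_years = c(1980L, 1980L))
  co <- generate_cohort(cfg, seed = 82)
  expect_true(all(co$windows$entry_age == 20))
  expect_true(all(co$windows$exit_age == 28))
  cfg2 <- cfg_two_state(200, lambda = 0, birth_years = c(1950L, 1950L))
  co2 <- generate_cohort(cfg2, seed = 82)
  expect_true(all(co2$windows$entry_age == 42))
  expect_true(all(co2$windows$exit_age == 58))
})

test_that("generation is reproducible given a seed", {
  cfg <- default_config(150)
  a <- generate_cohort(cfg, seed = 83)
  b <- generate_cohort(cfg, seed = 83)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$covariates, b$covariates)
  c2 <- generate_cohort(cfg, seed = 84)
  expect_false(identical(a$episodes, c2$episodes))
})

test_that("transition counts are zero exactly where intensities are zero", {
  cfg <- cfg_constant(600) # untruncated, no same-state injection
  co <- generate_cohort(cfg, seed = 85)
  pr <- episodes_to_process(co$episodes, co$windows)
  ct <- count_transitions(pr)
  z <- cfg$intensities[[1]]
  for (j in 1:7) {
    for (k in 1:8) {
      if (j != k && z[j, k] == 0) {
        expect_equal(unname(ct[j, k]), 0L)
      }
    }
  }
  # and the allowed pairs with sizeable rates do occur
  expect_gt(ct[1, 2], 0)
  expect_gt(ct[2, 1], 0)
})

test_that("default config encodes the published group structure", {
  cfg <- default_config(1000)
  prev <- cfg$group_prevalences
  expect_equal(sum(prev), 1, tolerance = 1e-9)
  # low-IQ prevalence near the published combined-score proportion
  expect_equal(
    unname(prev["low.none"] + prev["low.problems"]),
    57092 / 863369,
    tolerance = 0.01
  )
  # mental-problem prevalence near the published scored proportion
  # (the joint-table anchors pull it slightly above the marginal share)
  expect_lt(
    abs(unname(prev["average.problems"] + prev["low.problems"] +
      prev["high.problems"]) - 33880 / 610294),
    0.01
  )
  # disability-entry effects ordered as published
  e <- cfg$group_effects[, 6]
  expect_gt(e[["low.problems"]], e[["average.problems"]])
  expect_gte(e[["average.problems"]], e[["low.none"]] - 0.1)
  expect_gt(e[["low.none"]], e[["average.none"]])
  expect_error(default_config(50), "at least 100")
})

test_that("scale bounds the observed cohort size", {
  co <- generate_cohort(default_config(400), seed = 86)
  expect_lte(nrow(co$windows), 400)
  expect_gt(nrow(co$windows), 300)
  # covariates line up with observed persons
  expect_setequal(co$covariates$person_id, co$windows$person_id)
})

test_that("invalid configurations are rejected", {
  cfg <- default_config(200)
  cfg$intensities[[1]][2, 1] <- -1
  expect_error(generate_cohort(cfg, seed = 1), "non-negative")
  cfg2 <- default_config(200)
  cfg2$group_prevalences <- cfg2$group_prevalences * 2
  expect_error(generate_cohort(cfg2, seed = 1), "sum to 1")
  cfg3 <- default_config(200)
  cfg3$intensities[[1]][8, 1] <- 0.1
  expect_error(generate_cohort(cfg3, seed = 1), "absorbing")
  cfg4 <- default_config(200)
  cfg4$age_range <- c(20, Inf)
  cfg4$intensities[[1]][3, ] <- 0
  cfg4$intensities[[2]][3, ] <- 0
  expect_error(generate_cohort(cfg4, seed = 1), "infinite horizon")
})
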