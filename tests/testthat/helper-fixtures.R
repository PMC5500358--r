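# Shared fixtures: hand-enumerable toy cohorts and small simulation
# configurations with known generating intensities.

toy_windows <- function() {
  data.frame(
    person_id = 1:3,
    entry_age = c(20, 20, 25),
    exit_age = c(36, 36, 36)
  )
}

# person 1: one sick-leave episode inside the window
# person 2: sick leave then death at 30
# person 3: delayed entry at 25, already on vocational rehabilitation
toy_episodes <- function() {
  data.frame(
    person_id = c(1L, 2L, 2L, 3L),
    state = c(2L, 2L, 8L, 3L),
    start_age = c(25, 27, 30, 24),
    end_age = c(26, 29, 36, 27)
  )
}

toy_process <- function() {
  episodes_to_process(toy_episodes(), toy_windows())
}

# config with a single employment -> dead transition, staggered windows
cfg_two_state <- function(n, lambda = 0.08,
                          birth_years = c(1972L, 1980L)) {
  cfg <- default_config(max(n, 100))
  cfg$n_persons <- as.integer(n)
  cfg$birth_year_range <- birth_years
  cfg$same_state_prob <- 0
  cfg$covariate_model$iq_missing <- 0
  cfg$covariate_model$mental_missing <- 0
  z <- matrix(0, 8, 8)
  z[1, 8] <- lambda
  cfg$intensities <- list(z, z)
  cfg$group_effects <- matrix(
    1, 6, 8,
    dimnames = dimnames(cfg$group_effects)
  )
  cfg
}

# constant-intensity four-state model (employment, sick leave,
# disability, dead) embedded in the eight-state machinery; birth year
# 1980 so every path is observed over ages [20, 28] with no truncation
cfg_constant <- function(n) {
  cfg <- default_config(max(n, 100))
  cfg$n_persons <- as.integer(n)
  cfg$birth_year_range <- c(1980L, 1980L)
  cfg$same_state_prob <- 0
  cfg$covariate_model$iq_missing <- 0
  cfg$covariate_model$mental_missing <- 0
  z <- matrix(0, 8, 8)
  z[1, 2] <- 0.30
  z[2, 1] <- 1.20
  z[1, 6] <- 0.02
  z[2, 6] <- 0.10
  z[6, 1] <- 0.05
  z[1, 8] <- 0.01
  z[2, 8] <- 0.02
  z[6, 8] <- 0.03
  cfg$intensities <- list(z, z)
  cfg$group_effects <- matrix(
    1, 6, 8,
    dimnames = dimnames(cfg$group_effects)
  )
  cfg
}

cfg_generator_matrix <- function(cfg) {
  z <- cfg$intensities[[1]]
  diag(z) <- -rowSums(z)
  z
}

# two-state disability-entry config with a known multiplicative group
# effect concentrated on the low-IQ groups
cfg_recovery <- function(n, effect = 14, lambda = 0.004) {
  cfg <- default_config(max(n, 100))
  cfg$n_persons <- as.integer(n)
  cfg$birth_year_range <- c(1980L, 1980L)
  cfg$same_state_prob <- 0
  cfg$covariate_model$iq_missing <- 0
  cfg$covariate_model$mental_missing <- 0
  z <- matrix(0, 8, 8)
  z[1, 6] <- lambda
  cfg$intensities <- list(z, z)
  eff <- matrix(1, 6, 8, dimnames = dimnames(cfg$group_effects))
  eff[, 6] <- c(1, effect, 1, 1, effect, 1)
  cfg$group_effects <- eff
  cfg$group_prevalences <- stats::setNames(
    c(0.35, 0.3, 0.1, 0.1, 0.1, 0.05), rownames(eff)
  )
  cfg
}

# independent brute-force Nelson-Aalen for one transition pair
brute_force_na <- function(events, intervals, j, k) {
  ev <- events[events$from == j & events$to == k & events$from != events$to, ]
  ts <- sort(unique(ev$time))
  H <- 0
  V <- 0
  out_H <- numeric(length(ts))
  out_V <- numeric(length(ts))
  for (s in seq_along(ts)) {
    t <- ts[s]
    Y <- sum(
      intervals$state == j & intervals$entry < t & intervals$exit >= t
    )
    n <- sum(ev$time == t)
    H <- H + n / Y
    V <- V + n / Y^2
    out_H[s] <- H
    out_V[s] <- V
  }
  data.frame(time = ts, H = out_H, var = out_V)
}
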