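#' Read and write registry-schema CSV files
#'
#' `episodes.csv` has columns `person_id, state_code, start_age, end_age`
#' (decimal years, '.' separator, header row); `covariates.csv` has
#' `person_id, iq_raw, mental_raw, phys_health, arm, hand, walking, back,
#' skin, bmi, birth_year`, with the empty string for missing values.
#'
#' @param path file path.
#' @return A data frame in the internal column naming.
#' @export
read_episodes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("person_id", "state_code", "start_age", "end_age")
  if (!all(req %in% names(d))) {
    stop("episodes.csv must have columns ", paste(req, collapse = ", "))
  }
  data.frame(
    person_id = d$person_id, state = as.integer(d$state_code),
    start_age = as.numeric(d$start_age), end_age = as.numeric(d$end_age)
  )
}

#' @rdname read_episodes
#' @param episodes episode table with internal column names.
#' @export
write_episodes <- function(episodes, path) {
  utils::write.csv(
    data.frame(
      person_id = episodes$person_id, state_code = episodes$state,
      start_age = episodes$start_age, end_age = episodes$end_age
    ),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname read_episodes
#' @export
read_covariates <- function(path) {
  d <- utils::read.csv(
    path,
    stringsAsFactors = FALSE,
    na.strings = c("", "NA")
  )
  if (!all(c("person_id", "birth_year") %in% names(d))) {
    stop("covariates.csv must carry person_id and birth_year")
  }
  d
}

#' @rdname read_episodes
#' @param covariates covariate table.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE,
    na = "")
  invisible(path)
}

# small deterministic fingerprint for the manifest (not cryptographic)
config_fingerprint <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
    collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional), process, estimate, infer and model in
#' order with one master seed fanned out per stage, writing tidy CSV
#' outputs and a JSON manifest. Every table passes its conservation
#' checks (row-stochasticity, restricted means summing to the window
#' length) before it is written; a violation aborts the stage. With the
#' same config and seed the outputs are byte-identical across runs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a `sim_config`; ignored when `episodes`/`covariates`
#'   are given.
#' @param episodes,covariates optional input tables (or CSV paths) to
#'   analyse instead of simulating.
#' @param seed master seed.
#' @param min_count rare-transition threshold.
#' @param mean_window age window for restricted means.
#' @param ci_level confidence level for the restricted-mean intervals.
#' @param B perturbation replicates for the intervals.
#' @param hrr fit hazard-rate-ratio models (`"none"`, `"unadjusted"`,
#'   `"both"`).
#' @param verbose narrate cohort sizes and event counts.
#' @return Invisibly, a list with every table written (class
#'   `analysis_report`).
#' @export
run_pipeline <- function(out_dir,
                         config = default_config(1000),
                         episodes = NULL, covariates = NULL,
                         seed = 1L, min_count = 10L,
                         mean_window = c(20, 45),
                         ci_level = 0.99, B = 1000L,
                         hrr = c("both", "unadjusted", "none"),
                         verbose = TRUE) {
  hrr <- match.arg(hrr)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- list(simulate = seed, ci = seed + 1L)

  if (is.null(episodes)) {
    say("simulating cohort of %d persons (seed %d)", config$n_persons,
      seeds$simulate)
    cohort <- generate_cohort(config, seed = seeds$simulate)
    episodes <- cohort$episodes
    covariates <- cohort$covariates
    write_episodes(episodes, file.path(out_dir, "episodes.csv"))
    write_covariates(covariates, file.path(out_dir, "covariates.csv"))
  } else {
    if (is.character(episodes)) episodes <- read_episodes(episodes)
    if (is.character(covariates)) covariates <- read_covariates(covariates)
  }

  windows <- observation_windows(covariates)
  say("processing %d persons with %d registry episodes",
    nrow(windows), nrow(episodes))
  processed <- episodes_to_process(episodes, windows)
  counts <- count_transitions(processed)
  say("%d transitions recorded, %d censored spells",
    sum(counts[, 1:8]), sum(counts[, "censored"]))

  filt <- filter_rare_transitions(processed, min_count = min_count)
  processed <- filt$processed
  if (nrow(filt$removed)) {
    say("removed %d rare transition pair(s): %s", nrow(filt$removed),
      paste(filt$removed$from, "->", filt$removed$to, collapse = ", "))
  }

  utils::write.csv(
    as.data.frame.table(counts, responseName = "n"),
    file.path(out_dir, "transition_counts.csv"),
    row.names = FALSE
  )

  # full-space occupation curves, overall and per group
  H8 <- nelson_aalen(processed)
  grid <- seq(20, floor(H8$range[2]), by = 0.5)
  occ <- occupation_probabilities(H8, origin_age = 20, grid = grid)
  if (any(abs(rowSums(occ$Q) - 1) > 1e-8)) {
    stop("occupation probabilities do not conserve mass; refusing to write")
  }
  curves <- as.data.frame(occ)
  curves$group <- "all"
  grp <- classify_group(covariates$iq_raw, covariates$mental_raw)
  for (g in levels(grp)) {
    ids <- covariates$person_id[!is.na(grp) & grp == g]
    ids <- intersect(ids, processed$windows$person_id)
    if (length(ids) < 25) next
    sub <- subset_process(processed, ids)
    Hg <- nelson_aalen(sub)
    og <- occupation_probabilities(
      Hg, origin_age = 20,
      grid = grid[grid <= max(Hg$range)]
    )
    cg <- as.data.frame(og)
    cg$group <- g
    curves <- rbind(curves, cg)
  }
  utils::write.csv(curves, file.path(out_dir, "occupation_curves.csv"),
    row.names = FALSE)

  # merged-space restricted means with simulation CIs
  merged <- merge_states(processed)
  H6 <- nelson_aalen(merged)
  ci <- simulation_ci(
    H6,
    functional = "restricted_mean", B = B, level = ci_level,
    seed = seeds$ci, origin_age = mean_window[1],
    t0 = mean_window[1], t1 = mean_window[2]
  )
  if (abs(sum(ci$estimate) - diff(mean_window)) > 1e-6) {
    stop("restricted means do not sum to the window length; refusing to write")
  }
  utils::write.csv(ci, file.path(out_dir, "restricted_means.csv"),
    row.names = FALSE)

  report <- list(
    transition_counts = counts, removed = filt$removed,
    occupation_curves = curves, restricted_means = ci
  )

  if (hrr != "none") {
    say("fitting unadjusted hazard-rate-ratio models")
    fits_u <- hrr_models(merged, covariates, adjusted = FALSE)
    tab_u <- hrr_table(fits_u)
    utils::write.csv(tab_u, file.path(out_dir, "hrr_unadjusted.csv"),
      row.names = FALSE)
    report$hrr_unadjusted <- tab_u
    if (hrr == "both") {
      say("fitting adjusted hazard-rate-ratio models")
      fits_a <- hrr_models(merged, covariates, adjusted = TRUE)
      tab_a <- hrr_table(fits_a)
      utils::write.csv(tab_a, file.path(out_dir, "hrr_adjusted.csv"),
        row.names = FALSE)
      report$hrr_adjusted <- tab_a
    }
  }

  manifest <- list(
    package = "msregistry",
    version = as.character(utils::packageVersion("msregistry")),
    seed = seed, stage_seeds = seeds,
    min_count = min_count, ci_level = ci_level, B = B,
    n_persons = processed$n_persons,
    n_events = nrow(processed$events),
    removed_pairs = filt$removed,
    config_fingerprint = if (!is.null(config)) {
      config_fingerprint(config)
    } else {
      NA
    }
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  say("report written to %s", out_dir)
  class(report) <- "analysis_report"
  invisible(report)
}

# restrict a processed cohort to a subset of persons
subset_process <- function(processed, ids) {
  keep <- processed$windows$person_id %in% ids
  structure(
    list(
      events = processed$events[
        processed$events$person_id %in% ids, ,
        drop = FALSE
      ],
      intervals = processed$intervals[
        processed$intervals$person_id %in% ids, ,
        drop = FALSE
      ],
      windows = processed$windows[keep, , drop = FALSE],
      first_state = processed$first_state[keep],
      space = processed$space,
      n_persons = sum(keep)
    ),
    class = "msm_process"
  )
}
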