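#' Build a person-year panel of state indicators
#'
#' Constructs the discrete-time panel behind the cloglog GEE models: one
#' row per person per observed calendar-age year, with a binary indicator
#' equal to one when the person occupies the outcome state at any point
#' during that year. Conventions:
#' * a year is included when any part of it falls inside the person's
#'   observation window;
#' * death is absorbing, so for the death outcome the indicator stays one
#'   from the year of death to the end of the person's calendar window,
#'   while for every other outcome rows stop after the year of death;
#' * for outcomes other than emigration, years spent entirely abroad are
#'   excluded from the risk rows;
#' * persons whose IQ or mental-health score is missing are excluded
#'   (complete-covariate persons only).
#'
#' @param processed an `msm_process` object (any state space).
#' @param covariates covariate table with at least `person_id`, `iq_raw`,
#'   `mental_raw`; physical scores and BMI are carried through when
#'   present.
#' @param outcome_state state code of the outcome.
#' @param ages integer calendar-age years spanning the panel.
#' @return A data frame `person_id`, `age`, `y`, `group` (six-level
#'   IQ-by-mental factor) plus any physical-score/BMI columns found.
#' @export
build_panel <- function(processed, covariates, outcome_state,
                        ages = 20:58) {
  stopifnot(inherits(processed, "msm_process"))
  space <- processed$space
  absorbing <- space$absorbing
  if (!outcome_state %in% space$codes) {
    stop("outcome_state is not in the state space")
  }
  group <- classify_group(covariates$iq_raw, covariates$mental_raw)
  keep <- !is.na(group)
  cov_ok <- covariates[keep, , drop = FALSE]
  cov_ok$group <- group[keep]

  win <- processed$windows
  win <- win[win$person_id %in% cov_ok$person_id, , drop = FALSE]
  if (!nrow(win)) stop("no persons with complete covariates observed")
  iv <- processed$intervals
  iv <- iv[iv$person_id %in% win$person_id, , drop = FALSE]
  iv_split <- split(iv, factor(iv$person_id, levels = win$person_id))
  # death times: event into the absorbing state
  ev <- processed$events
  dth <- ev[ev$to == absorbing, , drop = FALSE]
  death_at <- stats::setNames(dth$time, dth$person_id)
  # emigrated code differs between full and merged space
  emig_code <- which(space$labels == "emigrated")

  out_pid <- vector("list", nrow(win))
  out_age <- vector("list", nrow(win))
  out_y <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    pid <- win$person_id[i]
    entry <- win$entry_age[i]
    exit <- win$exit_age[i]
    d <- death_at[as.character(pid)]
    died <- !is.na(d)
    obs_end <- if (died && outcome_state != absorbing) d else exit
    yrs <- ages[ages < obs_end & (ages + 1) > entry]
    if (died && outcome_state != absorbing) {
      # keep the partial year of death as an at-risk row
      yrs <- ages[ages < d + 1e-9 & (ages + 1) > entry]
      yrs <- yrs[yrs <= floor(d + 1e-9)]
      yrs <- yrs[yrs < exit]
    }
    if (!length(yrs)) next
    spells <- iv_split[[i]]
    occ <- logical(length(yrs))
    s_match <- spells[spells$state == outcome_state, , drop = FALSE]
    if (nrow(s_match)) {
      for (r in seq_len(nrow(s_match))) {
        occ <- occ | (yrs < s_match$exit[r] & (yrs + 1) > s_match$entry[r])
      }
    }
    if (outcome_state == absorbing && died) {
      occ <- occ | (yrs + 1 > d)
    }
    if (outcome_state != emig_code && outcome_state != absorbing) {
      abroad <- spells[spells$state == emig_code, , drop = FALSE]
      if (nrow(abroad)) {
        fully_abroad <- rep(FALSE, length(yrs))
        for (r in seq_len(nrow(abroad))) {
          fully_abroad <- fully_abroad |
            (yrs >= abroad$entry[r] - 1e-9 & yrs + 1 <= abroad$exit[r] + 1e-9)
        }
        keep_yr <- !fully_abroad
        yrs <- yrs[keep_yr]
        occ <- occ[keep_yr]
      }
    }
    if (!length(yrs)) next
    out_pid[[i]] <- rep(pid, length(yrs))
    out_age[[i]] <- yrs
    out_y[[i]] <- as.integer(occ)
  }
  panel <- data.frame(
    person_id = unlist(out_pid),
    age = unlist(out_age),
    y = unlist(out_y)
  )
  if (!nrow(panel)) stop("no observed person-years for this outcome")
  m <- match(panel$person_id, cov_ok$person_id)
  panel$group <- cov_ok$group[m]
  extra <- intersect(
    c("phys_health", "arm", "hand", "walking", "back", "skin", "bmi"),
    names(cov_ok)
  )
  for (v in extra) panel[[v]] <- cov_ok[[v]][m]
  panel
}
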