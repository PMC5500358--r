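#' Fit the hazard-rate-ratio models for benefit outcomes
#'
#' For each outcome state, fits one discrete-time cloglog GEE on the
#' person-year panel with a separate intercept per age year and a
#' group-by-period interaction, where the period splits each effect at
#' `split_age` (default 35, the last age at which the targeted young-age
#' disability benefit can be granted). Because the period indicator is a
#' function of age it is absorbed by the year intercepts, so the design
#' carries one column per non-reference group and period; the reference
#' group (average IQ, no mental health problems) is the baseline in both
#' periods. The adjusted variant adds the six physical enrolment scores,
#' dichotomized as "any impairment" (score below 9), and continuous BMI.
#'
#' @param processed an `msm_process`, normally on the merged six-state
#'   space.
#' @param covariates covariate table (see [build_panel()]).
#' @param outcomes integer state codes to model; default: every state
#'   except employment and the states a panel cannot be built for.
#' @param split_age age at which group effects are split (years).
#' @param adjusted logical; add physical scores and BMI.
#' @param corstr working correlation passed to the GEE solver.
#' @param ages panel age range.
#' @return A named list of `cloglog_gee` fits (class `hrr_fits`), one per
#'   outcome, each carrying attributes `outcome`, `split_age`,
#'   `adjusted`.
#' @export
hrr_models <- function(processed, covariates, outcomes = NULL,
                       split_age = 35, adjusted = FALSE,
                       corstr = "ar1", ages = 20:58) {
  stopifnot(inherits(processed, "msm_process"))
  space <- processed$space
  if (is.null(outcomes)) {
    outcomes <- setdiff(space$codes, which(space$labels == "employment"))
  }
  fits <- list()
  for (st in outcomes) {
    fit <- tryCatch(
      {
        panel <- build_panel(processed, covariates, st, ages = ages)
        des <- hrr_design(panel, split_age = split_age, adjusted = adjusted)
        f <- cloglog_gee_fit(
          des$y, des$X, des$id, des$time, corstr = corstr
        )
        attr(f, "empty_cells") <- des$empty_cells
        f
      },
      error = function(e) {
        warning(
          "skipping outcome '", space$labels[st], "': ",
          conditionMessage(e),
          call. = FALSE
        )
        NULL
      }
    )
    if (is.null(fit)) next
    attr(fit, "outcome") <- space$labels[st]
    attr(fit, "split_age") <- split_age
    attr(fit, "adjusted") <- adjusted
    attr(fit, "empty_cells") <- des$empty_cells
    fits[[space$labels[st]]] <- fit
  }
  class(fits) <- "hrr_fits"
  fits
}

# Explicit design matrix: year intercepts + group x period columns for
# the non-reference groups (+ optional physical adjustment).
hrr_design <- function(panel, split_age = 35, adjusted = FALSE) {
  stopifnot(all(c("person_id", "age", "y", "group") %in% names(panel)))
  phys <- c("phys_health", "arm", "hand", "walking", "back", "skin")
  keep <- rep(TRUE, nrow(panel))
  if (adjusted) {
    have <- c(intersect(phys, names(panel)),
      intersect("bmi", names(panel)))
    if (!length(have)) stop("no physical covariates present to adjust for")
    keep <- stats::complete.cases(panel[have])
  }
  panel <- panel[keep, , drop = FALSE]
  if (!any(panel$y == 1)) {
    stop("no events for this outcome; cannot fit a hazard model")
  }
  # years with no events have -Inf intercepts; drop their rows (standard
  # discrete-time practice, they carry no information on the effects)
  ev_ages <- sort(unique(panel$age[panel$y == 1]))
  panel <- panel[panel$age %in% ev_ages, , drop = FALSE]
  age_f <- factor(panel$age)
  X_age <- stats::model.matrix(~ 0 + age_f)
  colnames(X_age) <- paste0("age", levels(age_f))
  period <- ifelse(panel$age < split_age, "before", "after")
  grp <- as.character(panel$group)
  cols <- list()
  empty <- character(0)
  for (g in setdiff(group_levels(), "average.none")) {
    for (p in c("before", "after")) {
      nm <- paste0("group", g, ":", p)
      v <- as.numeric(grp == g & period == p)
      # a cell with no person-years or no events is inestimable
      if (!any(v > 0) || !any(panel$y[v > 0] == 1)) {
        empty <- c(empty, nm)
        next
      }
      cols[[nm]] <- v
    }
  }
  X <- cbind(X_age, do.call(cbind, cols))
  if (adjusted) {
    for (v in intersect(phys, names(panel))) {
      X <- cbind(X, as.numeric(panel[[v]] < 9))
      colnames(X)[ncol(X)] <- paste0("impaired_", v)
    }
    if ("bmi" %in% names(panel)) {
      X <- cbind(X, bmi = panel$bmi)
    }
  }
  list(
    y = panel$y, X = X, id = panel$person_id, time = panel$age,
    empty_cells = empty
  )
}

#' Hazard-rate-ratio table
#'
#' Extracts the exponentiated group-by-period coefficients from one or
#' more cloglog GEE fits (see [hrr_models()]) into a table mirroring the
#' usual published layout: outcome, mental-health group, IQ group, period
#' relative to the split age, hazard rate ratio with Wald confidence
#' interval on the exponentiated scale, and p-value. The reference group
#' (average IQ, no mental problems) appears with HRR exactly 1.
#'
#' @param fits an `hrr_fits` list or a single `cloglog_gee` fit with
#'   group-by-period columns.
#' @param level confidence level for the Wald intervals.
#' @return A data frame of class `hrr_table`.
#' @export
hrr_table <- function(fits, level = 0.95) {
  if (inherits(fits, "cloglog_gee")) {
    fits <- structure(
      stats::setNames(list(fits), attr(fits, "outcome") %||% "outcome"),
      class = "hrr_fits"
    )
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    b <- stats::coef(fit)
    gp <- grep("^group.*:(before|after)$", names(b), value = TRUE)
    if (!length(gp)) {
      stop("fit for '", nm, "' has no group-by-period interaction terms")
    }
    se_all <- rep(NA_real_, length(b))
    se_all[!is.na(b)] <- sqrt(diag(fit$vcov))
    parse <- regmatches(
      gp, regexec("^group([a-z]+)\\.([a-z]+):(before|after)$", gp)
    )
    adjusted <- isTRUE(attr(fit, "adjusted"))
    for (period in c("before", "after")) {
      rows[[length(rows) + 1]] <- data.frame(
        outcome = nm, mental = "none", iq = "average", period = period,
        hrr = 1, lower = NA_real_, upper = NA_real_, p = NA_real_,
        reference = TRUE, adjusted = adjusted
      )
    }
    for (nm_cell in attr(fit, "empty_cells") %||% character(0)) {
      pieces <- regmatches(
        nm_cell, regexec("^group([a-z]+)\\.([a-z]+):(before|after)$", nm_cell)
      )[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        outcome = nm, mental = pieces[3], iq = pieces[2],
        period = pieces[4], hrr = NA_real_, lower = NA_real_,
        upper = NA_real_, p = NA_real_, reference = FALSE,
        adjusted = adjusted
      )
    }
    for (i in seq_along(gp)) {
      est <- b[gp[i]]
      se <- se_all[match(gp[i], names(b))]
      pieces <- parse[[i]]
      rows[[length(rows) + 1]] <- data.frame(
        outcome = nm, mental = pieces[3], iq = pieces[2],
        period = pieces[4],
        hrr = exp(unname(est)),
        lower = exp(unname(est) - z * se),
        upper = exp(unname(est) + z * se),
        p = 2 * stats::pnorm(-abs(unname(est) / se)),
        reference = FALSE, adjusted = adjusted
      )
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(
    match(out$outcome, unique(out$outcome)),
    match(out$mental, c("none", "problems")),
    match(out$iq, c("high", "average", "low")),
    match(out$period, c("before", "after"))
  )
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hrr_table", "data.frame"), level = level)
}

#' @export
print.hrr_table <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Hazard rate ratios (%g%% Wald CIs)%s:\n",
    100 * attr(x, "level"),
    if (any(x$adjusted)) ", adjusted" else ""
  ))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
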