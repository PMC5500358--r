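#' Nelson-Aalen cumulative transition intensities
#'
#' Estimates the cumulative transition intensity for every pair of states
#' j != k by the counting-process Nelson-Aalen estimator
#' \deqn{\hat H_{jk}(t) = \sum_{T_s \le t} n_{jk}(T_s) / Y_j(T_s),}
#' where `n_jk(T_s)` is the number of j-to-k events at the event time `T_s`
#' (ties aggregated) and `Y_j(T_s)` the number of persons at risk in state
#' j at `T_s`. The variance increments are `n_jk(T_s) / Y_j(T_s)^2`. Risk
#' sets use left limits: a person transitioning at `T_s` is counted at risk
#' in the origin state at `T_s`, and a person with delayed entry at `T_s`
#' is not yet at risk. Same-state re-episode events carry no intensity and
#' are ignored here.
#'
#' @param processed an `msm_process` object from [episodes_to_process()].
#' @return An object of class `msna`: list with `times` (sorted distinct
#'   event times), `inc` (data frame `time_id`, `time`, `from`, `to`, `n`,
#'   `atrisk`, `dh`, `dvar`), the `space`, person count and observed age
#'   `range`.
#' @seealso [aalen_johansen()], [occupation_probabilities()],
#'   [cumulative_intensity()]
#' @export
nelson_aalen <- function(processed) {
  stopifnot(inherits(processed, "msm_process"))
  space <- processed$space
  ev <- processed$events
  ev <- ev[ev$from != ev$to, , drop = FALSE]
  iv <- processed$intervals

  if (nrow(ev)) {
    times <- sort(unique(ev$time))
    tid <- match(ev$time, times)
    key <- paste(tid, ev$from, ev$to)
    first <- !duplicated(key)
    n <- as.integer(table(factor(key, levels = key[first])))
    inc <- data.frame(
      time_id = tid[first], time = ev$time[first],
      from = ev$from[first], to = ev$to[first], n = n
    )
    inc <- inc[order(inc$time_id, inc$from, inc$to), , drop = FALSE]
    rownames(inc) <- NULL

    # Y_j(t) = #{entry < t} - #{exit < t} among intervals in state j
    atrisk <- integer(nrow(inc))
    for (j in unique(inc$from)) {
      rows <- which(inc$from == j)
      ent <- sort(iv$entry[iv$state == j])
      ext <- sort(iv$exit[iv$state == j])
      tt <- inc$time[rows]
      atrisk[rows] <- findInterval(tt, ent, left.open = TRUE) -
        findInterval(tt, ext, left.open = TRUE)
    }
    if (any(atrisk < inc$n)) {
      stop("event with empty or deficient risk set; inconsistent input")
    }
    inc$atrisk <- atrisk
    inc$dh <- inc$n / inc$atrisk
    inc$dvar <- inc$n / inc$atrisk^2
  } else {
    times <- numeric(0)
    inc <- data.frame(
      time_id = integer(0), time = numeric(0), from = integer(0),
      to = integer(0), n = integer(0), atrisk = integer(0),
      dh = numeric(0), dvar = numeric(0)
    )
  }

  structure(
    list(
      times = times, inc = inc, space = space,
      n_persons = processed$n_persons,
      range = c(
        min(processed$windows$entry_age),
        max(processed$windows$exit_age)
      )
    ),
    class = "msna"
  )
}

#' @export
print.msna <- function(x, ...) {
  cat(sprintf(
    "<msna> Nelson-Aalen fit: %d persons, %d event times, %d transition pairs\n",
    x$n_persons, length(x$times),
    nrow(unique(x$inc[c("from", "to")]))
  ))
  cat(sprintf(
    "  observed age range [%.2f, %.2f]\n", x$range[1], x$range[2]
  ))
  invisible(x)
}

#' @export
summary.msna <- function(object, ...) {
  ci <- cumulative_intensity(object)
  if (nrow(ci)) {
    last <- do.call(rbind, lapply(
      split(ci, paste(ci$from, ci$to)),
      function(d) d[which.max(d$time), ]
    ))
    last <- last[order(last$from, last$to), , drop = FALSE]
    rownames(last) <- NULL
  } else {
    last <- ci
  }
  structure(
    list(fit = object, final = last),
    class = "summary.msna"
  )
}

#' @export
print.summary.msna <- function(x, ...) {
  print(x$fit)
  cat("Cumulative intensities at the last event time per pair:\n")
  f <- x$final
  if (nrow(f)) {
    f$se <- sqrt(f$var)
    print(f[c("from", "to", "time", "H", "se", "n_events")],
      row.names = FALSE, digits = 4
    )
  }
  invisible(x)
}

#' Cumulative Nelson-Aalen step functions
#'
#' @param object an `msna` fit.
#' @return A data frame with one row per (pair, event time): `time`,
#'   `from`, `to`, increment `dh`, cumulative `H`, cumulative `var`,
#'   and `n_events`.
#' @export
cumulative_intensity <- function(object) {
  stopifnot(inherits(object, "msna"))
  inc <- object$inc
  if (!nrow(inc)) {
    return(data.frame(
      time = numeric(0), from = integer(0), to = integer(0),
      dh = numeric(0), H = numeric(0), var = numeric(0),
      n_events = integer(0)
    ))
  }
  o <- order(inc$from, inc$to, inc$time_id)
  inc <- inc[o, , drop = FALSE]
  grp <- cumsum(!duplicated(inc[c("from", "to")]))
  H <- stats::ave(inc$dh, grp, FUN = cumsum)
  V <- stats::ave(inc$dvar, grp, FUN = cumsum)
  ne <- stats::ave(inc$n, grp, FUN = cumsum)
  data.frame(
    time = inc$time, from = inc$from, to = inc$to,
    dh = inc$dh, H = H, var = V, n_events = as.integer(ne)
  )
}

#' @export
plot.msna <- function(x, pairs = NULL, ...) {
  ci <- cumulative_intensity(x)
  if (!nrow(ci)) {
    stop("no events to plot")
  }
  ci$pair <- paste0(ci$from, "→", ci$to)
  if (!is.null(pairs)) ci <- ci[ci$pair %in% pairs, , drop = FALSE]
  sp <- split(ci, ci$pair)
  cols <- grDevices::hcl.colors(length(sp), "Dark 3")
  graphics::plot(
    range(ci$time), range(0, ci$H),
    type = "n", xlab = "age (years)",
    ylab = "cumulative intensity", ...
  )
  for (i in seq_along(sp)) {
    d <- sp[[i]]
    graphics::lines(
      stats::stepfun(d$time, c(0, d$H)),
      do.points = FALSE, col = cols[i]
    )
  }
  graphics::legend("topleft", legend = names(sp), col = cols, lty = 1,
    cex = 0.7, bty = "n")
  invisible(x)
}
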