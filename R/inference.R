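#' Perturb Nelson-Aalen increments
#'
#' Draws one replicate of the cumulative-intensity increments by adding
#' independent mean-zero normal noise with the estimated increment
#' variances: each increment is replaced by
#' `max(0, dH + N(0, dvar))`, independently across transition pairs and
#' event times. Negative draws are truncated at zero so every perturbed
#' increment remains a valid intensity mass; if the perturbed increments
#' out of one state at one time sum to more than one, the row is rescaled
#' to one so downstream probabilities stay in `[0, 1]`.
#'
#' @param H an `msna` fit.
#' @param seed optional integer seed for reproducibility.
#' @return An `msna` object with perturbed `dh` (attribute
#'   `perturbed = TRUE`).
#' @export
perturb_intensities <- function(H, seed = NULL) {
  stopifnot(inherits(H, "msna"))
  if (!is.null(seed)) set.seed(seed)
  draws <- perturb_draws(H, 1)
  H$inc$dh <- draws[, 1]
  attr(H, "perturbed") <- TRUE
  H
}

# matrix of B independent perturbed increment vectors (rows follow H$inc)
perturb_draws <- function(H, B) {
  inc <- H$inc
  m <- nrow(inc)
  if (!m) {
    return(matrix(numeric(0), 0, B))
  }
  draws <- matrix(
    stats::rnorm(m * B, mean = inc$dh, sd = sqrt(inc$dvar)), m, B
  )
  draws[draws < 0] <- 0
  # rescale any (time, from) row whose mass exceeds one
  g <- match(
    paste(inc$time_id, inc$from),
    unique(paste(inc$time_id, inc$from))
  )
  sums <- rowsum(draws, g)
  over <- sums > 1
  if (any(over)) {
    fac <- matrix(1, nrow(sums), B)
    fac[over] <- 1 / sums[over]
    draws <- draws * fac[g, , drop = FALSE]
  }
  draws
}

#' Simulation-based confidence intervals
#'
#' Confidence intervals for state-occupation probabilities or restricted
#' mean times in state, obtained by recomputing the functional on `B`
#' perturbed replicates of the Nelson-Aalen increments (see
#' [perturb_intensities()]) and taking empirical percentile (default) or
#' normal-theory bounds across replicates. The point estimate is always
#' the unperturbed one.
#'
#' @param H an `msna` fit.
#' @param functional `"restricted_mean"` or `"occupation"`.
#' @param B number of replicates (default 1000).
#' @param level confidence level in (0, 1).
#' @param seed optional integer seed.
#' @param origin_age origin age for the occupation curve.
#' @param weights initial distribution over states (default: all mass on
#'   state 1).
#' @param t0,t1 integration window for the restricted-mean functional.
#' @param grid ages at which the occupation functional is evaluated.
#' @param type `"percentile"` for empirical quantile bounds,
#'   `"normal"` for point +/- z * replicate SD.
#' @return A data frame of class `simulation_ci` with columns `state`
#'   (and `age` for the occupation functional), `estimate`, `lower`,
#'   `upper`; attributes `level`, `B`, `type`.
#' @export
simulation_ci <- function(H, functional = c("restricted_mean", "occupation"),
                          B = 1000, level = 0.95, seed = NULL,
                          origin_age = NULL, weights = NULL,
                          t0 = NULL, t1 = NULL, grid = NULL,
                          type = c("percentile", "normal")) {
  stopifnot(inherits(H, "msna"))
  functional <- match.arg(functional)
  type <- match.arg(type)
  if (B < 2) stop("B must be at least 2")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  S <- n_states(H$space)
  if (is.null(origin_age)) origin_age <- H$range[1]
  if (is.null(weights)) weights <- c(1, rep(0, S - 1))

  if (functional == "restricted_mean") {
    if (is.null(t0)) t0 <- origin_age
    if (is.null(t1)) t1 <- H$range[2]
    point <- restricted_mean_times(
      occupation_probabilities(H, origin_age, weights), t0, t1
    )
    reps <- propagate_restricted(
      H, perturb_draws(H, B), weights, origin_age, t0, t1
    )
    est <- as.numeric(point)
    lab <- data.frame(state = H$space$labels)
  } else {
    if (is.null(grid)) {
      stop("the occupation functional needs a grid of ages")
    }
    curve <- occupation_probabilities(H, origin_age, weights, grid = grid)
    est <- as.vector(curve$Qgrid) # state-major after flatten below
    reps <- propagate_occupation(
      H, perturb_draws(H, B), weights, origin_age, grid
    )
    lab <- data.frame(
      state = rep(H$space$labels, each = length(grid)),
      age = rep(grid, S)
    )
    est <- as.vector(curve$Qgrid) # (age x state) column-major
  }

  alpha <- (1 - level) / 2
  if (type == "percentile") {
    qs <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
      names = FALSE, type = 7)
    lower <- qs[1, ]
    upper <- qs[2, ]
  } else {
    sds <- apply(reps, 2, stats::sd)
    z <- stats::qnorm(1 - alpha)
    lower <- est - z * sds
    upper <- est + z * sds
  }
  out <- cbind(lab, estimate = est, lower = lower, upper = upper)
  structure(out,
    class = c("simulation_ci", "data.frame"),
    level = level, B = B, type = type, functional = functional
  )
}

#' @export
print.simulation_ci <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Simulation-based %g%% CIs (%s, B = %d) for %s:\n",
    100 * attr(x, "level"), attr(x, "type"), attr(x, "B"),
    attr(x, "functional")
  ))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# Propagate B perturbed increment vectors through the product-limit
# recursion and integrate Q over [t0, t1]. Returns a B x S matrix of
# restricted means. Vectorised across replicates: Qb is B x S and each
# event time applies one matrix factor to all replicates at once.
propagate_restricted <- function(H, draws, weights, origin, t0, t1) {
  S <- n_states(H$space)
  B <- ncol(draws)
  Qb <- matrix(weights, B, S, byrow = TRUE)
  E <- matrix(0, B, S)
  sel <- which(H$times > origin & H$times <= t1)
  inc <- H$inc
  last <- t0
  if (length(sel)) {
    keep <- inc$time_id %in% sel
    rows_by_time <- split(which(keep), inc$time_id[keep])
    tvals <- H$times[sel]
    for (i in seq_along(rows_by_time)) {
      tm <- tvals[i]
      if (tm > t0) {
        E <- E + Qb * (tm - last)
        last <- tm
      }
      rows <- rows_by_time[[i]]
      if (length(rows) == 1L) {
        r <- rows
        d <- Qb[, inc$from[r]] * draws[r, ]
        Qb[, inc$to[r]] <- Qb[, inc$to[r]] + d
        Qb[, inc$from[r]] <- Qb[, inc$from[r]] - d
      } else {
        Q0 <- Qb
        for (r in rows) {
          d <- Q0[, inc$from[r]] * draws[r, ]
          Qb[, inc$to[r]] <- Qb[, inc$to[r]] + d
          Qb[, inc$from[r]] <- Qb[, inc$from[r]] - d
        }
      }
    }
  }
  E <- E + Qb * (t1 - last)
  colnames(E) <- H$space$labels
  E
}

# As above but records Q at the requested grid ages. Returns a
# B x (length(grid) * S) matrix, grid-major within state (matching
# as.vector of an (age x state) matrix).
propagate_occupation <- function(H, draws, weights, origin, grid) {
  S <- n_states(H$space)
  B <- ncol(draws)
  G <- length(grid)
  grid_o <- order(grid)
  gsorted <- grid[grid_o]
  Qb <- matrix(weights, B, S, byrow = TRUE)
  out <- array(0, dim = c(B, G, S))
  sel <- which(H$times > origin & H$times <= max(gsorted))
  inc <- H$inc
  gi <- 1L
  record_upto <- function(tm) {
    while (gi <= G && gsorted[gi] < tm) {
      out[, gi, ] <<- Qb
      gi <<- gi + 1L
    }
  }
  if (length(sel)) {
    keep <- inc$time_id %in% sel
    rows_by_time <- split(which(keep), inc$time_id[keep])
    tvals <- H$times[sel]
    for (i in seq_along(rows_by_time)) {
      record_upto(tvals[i])
      rows <- rows_by_time[[i]]
      if (length(rows) == 1L) {
        r <- rows
        d <- Qb[, inc$from[r]] * draws[r, ]
        Qb[, inc$to[r]] <- Qb[, inc$to[r]] + d
        Qb[, inc$from[r]] <- Qb[, inc$from[r]] - d
      } else {
        Q0 <- Qb
        for (r in rows) {
          d <- Q0[, inc$from[r]] * draws[r, ]
          Qb[, inc$to[r]] <- Qb[, inc$to[r]] + d
          Qb[, inc$from[r]] <- Qb[, inc$from[r]] - d
        }
      }
    }
  }
  record_upto(Inf)
  # undo grid sorting, flatten to B x (G*S), grid-major within state
  out <- out[, order(grid_o), , drop = FALSE]
  dim(out) <- c(B, G * S)
  out
}
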