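#' Aalen-Johansen transition probability matrix
#'
#' Product-limit estimator of the matrix of transition probabilities
#' `P_jk(t1, t2) = P(X(t2) = k | X(t1) = j)`:
#' \deqn{\hat P(t_1, t_2) = \prod_{t_1 < s \le t_2} (I + \Delta\hat H(s)),}
#' the product running over distinct event times in order, with the
#' diagonal of each increment matrix set to minus its row sum. All events
#' at one time enter through a single matrix factor, so simultaneous
#' transitions out of different states are handled in one step. The
#' estimator assumes the multi-state process is Markovian. Every row of
#' the result sums to one.
#'
#' @param H an `msna` fit from [nelson_aalen()].
#' @param t1,t2 ages with `t1 <= t2`.
#' @return A matrix of class `transition_probability` over the state
#'   space, with attributes `t1` and `t2`.
#' @examples
#' # t1 == t2 gives the identity: the empty product
#' @export
aalen_johansen <- function(H, t1, t2) {
  stopifnot(inherits(H, "msna"))
  if (t1 > t2) stop("t1 must not exceed t2")
  S <- n_states(H$space)
  P <- diag(S)
  sel <- which(H$times > t1 & H$times <= t2)
  if (length(sel)) {
    inc <- H$inc[H$inc$time_id %in% sel, , drop = FALSE]
    for (rows in split(seq_len(nrow(inc)), inc$time_id)) {
      M <- diag(S)
      f <- inc$from[rows]
      k <- inc$to[rows]
      dh <- inc$dh[rows]
      M[cbind(f, k)] <- M[cbind(f, k)] + dh
      rs <- rowsum(dh, f)
      jj <- as.integer(rownames(rs))
      M[cbind(jj, jj)] <- M[cbind(jj, jj)] - rs[, 1]
      if (any(diag(M) < 0)) {
        stop(
          "negative diagonal in a product factor: more simultaneous ",
          "events than persons at risk (tie-handling violation)"
        )
      }
      P <- P %*% M
    }
  }
  dimnames(P) <- list(H$space$labels, H$space$labels)
  structure(P, class = c("transition_probability", "matrix"),
    t1 = t1, t2 = t2)
}

#' @export
print.transition_probability <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Aalen-Johansen transition probabilities P(%.2f, %.2f)\n",
    attr(x, "t1"), attr(x, "t2")
  ))
  m <- unclass(x)
  attr(m, "t1") <- attr(m, "t2") <- NULL
  print(round(m, digits))
  invisible(x)
}

#' State-occupation probabilities
#'
#' The unconditional probability of occupying each state at age t,
#' estimated as the initial-distribution-weighted sum of Aalen-Johansen
#' transition probabilities from the origin age:
#' \deqn{\hat Q_k(t) = \sum_j W_j \hat P_{jk}(t_0, t).}
#' The default weights put all mass on employment at the origin age
#' (everyone employed, or in education, at age 20), so the curves start at
#' 100 percent employment. `Q` is carried as a right-continuous step
#' function changing at event times; requested grid ages are read off that
#' step function exactly.
#'
#' @param H an `msna` fit.
#' @param origin_age age at which the weights apply.
#' @param weights probability vector over states; default point mass on
#'   state 1.
#' @param grid optional ages at which to tabulate the curves.
#' @return An object of class `occupation_curve`: list with `step_times`
#'   (origin plus event times), matrix `Q` (rows = step times), `grid` and
#'   `Qgrid` when a grid was supplied, `weights`, `origin` and `space`.
#' @export
occupation_probabilities <- function(H, origin_age, weights = NULL,
                                     grid = NULL) {
  stopifnot(inherits(H, "msna"))
  S <- n_states(H$space)
  if (is.null(weights)) {
    weights <- c(1, rep(0, S - 1))
  }
  if (length(weights) != S || any(weights < 0) ||
    abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be a probability vector over the states")
  }
  sel <- which(H$times > origin_age)
  times <- H$times[sel]
  Q <- matrix(0, length(sel) + 1, S)
  Q[1, ] <- weights
  q <- weights
  if (length(sel)) {
    inc <- H$inc[H$inc$time_id %in% sel, , drop = FALSE]
    rows_by_time <- split(seq_len(nrow(inc)), inc$time_id)
    for (i in seq_along(rows_by_time)) {
      rows <- rows_by_time[[i]]
      q0 <- q
      for (r in rows) {
        d <- q0[inc$from[r]] * inc$dh[r]
        q[inc$to[r]] <- q[inc$to[r]] + d
        q[inc$from[r]] <- q[inc$from[r]] - d
      }
      Q[i + 1, ] <- q
    }
  }
  colnames(Q) <- H$space$labels
  out <- list(
    step_times = c(origin_age, times), Q = Q,
    weights = weights, origin = origin_age, space = H$space
  )
  if (!is.null(grid)) {
    out$grid <- grid
    out$Qgrid <- eval_step(out, grid)
  }
  class(out) <- "occupation_curve"
  out
}

# right-continuous step evaluation of an occupation curve
eval_step <- function(curve, at) {
  idx <- findInterval(at, curve$step_times)
  idx[idx < 1] <- 1 # before the origin: initial weights
  m <- curve$Q[idx, , drop = FALSE]
  rownames(m) <- format(at)
  m
}

#' @export
print.occupation_curve <- function(x, ...) {
  cat(sprintf(
    "<occupation_curve> %d states, origin age %.2f, %d step times\n",
    ncol(x$Q), x$origin, length(x$step_times)
  ))
  last <- x$Q[nrow(x$Q), ]
  cat("occupation at last event time:\n")
  print(round(last, 4))
  invisible(x)
}

#' @export
plot.occupation_curve <- function(x, states = NULL, ...) {
  S <- ncol(x$Q)
  sel <- if (is.null(states)) seq_len(S) else states
  cols <- grDevices::hcl.colors(length(sel), "Dark 3")
  graphics::matplot(
    x$step_times, x$Q[, sel, drop = FALSE],
    type = "s", lty = 1, col = cols,
    xlab = "age (years)", ylab = "state occupation probability", ...
  )
  graphics::legend("right", legend = x$space$labels[sel], col = cols,
    lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.occupation_curve <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  if (!is.null(x$grid)) {
    ages <- x$grid
    Q <- x$Qgrid
  } else {
    ages <- x$step_times
    Q <- x$Q
  }
  data.frame(
    state = rep(x$space$labels, each = length(ages)),
    age = rep(ages, ncol(Q)),
    estimate = as.vector(Q)
  )
}

#' Restricted mean times in state
#'
#' Expected number of years spent in each state over an age window,
#' obtained by integrating the state-occupation probabilities:
#' \deqn{\hat E_k = \int_{t_0}^{t_1} \hat Q_k(u)\,du.}
#' Because `Q` is piecewise constant, the integral is an exact sum of
#' rectangle areas; the state means add up to `t1 - t0` by construction.
#'
#' @param Q an `occupation_curve`.
#' @param t0,t1 integration limits, `t0 < t1`, with `t0` at or after the
#'   curve's origin.
#' @return A named numeric vector of class `restricted_means` with
#'   attributes `t0`, `t1`.
#' @examples
#' # a curve constant at 100% employment over [20, 45] gives 25 years
#' @export
restricted_mean_times <- function(Q, t0, t1) {
  stopifnot(inherits(Q, "occupation_curve"))
  if (t0 >= t1) stop("t0 must be smaller than t1")
  if (t0 < Q$origin - 1e-9) {
    stop("t0 lies before the origin of the occupation curve")
  }
  inner <- Q$step_times[Q$step_times > t0 & Q$step_times < t1]
  breaks <- c(t0, inner, t1)
  vals <- eval_step(Q, breaks[-length(breaks)])
  E <- colSums(vals * diff(breaks))
  names(E) <- Q$space$labels
  structure(E, class = "restricted_means", t0 = t0, t1 = t1)
}

#' @export
print.restricted_means <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Restricted mean years in state over ages [%g, %g]:\n",
    attr(x, "t0"), attr(x, "t1")
  ))
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(round(v, digits))
  invisible(x)
}
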