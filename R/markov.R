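#' Per-cycle transition schedule for the three-state model
#'
#' Builds the per-cycle transition probabilities of the
#' PFS / progressed (DP) / dead cohort model from two fitted Weibull
#' curves. The PFS curve supplies the probability of leaving PFS in each
#' cycle; the OS curve supplies the probability of dying, applied
#' identically to both alive states; progression is the remainder,
#' floored at zero:
#' `p_pfs_to_dp(t) = max(0, p_pfs_exit(t) - p_death(t))`.
#'
#' @param pfs,os [weibull_params()] for progression-free and overall
#'   survival (day scale).
#' @param n_cycles Number of cycles, `>= 1`.
#' @param cycle_length Cycle length in days (default 21).
#' @return An object of class `transition_schedule`: a data frame with
#'   columns `cycle`, `p_pfs_exit`, `p_death`, `p_pfs_to_dp` and a
#'   `cycle_length` attribute.
#' @export
transition_schedule <- function(pfs, os, n_cycles, cycle_length = 21) {
  stopifnot(inherits(pfs, "weibull_params"), inherits(os, "weibull_params"))
  if (n_cycles < 1 || n_cycles != floor(n_cycles)) {
    stop("`n_cycles` must be an integer >= 1", call. = FALSE)
  }
  cyc <- seq_len(n_cycles)
  p_exit <- cycle_transition_prob(pfs, cyc, cycle_length)
  p_death <- cycle_transition_prob(os, cyc, cycle_length)
  out <- data.frame(
    cycle = cyc,
    p_pfs_exit = p_exit,
    p_death = p_death,
    p_pfs_to_dp = pmax(0, p_exit - p_death)
  )
  attr(out, "cycle_length") <- cycle_length
  class(out) <- c("transition_schedule", "data.frame")
  out
}

#' Assemble a transition schedule from raw probability series
#'
#' Lower-level constructor used by tests and by callers with externally
#' derived probabilities.
#'
#' @param p_pfs_exit,p_death Numeric vectors of equal length with values
#'   in `[0, 1]`.
#' @inheritParams transition_schedule
#' @export
schedule_from_probs <- function(p_pfs_exit, p_death, cycle_length = 21) {
  stopifnot(length(p_pfs_exit) == length(p_death), length(p_pfs_exit) >= 1L)
  if (any(p_pfs_exit < 0 | p_pfs_exit > 1) || any(p_death < 0 | p_death > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(
    cycle = seq_along(p_pfs_exit),
    p_pfs_exit = p_pfs_exit,
    p_death = p_death,
    p_pfs_to_dp = pmax(0, p_pfs_exit - p_death)
  )
  attr(out, "cycle_length") <- cycle_length
  class(out) <- c("transition_schedule", "data.frame")
  out
}

#' Run the three-state Markov cohort trace
#'
#' Advances a cohort that starts fully progression-free through the
#' schedule. States are mutually exclusive and transitions one-way
#' (PFS -> DP -> dead; PFS -> dead); death is absorbing. The recursion
#' per cycle `t` is
#' \deqn{PFS(t) = PFS(t-1)(1 - p_{dp}(t) - p_{death}(t))}
#' \deqn{DP(t) = DP(t-1)(1 - p_{death}(t)) + PFS(t-1)\,p_{dp}(t)}
#' \deqn{Death(t) = 1 - PFS(t) - DP(t).}
#'
#' @param schedule A [transition_schedule()].
#' @return An object of class `cohort_trace`: a data frame with columns
#'   `cycle` (0..n), `pfs`, `dp`, `death`; rows sum to 1, `death` is
#'   non-decreasing and `pfs` non-increasing. The generating schedule is
#'   attached as attribute `schedule`.
#' @export
run_cohort <- function(schedule) {
  stopifnot(inherits(schedule, "transition_schedule"))
  n <- nrow(schedule)
  pfs <- dp <- death <- numeric(n + 1L)
  pfs[1L] <- 1
  for (t in seq_len(n)) {
    p_dp <- schedule$p_pfs_to_dp[t]
    p_de <- schedule$p_death[t]
    stay <- 1 - p_dp - p_de
    if (stay < -1e-12) {
      stop(sprintf("cycle %d: p_pfs_to_dp + p_death exceeds 1", t), call. = FALSE)
    }
    pfs[t + 1L] <- pfs[t] * max(stay, 0)
    dp[t + 1L] <- dp[t] * (1 - p_de) + pfs[t] * p_dp
    death[t + 1L] <- 1 - pfs[t + 1L] - dp[t + 1L]
    if (death[t + 1L] < -1e-9) {
      stop("internal consistency error: negative death occupancy", call. = FALSE)
    }
  }
  out <- data.frame(cycle = 0:n, pfs = pfs, dp = dp, death = death)
  attr(out, "cycle_length") <- attr(schedule, "cycle_length")
  attr(out, "schedule") <- schedule
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x) - 1L
  cat(sprintf(
    "Cohort trace: %d cycles of %g days; final occupancy PFS %.4f / DP %.4f / dead %.4f\n",
    n, attr(x, "cycle_length"), x$pfs[n + 1L], x$dp[n + 1L], x$death[n + 1L]))
  invisible(x)
}

#' Median time spent in a state-membership set
#'
#' Finds the time at which a membership series (PFS occupancy, or the
#' alive fraction PFS + DP) crosses 0.5, by linear interpolation between
#' the bracketing cycle boundaries, and converts days to months.
#'
#' @param trace A [cohort_trace()].
#' @param state `"pfs"` for progression-free membership or `"alive"` for
#'   PFS + DP membership.
#' @param days_per_month Conversion constant (default 30.44).
#' @return Median in months, or `NA` with a warning of class
#'   `markovcua_median_not_reached` when the series never falls to 0.5
#'   within the horizon.
#' @export
median_state_time <- function(trace, state = c("pfs", "alive"),
                              days_per_month = 30.44) {
  stopifnot(inherits(trace, "cohort_trace"))
  state <- match.arg(state)
  series <- if (state == "pfs") trace$pfs else trace$pfs + trace$dp
  cl <- attr(trace, "cycle_length")
  below <- which(series < 0.5)
  if (length(below) == 0L) {
    warning(structure(
      class = c("markovcua_median_not_reached", "warning", "condition"),
      list(message = sprintf("median not reached: %s membership stays above 0.5", state),
           call = sys.call())))
    return(NA_real_)
  }
  i <- below[1L]
  if (i == 1L) return(0)  # degenerate: starts below 0.5
  lo <- series[i - 1L]
  hi <- series[i]
  if (lo == 0.5 || isTRUE(all.equal(lo, 0.5, tolerance = 1e-12))) {
    cross_cycles <- trace$cycle[i - 1L]
  } else {
    frac <- (lo - 0.5) / (lo - hi)
    cross_cycles <- trace$cycle[i - 1L] + frac
  }
  cross_cycles * cl / days_per_month
}
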