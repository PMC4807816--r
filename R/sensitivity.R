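#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies one parameter at a time to each bound of its range, re-runs
#' the full two-arm pipeline at each bound with everything else at base,
#' and records the incremental cost-utility ratio at the low and high
#' bound. Results are sorted by the absolute ICUR span for tornado
#' rendering. Bounds are validated against each parameter's type
#' invariant before any model run. As in the probabilistic analysis,
#' per-event ADR utility decrements are floored at zero when a low
#' `u_pfs` bound falls below an ADR utility. When a bound flips the sign of the
#' incremental QALYs the ratio is discontinuous across the range; the
#' row is flagged `unstable` and its span should be read with care.
#'
#' @param cfg A `model_config`.
#' @param ranges Named list of `c(low, high)` ranges; defaults to
#'   `cfg$owsa`. Names follow [get_config_param()].
#' @return An object of class `owsa_result`: a data frame with columns
#'   `parameter`, `low`, `high`, `icur_low`, `icur_high`, `width`,
#'   `unstable`, sorted by `width` descending, with the base-case ICUR
#'   attached as attribute `base_icur`.
#' @export
one_way_sa <- function(cfg, ranges = cfg$owsa) {
  stopifnot(inherits(cfg, "model_config"))
  if (is.null(ranges) || length(ranges) == 0L) {
    stop("no one-way ranges supplied", call. = FALSE)
  }
  # validate every bound before running anything
  for (nm in names(ranges)) {
    r <- as.numeric(ranges[[nm]])
    if (length(r) != 2L || r[1L] > r[2L]) {
      stop(sprintf("range for `%s` must be c(low, high)", nm), call. = FALSE)
    }
    for (v in r) invisible(set_config_param(cfg, nm, v))
  }
  base <- compare_strategies(cfg, adr_strict = FALSE)
  icur_at <- function(nm, v) {
    res <- compare_strategies(set_config_param(cfg, nm, v), adr_strict = FALSE)
    c(icur = res$icur$icur, dq = res$icur$delta_qaly)
  }
  rows <- lapply(names(ranges), function(nm) {
    r <- as.numeric(ranges[[nm]])
    lo <- icur_at(nm, r[1L])
    hi <- icur_at(nm, r[2L])
    data.frame(parameter = nm, low = r[1L], high = r[2L],
               icur_low = lo[["icur"]], icur_high = hi[["icur"]],
               width = abs(hi[["icur"]] - lo[["icur"]]),
               unstable = sign(lo[["dq"]]) != sign(hi[["dq"]]) ||
                 lo[["dq"]] == 0 || hi[["dq"]] == 0)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icur") <- base$icur$icur
  class(out) <- c("owsa_result", "data.frame")
  out
}

# ---- PSA distributions --------------------------------------------------

# Lognormal matched so the base case is the mean and [lo, hi] spans ~95%
# of the mass (sigma from the log-range); degenerate ranges are fixed.
psa_draw_lognormal <- function(n, base, lo, hi) {
  if (hi <= lo || lo <= 0) return(rep(base, n))
  sigma <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  mu <- log(base) - sigma^2 / 2
  stats::rlnorm(n, meanlog = mu, sdlog = sigma)
}

# Beta matched by moments: mean = base, sd = range/3.92.
psa_draw_beta <- function(n, base, lo, hi) {
  if (hi <= lo || base <= 0 || base >= 1) return(rep(base, n))
  v <- ((hi - lo) / (2 * stats::qnorm(0.975)))^2
  v <- min(v, base * (1 - base) * 0.99)
  k <- base * (1 - base) / v - 1
  stats::rbeta(n, shape1 = base * k, shape2 = (1 - base) * k)
}

#' Distribution assignment for the probabilistic sensitivity analysis
#'
#' Costs are sampled from lognormal distributions, utilities and ADR
#' probabilities from beta distributions, each moment-matched so the
#' base case is the mean and the one-way range spans roughly 95% of the
#' mass. The discount rate is held fixed. Parameters with degenerate
#' ranges stay at base.
#'
#' @param cfg A `model_config`.
#' @return Data frame `parameter`, `dist`, `base`, `low`, `high`.
#' @export
psa_distributions <- function(cfg) {
  ranges <- cfg$owsa
  rows <- lapply(names(ranges), function(nm) {
    r <- as.numeric(ranges[[nm]])
    root <- strsplit(nm, ".", fixed = TRUE)[[1L]][1L]
    dist <- switch(root,
      discount_annual = "fixed",
      u_pfs = , u_dp = , adr_prob = "beta",
      "lognormal")
    if (r[1L] == r[2L]) dist <- "fixed"
    data.frame(parameter = nm, dist = dist,
               base = get_config_param(cfg, nm), low = r[1L], high = r[2L])
  })
  do.call(rbind, rows)
}

#' Probabilistic sensitivity analysis
#'
#' Jointly redraws every uncertain parameter per iteration, re-runs the
#' two-arm pipeline, and stores the incremental cost and QALYs of the
#' first (new) arm versus the second. Reproducible given `seed`; the
#' discount rate stays fixed at its base value. Per-draw ADR utility
#' decrements are floored at zero when a redrawn `u_pfs` falls below an
#' ADR utility (see [expected_adr_adjustment()]).
#'
#' @param cfg A `model_config`.
#' @param n Number of draws (default `cfg$psa$n`).
#' @param seed Integer seed (default `cfg$psa$seed`).
#' @param distributions Distribution table from [psa_distributions()].
#' @return An object of class `psa_result`: list with `samples` (data
#'   frame `draw`, `delta_cost`, `delta_qaly`), `n`, `seed`,
#'   `base_delta_cost`, `base_delta_qaly`.
#' @export
run_psa <- function(cfg, n = cfg$psa$n, seed = cfg$psa$seed,
                    distributions = psa_distributions(cfg)) {
  stopifnot(inherits(cfg, "model_config"), n >= 1)
  base <- compare_strategies(cfg)
  set.seed(seed)
  active <- distributions[distributions$dist != "fixed", , drop = FALSE]
  draws <- matrix(NA_real_, nrow = n, ncol = nrow(active),
                  dimnames = list(NULL, active$parameter))
  for (j in seq_len(nrow(active))) {
    d <- active[j, ]
    draws[, j] <- switch(d$dist,
      lognormal = psa_draw_lognormal(n, d$base, d$low, d$high),
      beta = psa_draw_beta(n, d$base, d$low, d$high),
      stop(sprintf("unknown distribution `%s`", d$dist), call. = FALSE))
  }
  dc <- dq <- numeric(n)
  for (i in seq_len(n)) {
    cfg_i <- cfg
    for (nm in colnames(draws)) {
      cfg_i <- set_config_param(cfg_i, nm, draws[i, nm])
    }
    res <- compare_strategies(cfg_i, adr_strict = FALSE)
    dc[i] <- res$icur$delta_cost
    dq[i] <- res$icur$delta_qaly
  }
  structure(
    list(samples = data.frame(draw = seq_len(n), delta_cost = dc, delta_qaly = dq),
         n = n, seed = seed,
         base_delta_cost = base$icur$delta_cost,
         base_delta_qaly = base$icur$delta_qaly),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  dom <- mean(x$samples$delta_cost < 0 & x$samples$delta_qaly > 0)
  cat(sprintf("PSA: %d draws (seed %s); mean delta cost $%.2f, mean delta QALY %.4f; %.1f%% dominant\n",
              x$n, format(x$seed), mean(x$samples$delta_cost),
              mean(x$samples$delta_qaly), 100 * dom))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `w`, the fraction of PSA samples
#' in which the new strategy has strictly positive incremental net
#' monetary benefit `w * delta_QALY - delta_cost` (ties count as not
#' preferred).
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Strictly increasing vector of willingness-to-pay
#'   values (USD/QALY).
#' @return An object of class `ceac_curve`: data frame `wtp`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"), length(wtp_grid) >= 1)
  if (any(diff(wtp_grid) <= 0) && length(wtp_grid) > 1L) {
    stop("`wtp_grid` must be strictly increasing", call. = FALSE)
  }
  s <- psa$samples
  prob <- vapply(wtp_grid, function(w) {
    mean(w * s$delta_qaly - s$delta_cost > 0)
  }, numeric(1))
  out <- data.frame(wtp = wtp_grid, probability = prob)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Default willingness-to-pay grid
#'
#' Even grid from 0 to `max_gdp_multiple` times per-capita GDP
#' (the conventional affordability anchor), `points` values.
#'
#' @param cfg A `model_config`.
#' @export
wtp_grid <- function(cfg) {
  seq(0, cfg$wtp$max_gdp_multiple * cfg$gdp_per_capita,
      length.out = cfg$wtp$points)
}
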