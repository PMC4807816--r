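#' Economic parameters for one treatment arm
#'
#' Costs are 2014 US dollars. Drug cost is charged per 21-day cycle
#' while the cohort is progression-free, up to and including cycle
#' `free_drug_after_cycle` — beyond that the manufacturer assistance
#' programme supplies the drug free of charge. After progression the
#' cohort receives docetaxel (`docetaxel_ampules_per_cycle` ampules per
#' cycle, for `docetaxel_cycles` cycles after entering DP) plus routine
#' follow-up; afterwards follow-up only. Death carries neither cost nor
#' utility.
#'
#' @param arm Arm identifier (e.g. `"icotinib"`).
#' @param drug_cost_per_cycle USD per 21-day cycle while charged.
#' @param free_drug_after_cycle Last charged cycle (9 for icotinib's
#'   6-month programme, 7 for gefitinib's 5-month programme).
#' @param followup_cost_per_cycle USD, routine follow-up in DP.
#' @param docetaxel_ampule_cost USD per 20 mg ampule.
#' @param docetaxel_ampules_per_cycle Ampules per salvage cycle.
#' @param docetaxel_cycles Number of salvage cycles after progression.
#' @param adr_events Data frame with columns `name`, `probability`,
#'   `cost`, `utility`: serious adverse-drug-reaction events for the
#'   arm, treated as one-off expectations at model entry.
#' @param u_pfs,u_dp Health-state utilities in `[0, 1]`.
#' @param discount_annual Annual discount rate in `[0, 0.08]`.
#' @param cycle_length Cycle length in days.
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(arm,
                        drug_cost_per_cycle,
                        free_drug_after_cycle,
                        followup_cost_per_cycle = 57.96,
                        docetaxel_ampule_cost = 108.72,
                        docetaxel_ampules_per_cycle = 6,
                        docetaxel_cycles = 6,
                        adr_events = data.frame(name = character(),
                                                probability = numeric(),
                                                cost = numeric(),
                                                utility = numeric()),
                        u_pfs = 0.673,
                        u_dp = 0.473,
                        discount_annual = 0.03,
                        cycle_length = 21) {
  costs <- c(drug_cost_per_cycle, followup_cost_per_cycle,
             docetaxel_ampule_cost, adr_events$cost)
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  utils_ <- c(u_pfs, u_dp, adr_events$utility)
  if (any(utils_ < 0 | utils_ > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(adr_events$probability < 0 | adr_events$probability > 1)) {
    stop("ADR probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (discount_annual < 0 || discount_annual > 0.08) {
    stop("`discount_annual` must lie in [0, 0.08]", call. = FALSE)
  }
  if (free_drug_after_cycle < 0) stop("`free_drug_after_cycle` must be >= 0", call. = FALSE)
  structure(
    list(arm = arm,
         drug_cost_per_cycle = drug_cost_per_cycle,
         free_drug_after_cycle = free_drug_after_cycle,
         followup_cost_per_cycle = followup_cost_per_cycle,
         docetaxel_ampule_cost = docetaxel_ampule_cost,
         docetaxel_ampules_per_cycle = docetaxel_ampules_per_cycle,
         docetaxel_cycles = docetaxel_cycles,
         adr_events = adr_events,
         u_pfs = u_pfs, u_dp = u_dp,
         discount_annual = discount_annual,
         cycle_length = cycle_length),
    class = "econ_params")
}

#' @export
print.econ_params <- function(x, ...) {
  cat(sprintf("Economic parameters [%s]: drug $%.2f/cycle (charged through cycle %d),\n",
              x$arm, x$drug_cost_per_cycle, x$free_drug_after_cycle))
  cat(sprintf("  DP: follow-up $%.2f + docetaxel %d x $%.2f for %d cycles; u = %.3f/%.3f; discount %.0f%%/yr\n",
              x$followup_cost_per_cycle, x$docetaxel_ampules_per_cycle,
              x$docetaxel_ampule_cost, x$docetaxel_cycles, x$u_pfs, x$u_dp,
              100 * x$discount_annual))
  invisible(x)
}

#' Per-state cost and utility weight for one cycle
#'
#' @param econ An [econ_params()].
#' @param cycle Calendar cycle index, `>= 1`.
#' @param cycles_since_progression For the DP state, the number of
#'   completed cycles since entering DP (0 = the cycle of entry).
#' @return A list with numeric vectors `cost` and `utility`, each named
#'   `pfs`, `dp`, `death`.
#' @export
cycle_reward <- function(econ, cycle, cycles_since_progression = 0) {
  stopifnot(inherits(econ, "econ_params"))
  if (cycle < 1) stop("`cycle` must be >= 1", call. = FALSE)
  drug <- if (cycle <= econ$free_drug_after_cycle) econ$drug_cost_per_cycle else 0
  doce <- if (cycles_since_progression < econ$docetaxel_cycles) {
    econ$docetaxel_ampules_per_cycle * econ$docetaxel_ampule_cost
  } else 0
  list(
    cost = c(pfs = drug, dp = econ$followup_cost_per_cycle + doce, death = 0),
    utility = c(pfs = econ$u_pfs, dp = econ$u_dp, death = 0)
  )
}

#' Expected one-off adverse-drug-reaction adjustment
#'
#' ADR events are rare one-off occurrences; their treatment cost and
#' quality-of-life impact are applied as expectations at model entry
#' (cycle 1): `cost = sum(p_i * cost_i)` and
#' `decrement = sum(p_i * (u_pfs - u_i))`, the expected drop of the
#' first-cycle utility weight.
#'
#' @param econ An [econ_params()].
#' @param strict When `TRUE` (default) an ADR utility above `u_pfs` is a
#'   validation error; when `FALSE` such events contribute zero
#'   decrement (used during probabilistic re-draws of `u_pfs`).
#' @return Named numeric vector `c(cost =, utility_decrement =)`.
#' @export
expected_adr_adjustment <- function(econ, strict = TRUE) {
  stopifnot(inherits(econ, "econ_params"))
  ev <- econ$adr_events
  if (nrow(ev) == 0L) return(c(cost = 0, utility_decrement = 0))
  dec <- econ$u_pfs - ev$utility
  if (any(dec < 0)) {
    if (strict) {
      stop("ADR utility exceeds u_pfs: decrement would be negative", call. = FALSE)
    }
    dec <- pmax(dec, 0)
  }
  c(cost = sum(ev$probability * ev$cost),
    utility_decrement = sum(ev$probability * dec))
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Rewards are assigned to end-of-cycle occupancy (no half-cycle
#' correction by default). The discount factor for cycle `t` is
#' `(1 + discount_annual)^(-t * cycle_length / 365.25)`. Docetaxel
#' costs are tracked by expected progression influx: the cohort entering
#' DP at cycle `s` receives docetaxel at cycles `s .. s + docetaxel_cycles - 1`
#' while surviving, follow-up throughout. The expected ADR cost and
#' utility decrement are applied once at cycle 1.
#'
#' @param trace A [cohort_trace()] (carrying its generating schedule).
#' @param econ An [econ_params()] with the same `cycle_length`.
#' @param half_cycle_correction Use the average of start- and
#'   end-of-cycle occupancy for rewards (default `FALSE`).
#' @param adr_strict Passed to [expected_adr_adjustment()].
#' @return An object of class `strategy_result` with elements `arm`,
#'   `total_cost`, `total_qaly`, `median_pfs_months`, `median_os_months`
#'   and the `trace`.
#' @export
accumulate_outcomes <- function(trace, econ, half_cycle_correction = FALSE,
                                adr_strict = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(econ, "econ_params"))
  cl <- attr(trace, "cycle_length")
  if (!isTRUE(all.equal(cl, econ$cycle_length))) {
    stop("trace and econ_params disagree on cycle length", call. = FALSE)
  }
  schedule <- attr(trace, "schedule")
  n <- nrow(trace) - 1L
  cyc_years <- cl / 365.25
  t <- seq_len(n)
  disc <- (1 + econ$discount_annual)^(-t * cyc_years)

  occ <- function(col) {
    if (half_cycle_correction) (trace[[col]][t] + trace[[col]][t + 1L]) / 2
    else trace[[col]][t + 1L]
  }
  pfs_occ <- occ("pfs")
  dp_occ <- occ("dp")

  # expected docetaxel exposure: decompose DP occupancy by entry cohort
  doce_occ <- numeric(n)  # DP occupancy still within the salvage window
  if (!is.null(schedule)) {
    influx <- trace$pfs[t] * schedule$p_pfs_to_dp
    for (s in t[influx > 0]) {
      alive <- influx[s]
      for (k in 0:(econ$docetaxel_cycles - 1L)) {
        tt <- s + k
        if (tt > n) break
        if (k > 0) alive <- alive * (1 - schedule$p_death[tt])
        doce_occ[tt] <- doce_occ[tt] + alive
      }
    }
  }
  doce_cost_cycle <- econ$docetaxel_ampules_per_cycle * econ$docetaxel_ampule_cost
  drug_charged <- as.numeric(t <= econ$free_drug_after_cycle)

  cost_t <- drug_charged * econ$drug_cost_per_cycle * pfs_occ +
    econ$followup_cost_per_cycle * dp_occ +
    doce_cost_cycle * doce_occ
  qaly_t <- (econ$u_pfs * pfs_occ + econ$u_dp * dp_occ) * cyc_years

  adr <- expected_adr_adjustment(econ, strict = adr_strict)
  total_cost <- sum(disc * cost_t) + disc[1L] * adr[["cost"]]
  total_qaly <- sum(disc * qaly_t) - disc[1L] * adr[["utility_decrement"]] * cyc_years

  med_pfs <- suppressWarnings(median_state_time(trace, "pfs"))
  med_os <- suppressWarnings(median_state_time(trace, "alive"))

  structure(
    list(arm = econ$arm, total_cost = total_cost, total_qaly = total_qaly,
         median_pfs_months = med_pfs, median_os_months = med_os,
         trace = trace),
    class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s: discounted cost $%.2f, QALYs %.4f; median PFS %.2f / OS %.2f months\n",
              x$arm, x$total_cost, x$total_qaly,
              x$median_pfs_months, x$median_os_months))
  invisible(x)
}

#' Incremental cost-utility ratio
#'
#' `ICUR = (cost_new - cost_comparator) / (QALY_new - QALY_comparator)`.
#' Dominance is classified from the incremental quadrant: `dominant`
#' (cheaper and more effective), `dominated` (dearer and less
#' effective), otherwise `tradeoff`. With zero incremental QALYs the
#' ratio is undefined and reported as `NA`.
#'
#' @param new,comparator [accumulate_outcomes()] results from the same
#'   horizon and discount rate.
#' @return An object of class `icur_result` with `delta_cost`,
#'   `delta_qaly`, `icur`, `icur_defined`, `dominance`.
#' @export
compute_icur <- function(new, comparator) {
  stopifnot(inherits(new, "strategy_result"),
            inherits(comparator, "strategy_result"))
  dc <- new$total_cost - comparator$total_cost
  dq <- new$total_qaly - comparator$total_qaly
  defined <- dq != 0
  icur <- if (defined) dc / dq else NA_real_
  dominance <- if (dc < 0 && dq > 0) "dominant"
  else if (dc > 0 && dq < 0) "dominated"
  else "tradeoff"
  structure(
    list(new_arm = new$arm, comparator_arm = comparator$arm,
         delta_cost = dc, delta_qaly = dq,
         icur = icur, icur_defined = defined, dominance = dominance),
    class = "icur_result")
}

#' @export
print.icur_result <- function(x, ...) {
  cat(sprintf("%s vs %s: delta cost $%.2f, delta QALY %.4f -> %s",
              x$new_arm, x$comparator_arm, x$delta_cost, x$delta_qaly, x$dominance))
  if (x$icur_defined) cat(sprintf(", ICUR $%.2f/QALY", x$icur))
  cat("\n")
  invisible(x)
}
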