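make_econ <- function(arm = "icotinib", ...) {
  defaults <- list(
    arm = arm,
    drug_cost_per_cycle = if (arm == "icotinib") 1349.40 else 1818.48,
    free_drug_after_cycle = if (arm == "icotinib") 9 else 7
  )
  do.call(econ_params, utils::modifyList(defaults, list(...)))
}

test_that("per-cycle drug costs follow from unit prices", {
  expect_equal(3 * 449.80, 1349.40, tolerance = 1e-12)
  expect_equal(2.1 * 865.94, 1818.48, tolerance = 1e-4)
  cfg <- default_config()
  expect_equal(cfg$arms$icotinib$drug_cost_per_cycle, 1349.40)
  expect_equal(cfg$arms$gefitinib$drug_cost_per_cycle, 1818.48, tolerance = 1e-5)
})

test_that("cycle_reward applies the assistance-programme cutoff and DP rules", {
  ico <- make_econ("icotinib")
  gef <- make_econ("gefitinib")
  # icotinib free from cycle 10 onwards; gefitinib still charged at cycle 3
  expect_equal(cycle_reward(ico, 10)$cost[["pfs"]], 0)
  expect_equal(cycle_reward(ico, 9)$cost[["pfs"]], 1349.40)
  expect_equal(cycle_reward(gef, 3)$cost[["pfs"]], 1818.48)
  expect_equal(cycle_reward(gef, 8)$cost[["pfs"]], 0)
  # DP: docetaxel (6 x 108.72) + follow-up within the salvage window
  r <- cycle_reward(ico, 5, cycles_since_progression = 0)
  expect_equal(r$cost[["dp"]], 57.96 + 6 * 108.72)
  expect_equal(cycle_reward(ico, 20, cycles_since_progression = 6)$cost[["dp"]], 57.96)
  # death carries neither cost nor utility
  expect_equal(r$cost[["death"]], 0)
  expect_equal(r$utility[["death"]], 0)
  expect_equal(r$utility[["pfs"]], 0.673)
  expect_equal(r$utility[["dp"]], 0.473)
})

test_that("expected ADR adjustment is the probability-weighted expectation", {
  empty <- make_econ()
  expect_equal(expected_adr_adjustment(empty), c(cost = 0, utility_decrement = 0))

  one <- make_econ(adr_events = data.frame(
    name = "diarrhea", probability = 0.02, cost = 5.18, utility = 0.606))
  adj <- expected_adr_adjustment(one)
  expect_equal(adj[["cost"]], 0.1036, tolerance = 1e-12)
  expect_equal(adj[["utility_decrement"]], 0.02 * (0.673 - 0.606), tolerance = 1e-12)

  # linearity: doubling every probability doubles both outputs
  two <- make_econ(adr_events = data.frame(
    name = c("diarrhea", "rash"), probability = c(0.02, 0.01),
    cost = c(5.18, 5.50), utility = c(0.606, 0.621)))
  doubled <- make_econ(adr_events = within(two$adr_events,
                                           probability <- probability * 2))
  expect_equal(expected_adr_adjustment(doubled),
               2 * expected_adr_adjustment(two))
})

test_that("an ADR utility above u_pfs errors unless flooring is requested", {
  bad <- make_econ(u_pfs = 0.5, adr_events = data.frame(
    name = "rash", probability = 0.01, cost = 5.5, utility = 0.621))
  expect_error(expected_adr_adjustment(bad), "exceeds u_pfs")
  adj <- expected_adr_adjustment(bad, strict = FALSE)
  expect_equal(adj[["utility_decrement"]], 0)
  expect_equal(adj[["cost"]], 0.055)
})

test_that("a single undiscounted PFS cycle accrues u_pfs * cycle/year QALYs", {
  econ <- make_econ(discount_annual = 0)
  trace <- run_cohort(schedule_from_probs(0, 0))
  res <- accumulate_outcomes(trace, econ)
  expect_equal(res$total_qaly, 0.673 * 21 / 365.25, tolerance = 1e-12)
  expect_equal(res$total_cost, 1349.40, tolerance = 1e-12)
})

test_that("discounting strictly shrinks totals that accrue after cycle 1", {
  sched <- transition_schedule(base_params$ico_pfs, base_params$ico_os, 87)
  trace <- run_cohort(sched)
  r0 <- accumulate_outcomes(trace, make_econ(discount_annual = 0))
  r3 <- accumulate_outcomes(trace, make_econ(discount_annual = 0.03))
  expect_lt(r3$total_cost, r0$total_cost)
  expect_lt(r3$total_qaly, r0$total_qaly)
})

test_that("undiscounted QALYs equal an independent occupancy summation", {
  sched <- transition_schedule(base_params$gef_pfs, base_params$gef_os, 87)
  trace <- run_cohort(sched)
  adr <- data.frame(name = "rash", probability = 0.01, cost = 5.5, utility = 0.621)
  econ <- make_econ("gefitinib", discount_annual = 0, adr_events = adr)
  res <- accumulate_outcomes(trace, econ)
  cyc_yr <- 21 / 365.25
  oracle <- sum((0.673 * trace$pfs[-1] + 0.473 * trace$dp[-1]) * cyc_yr) -
    0.01 * (0.673 - 0.621) * cyc_yr
  expect_equal(res$total_qaly, oracle, tolerance = 1e-12)
})

test_that("mismatched cycle lengths are a configuration error", {
  trace <- run_cohort(schedule_from_probs(rep(0.1, 5), rep(0.05, 5),
                                          cycle_length = 30))
  expect_error(accumulate_outcomes(trace, make_econ()), "cycle length")
})

test_that("raising any single cost parameter never lowers a strategy's cost", {
  cfg <- default_config()
  base_cost <- evaluate_arm(cfg, "icotinib")$total_cost
  for (nm in c("drug_cost.icotinib", "followup_cost", "docetaxel_ampule_cost",
               "adr_cost.diarrhea")) {
    bumped <- set_config_param(cfg, nm, get_config_param(cfg, nm) * 1.5)
    expect_gte(evaluate_arm(bumped, "icotinib")$total_cost, base_cost)
  }
})

test_that("ICUR arithmetic, undefined ratio and dominance classification", {
  mk <- function(cost, qaly) structure(
    list(arm = "x", total_cost = cost, total_qaly = qaly,
         median_pfs_months = NA_real_, median_os_months = NA_real_, trace = NULL),
    class = "strategy_result")
  # published headline totals: cheaper and more effective -> dominant,
  # ICUR (10662.82-13127.57)/(0.279-0.269) = -246475
  r <- compute_icur(mk(10662.82, 0.279), mk(13127.57, 0.269))
  expect_equal(r$icur, -246475, tolerance = 1e-6)
  expect_equal(r$dominance, "dominant")
  # identical strategies: deltas zero, ratio undefined
  same <- compute_icur(mk(100, 0.5), mk(100, 0.5))
  expect_false(same$icur_defined)
  expect_true(is.na(same$icur))
  # cheaper and less effective: southwest quadrant, positive ratio, tradeoff
  sw <- compute_icur(mk(90, 0.4), mk(100, 0.5))
  expect_equal(sw$dominance, "tradeoff")
  expect_gt(sw$icur, 0)
  # dearer and less effective: dominated
  expect_equal(compute_icur(mk(120, 0.4), mk(100, 0.5))$dominance, "dominated")
})

test_that("docetaxel exposure never exceeds DP occupancy", {
  sched <- transition_schedule(base_params$ico_pfs, base_params$ico_os, 87)
  trace <- run_cohort(sched)
  econ <- make_econ(discount_annual = 0, followup_cost_per_cycle = 0,
                    docetaxel_ampule_cost = 1, docetaxel_ampules_per_cycle = 1)
  res <- accumulate_outcomes(trace, econ)
  # with $1/cycle docetaxel and nothing else, DP costs are bounded by total
  # person-cycles in DP (and drug cost by charged PFS person-cycles)
  dp_cycles <- sum(trace$dp[-1])
  drug <- 1349.40 * sum(trace$pfs[2:10])
  expect_lte(res$total_cost, drug + dp_cycles + 1)
  expect_gt(res$total_cost, drug)
})
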