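test_that("identical PFS and OS curves yield zero progression probability", {
  s <- transition_schedule(base_params$ico_pfs, base_params$ico_pfs, 87)
  expect_equal(s$p_pfs_to_dp, rep(0, 87))
})

test_that("progression probability is floored at zero when death hazard dominates", {
  # OS curve falling faster than the PFS curve at every cycle
  fast_os <- weibull_params(gamma = 1, log_lambda = log(0.02))
  slow_pfs <- weibull_params(gamma = 1, log_lambda = log(0.001))
  s <- transition_schedule(slow_pfs, fast_os, 20)
  expect_true(all(s$p_pfs_to_dp == 0))
  expect_true(all(s$p_pfs_exit >= 0 & s$p_death <= 1))
})

test_that("cumulative PFS retention telescopes back to the survival curve", {
  s <- transition_schedule(base_params$ico_pfs, base_params$ico_os, 87, 21)
  trace <- run_cohort(s)
  # PFS(t) = prod(1 - p_pfs_exit) = S_pfs(t * 21); equality to 1e-12
  expect_equal(trace$pfs[-1],
               weibull_survival(base_params$ico_pfs, (1:87) * 21),
               tolerance = 1e-12)
  # alive fraction telescopes the OS curve the same way
  expect_equal(trace$pfs[-1] + trace$dp[-1],
               weibull_survival(base_params$ico_os, (1:87) * 21),
               tolerance = 1e-12)
})

test_that("all-zero probabilities leave the cohort untouched", {
  s <- schedule_from_probs(rep(0, 10), rep(0, 10))
  trace <- run_cohort(s)
  expect_equal(trace$pfs, rep(1, 11))
  expect_equal(trace$death, rep(0, 11))
})

test_that("constant-probability trace equals the matrix-power oracle", {
  s <- schedule_from_probs(rep(0.15, 3), rep(0.05, 3))  # p_pfs_to_dp = 0.1
  trace <- run_cohort(s)
  oracle <- matrix_trace(0.1, 0.05, 3)
  expect_equal(trace$pfs, oracle[, 1], tolerance = 1e-12)
  expect_equal(trace$dp, oracle[, 2], tolerance = 1e-12)
  expect_equal(trace$death, oracle[, 3], tolerance = 1e-12)
  expect_equal(trace$pfs[2:4], c(0.85, 0.7225, 0.614125), tolerance = 1e-12)
})

test_that("traces conserve mass and are monotone for random schedules", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    p_exit <- runif(n, 0, 0.9)
    p_death <- runif(n, 0, pmin(0.9, p_exit + 0.3))
    trace <- run_cohort(schedule_from_probs(p_exit, p_death))
    expect_true(all(abs(trace$pfs + trace$dp + trace$death - 1) < 1e-9))
    expect_true(all(diff(trace$pfs) <= 1e-12))
    expect_true(all(diff(trace$death) >= -1e-12))
    expect_true(all(trace$pfs >= 0 & trace$dp >= 0 & trace$death >= 0))
  }
})

test_that("no resurrection: with zero death probability nobody dies", {
  s <- schedule_from_probs(runif(20, 0, 0.5), rep(0, 20))
  trace <- run_cohort(s)
  expect_equal(trace$death, rep(0, 21))
})

test_that("median crossing exactly at a cycle boundary is exact", {
  # pfs hits exactly 0.5 at cycle 2 then keeps falling
  s <- schedule_from_probs(c(1 - sqrt(0.5), 1 - sqrt(0.5), 0.5), rep(0, 3))
  trace <- run_cohort(s)
  expect_equal(trace$pfs[3], 0.5, tolerance = 1e-12)
  expect_equal(median_state_time(trace, "pfs"), 2 * 21 / 30.44, tolerance = 1e-9)
})

test_that("median interpolates linearly between bracketing cycles", {
  # build a trace whose pfs series is 1, 0.8, .., 0.6 (cycle 5), 0.4 (cycle 6)
  pfs_target <- c(1, 0.95, 0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  p_exit <- 1 - pfs_target[-1] / pfs_target[-length(pfs_target)]
  trace <- run_cohort(schedule_from_probs(p_exit, rep(0, length(p_exit))))
  expect_equal(trace$pfs, pfs_target, tolerance = 1e-12)
  # crossing halfway between cycles 5 and 6 -> 5.5 cycles = 3.79 months
  expect_equal(median_state_time(trace, "pfs"), 5.5 * 21 / 30.44, tolerance = 1e-9)
  expect_equal(median_state_time(trace, "pfs"), 3.794, tolerance = 1e-3)
})

test_that("a median that is never reached signals explicitly", {
  trace <- run_cohort(schedule_from_probs(rep(0.01, 5), rep(0.001, 5)))
  expect_warning(m <- median_state_time(trace, "alive"),
                 class = "markovcua_median_not_reached")
  expect_true(is.na(m))
})

test_that("full icotinib model puts the alive median near the reported 13.6 months", {
  s <- transition_schedule(base_params$ico_pfs, base_params$ico_os, 87)
  m <- median_state_time(run_cohort(s), "alive")
  expect_equal(m, 13.6, tolerance = 0.08)  # ~1 month band, relative
})
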