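test_that("km_curve enforces its invariants", {
  expect_s3_class(km_curve(c(0, 10, 20), c(1, 0.7, 0.5)), "km_curve")
  expect_error(km_curve(c(10, 5), c(0.9, 0.8)), "strictly increasing")
  expect_error(km_curve(c(5, 10), c(0.5, 0.9)), "non-increasing")
  expect_error(km_curve(c(0, 10), c(0.9, 0.5)), "time 0 must be 1")
  expect_error(km_curve(c(5, 10), c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("linearised fit recovers an exponential exactly (gamma = 1)", {
  t <- seq(10, 200, by = 10)
  fit <- fit_weibull_km(km_curve(t, exp(-0.01 * t)))
  expect_equal(fit$gamma, 1, tolerance = 1e-6)
  expect_equal(fit$log_lambda, log(0.01), tolerance = 1e-6)
  expect_equal(fit$fit_corr, 1, tolerance = 1e-9)
})

test_that("linearised fit returns generating parameters on exact Weibull points", {
  t <- seq(21, 420, by = 21)
  fit <- fit_weibull_km(exact_curve(base_params$ico_pfs, t))
  expect_equal(fit$gamma, 0.9359, tolerance = 1e-6)
  expect_equal(fit$log_lambda, -5.0757, tolerance = 1e-6)
  expect_gt(fit$fit_r2, 1 - 1e-9)
})

test_that("fit round-trips over a grid of shapes and scales", {
  set.seed(42)
  for (i in 1:20) {
    gamma <- runif(1, 0.5, 3)
    log_lambda <- runif(1, -9, -2)
    p <- weibull_params(gamma, log_lambda)
    # sample times around the distribution's own scale so S stays in (0,1)
    tmed <- weibull_median(p)
    t <- seq(tmed / 5, tmed * 3, length.out = 12)
    fit <- fit_weibull_km(exact_curve(p, t))
    expect_equal(fit$gamma, gamma, tolerance = 1e-8)
    expect_equal(fit$log_lambda, log_lambda, tolerance = 1e-8)
  }
})

test_that("points with S = 1 or S = 0 are excluded with a message", {
  t <- seq(21, 210, by = 21)
  curve <- km_curve(c(0, t), c(1, weibull_survival(base_params$ico_pfs, t)))
  expect_message(fit <- fit_weibull_km(curve), "excluded 1 point")
  expect_equal(fit$n_dropped, 1L)
  expect_equal(fit$gamma, 0.9359, tolerance = 1e-6)
})

test_that("fit refuses fewer than 3 usable points", {
  expect_error(fit_weibull_km(km_curve(c(10, 20), c(0.9, 0.8))),
               "at least 3 usable points")
  # 4 points but only 2 usable after exclusion
  expect_error(
    suppressMessages(fit_weibull_km(km_curve(c(0, 5, 10, 20), c(1, 1, 0.9, 0.8)))),
    "at least 3 usable points")
})

test_that("weibull_survival obeys S(0) = 1, monotonicity and the median closed form", {
  p <- base_params$ico_pfs
  expect_identical(weibull_survival(p, 0), 1)
  t <- sort(runif(50, 0, 1000))
  s <- weibull_survival(p, t)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s > 0 & s <= 1))
  # median: (ln 2 / lambda)^(1/gamma) ~ 153.2 days for the icotinib PFS curve
  tmed <- weibull_median(p)
  expect_equal(tmed, (log(2) / exp(-5.0757))^(1 / 0.9359), tolerance = 1e-12)
  expect_equal(tmed, 153.20, tolerance = 1e-4)
  expect_equal(weibull_survival(p, tmed), 0.5, tolerance = 1e-12)
  expect_error(weibull_survival(p, -1), "non-negative")
})

test_that("per-cycle transition probability matches the direct formula", {
  # 1 - exp(-e^-5.0757 * 21^0.9359) at cycle 1 of the icotinib PFS curve
  p1 <- cycle_transition_prob(base_params$ico_pfs, 1, 21)
  expect_equal(p1, 1 - exp(-exp(-5.0757) * 21^0.9359), tolerance = 1e-12)
  expect_equal(p1, 0.1023, tolerance = 1e-3)
  expect_error(cycle_transition_prob(base_params$ico_pfs, 0), ">= 1")
})

test_that("gamma = 1 gives a constant per-cycle probability (memoryless)", {
  p <- weibull_params(gamma = 1, log_lambda = log(0.004))
  probs <- cycle_transition_prob(p, 1:50, 21)
  expect_equal(probs, rep(1 - exp(-0.004 * 21), 50), tolerance = 1e-12)
})

test_that("gamma > 1 gives a strictly increasing transition probability", {
  probs <- cycle_transition_prob(base_params$ico_os, 1:87, 21)
  expect_true(all(diff(probs) > 0))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("P(t) equals the conditional failure probability of the survival curve", {
  for (p in base_params) {
    cl <- 21
    t <- 1:87
    direct <- cycle_transition_prob(p, t, cl)
    s0 <- weibull_survival(p, (t - 1) * cl)
    s1 <- weibull_survival(p, t * cl)
    expect_equal(direct, (s0 - s1) / s0, tolerance = 1e-12)
  }
})

test_that("KM curves survive a CSV round trip", {
  curve <- exact_curve(base_params$gef_os, seq(21, 210, by = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_km_csv(curve, path)
  back <- read_km_csv(path)
  expect_equal(back$time_days, curve$time_days)
  expect_equal(back$survival, curve$survival)
})

test_that("resample_km evaluates the step function right-continuously", {
  curve <- km_curve(c(0, 30, 60), c(1, 0.8, 0.5))
  rs <- resample_km(curve, c(10, 30, 45, 100))
  expect_equal(rs$survival, c(1, 0.8, 0.8, 0.5))
})
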