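#' Default model configuration
#'
#' The bundled base case: a two-arm comparison of icotinib vs gefitinib
#' as second-line therapy for advanced NSCLC in China (costs in 2014
#' USD). Drug costs per 21-day cycle are derived from unit prices
#' (icotinib: 3 units of $449.80; gefitinib: 2.1 units of $865.94).
#' Weibull survival parameters for PFS and OS are on the day scale.
#' One-way ranges follow the convention that a single printed range
#' value is the low bound with the base case as the high bound.
#'
#' @return A validated object of class `model_config` (a named list).
#' @export
default_config <- function() {
  cfg <- list(
    horizon_years = 5,
    cycle_length_days = 21,
    discount_annual = 0.03,
    half_cycle_correction = FALSE,
    days_per_month = 30.44,
    gdp_per_capita = 7679,          # China, 2014, current USD
    wtp = list(max_gdp_multiple = 3, points = 100),
    psa = list(n = 1000, seed = 20140325),
    shared = list(
      followup_cost_per_cycle = 57.96,
      docetaxel_ampule_cost = 108.72,
      docetaxel_ampules_per_cycle = 6,   # 75 mg/m2 x BSA 1.6 m2 = 120 mg in 20 mg ampules
      docetaxel_cycles = 6,
      u_pfs = 0.673,
      u_dp = 0.473,
      adr_utility = list(diarrhea = 0.606, nausea = 0.605,
                         rash = 0.621, raised_alt = 0.639),
      adr_cost = list(diarrhea = 5.18, nausea = 13.61,
                      rash = 5.50, raised_alt = 216.35)
    ),
    arms = list(
      icotinib = list(
        drug_unit_price = 449.80,
        drug_units_per_cycle = 3,
        free_drug_after_cycle = 9,      # assistance programme from month 6
        weibull = list(
          pfs = list(gamma = 0.9359, log_lambda = -5.0757),
          os  = list(gamma = 1.1664, log_lambda = -7.3062)
        ),
        adr_prob = list(diarrhea = 0.02, rash = 0.005,
                        raised_alt = 0.005, nausea = 0.005)
      ),
      gefitinib = list(
        drug_unit_price = 865.94,
        drug_units_per_cycle = 2.1,
        free_drug_after_cycle = 7,      # assistance programme from month 5
        weibull = list(
          pfs = list(gamma = 0.94, log_lambda = -5.2677),
          os  = list(gamma = 1.1938, log_lambda = -7.5374)
        ),
        adr_prob = list(rash = 0.01, raised_alt = 0.01)
      )
    ),
    owsa = list(
      u_pfs = c(0.27, 0.80),
      u_dp = c(0.19, 0.56),
      `drug_cost.icotinib` = c(1349.40, 1349.40),
      `drug_cost.gefitinib` = c(1610.90, 1818.48),
      followup_cost = c(50.64, 57.96),
      docetaxel_ampule_cost = c(74.96, 108.72),
      `adr_cost.diarrhea` = c(4.14, 6.22),
      `adr_cost.nausea` = c(10.89, 16.33),
      `adr_cost.rash` = c(4.40, 6.60),
      `adr_cost.raised_alt` = c(173.08, 259.62),
      `adr_prob.icotinib.diarrhea` = c(0.014, 0.026),
      discount_annual = c(0, 0.08)
    )
  )
  class(cfg) <- c("model_config", "list")
  validate_config(cfg)
}

config_keys <- c("horizon_years", "cycle_length_days", "discount_annual",
                 "half_cycle_correction", "days_per_month", "gdp_per_capita",
                 "wtp", "psa", "shared", "arms", "owsa")
shared_keys <- c("followup_cost_per_cycle", "docetaxel_ampule_cost",
                 "docetaxel_ampules_per_cycle", "docetaxel_cycles",
                 "u_pfs", "u_dp", "adr_utility", "adr_cost")
arm_keys <- c("drug_unit_price", "drug_units_per_cycle", "drug_cost_per_cycle",
              "free_drug_after_cycle", "weibull", "adr_prob")

fail_field <- function(field, why) {
  stop(sprintf("invalid config field `%s`: %s", field, why), call. = FALSE)
}

#' Validate a model configuration
#'
#' Checks every type invariant (positivity, probability and utility
#' bounds, Weibull shape positivity, discount range) and rejects
#' unknown keys. Errors name the offending field.
#'
#' @param cfg A `model_config` list.
#' @return The config, invisibly classed, with derived per-cycle drug
#'   costs filled in.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown)) fail_field(unknown[1L], "unknown key")
  missing <- setdiff(setdiff(config_keys, "owsa"), names(cfg))
  if (length(missing)) fail_field(missing[1L], "missing")

  num_pos <- function(field, x, lo = 0, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      fail_field(field, sprintf("must be a number in [%g, %g]", lo, hi))
    }
  }
  num_pos("horizon_years", cfg$horizon_years, lo = 1e-6)
  num_pos("cycle_length_days", cfg$cycle_length_days, lo = 1e-6)
  num_pos("discount_annual", cfg$discount_annual, 0, 0.08)
  num_pos("days_per_month", cfg$days_per_month, lo = 1)
  num_pos("gdp_per_capita", cfg$gdp_per_capita, lo = 0)
  if (!is.logical(cfg$half_cycle_correction)) {
    fail_field("half_cycle_correction", "must be logical")
  }
  num_pos("psa.n", cfg$psa$n, lo = 1)
  num_pos("psa.seed", cfg$psa$seed, lo = 0, hi = 2^31 - 1)
  num_pos("wtp.max_gdp_multiple", cfg$wtp$max_gdp_multiple, lo = 0)
  num_pos("wtp.points", cfg$wtp$points, lo = 2)

  sh <- cfg$shared
  unknown <- setdiff(names(sh), shared_keys)
  if (length(unknown)) fail_field(paste0("shared.", unknown[1L]), "unknown key")
  num_pos("shared.followup_cost_per_cycle", sh$followup_cost_per_cycle)
  num_pos("shared.docetaxel_ampule_cost", sh$docetaxel_ampule_cost)
  num_pos("shared.docetaxel_ampules_per_cycle", sh$docetaxel_ampules_per_cycle)
  num_pos("shared.docetaxel_cycles", sh$docetaxel_cycles)
  num_pos("shared.u_pfs", sh$u_pfs, 0, 1)
  num_pos("shared.u_dp", sh$u_dp, 0, 1)
  for (nm in names(sh$adr_utility)) {
    num_pos(paste0("shared.adr_utility.", nm), sh$adr_utility[[nm]], 0, 1)
  }
  for (nm in names(sh$adr_cost)) {
    num_pos(paste0("shared.adr_cost.", nm), sh$adr_cost[[nm]])
  }

  for (arm in names(cfg$arms)) {
    a <- cfg$arms[[arm]]
    unknown <- setdiff(names(a), arm_keys)
    if (length(unknown)) fail_field(paste0("arms.", arm, ".", unknown[1L]), "unknown key")
    if (is.null(a$drug_cost_per_cycle)) {
      num_pos(paste0("arms.", arm, ".drug_unit_price"), a$drug_unit_price)
      num_pos(paste0("arms.", arm, ".drug_units_per_cycle"), a$drug_units_per_cycle)
      cfg$arms[[arm]]$drug_cost_per_cycle <-
        a$drug_unit_price * a$drug_units_per_cycle
    } else {
      num_pos(paste0("arms.", arm, ".drug_cost_per_cycle"), a$drug_cost_per_cycle)
    }
    num_pos(paste0("arms.", arm, ".free_drug_after_cycle"), a$free_drug_after_cycle)
    for (ep in c("pfs", "os")) {
      w <- a$weibull[[ep]]
      if (is.null(w)) fail_field(paste0("arms.", arm, ".weibull.", ep), "missing")
      if (!is.numeric(w$gamma) || w$gamma <= 0) {
        fail_field(paste0("arms.", arm, ".weibull.", ep, ".gamma"),
                   "Weibull shape must be > 0")
      }
      if (!is.numeric(w$log_lambda) || !is.finite(w$log_lambda)) {
        fail_field(paste0("arms.", arm, ".weibull.", ep, ".log_lambda"),
                   "must be finite")
      }
      unit <- w$time_unit %||% "days"
      if (!unit %in% c("days", "months")) {
        fail_field(paste0("arms.", arm, ".weibull.", ep, ".time_unit"),
                   "must be 'days' or 'months'")
      }
      if (unit == "months") {  # convert scale to the day metric
        cfg$arms[[arm]]$weibull[[ep]]$log_lambda <-
          w$log_lambda - w$gamma * log(cfg$days_per_month)
        cfg$arms[[arm]]$weibull[[ep]]$time_unit <- "days"
      }
    }
    for (nm in names(a$adr_prob)) {
      num_pos(paste0("arms.", arm, ".adr_prob.", nm), a$adr_prob[[nm]], 0, 1)
      if (is.null(cfg$shared$adr_cost[[nm]]) || is.null(cfg$shared$adr_utility[[nm]])) {
        fail_field(paste0("arms.", arm, ".adr_prob.", nm),
                   "no matching shared adr_cost/adr_utility entry")
      }
    }
  }
  if (!is.null(cfg$owsa)) {
    for (nm in names(cfg$owsa)) {
      r <- as.numeric(cfg$owsa[[nm]])
      if (length(r) != 2L || any(!is.finite(r)) || r[1L] > r[2L]) {
        fail_field(paste0("owsa.", nm), "must be c(low, high) with low <= high")
      }
      cfg$owsa[[nm]] <- r
      # bound check against the parameter's own invariant, before any run
      probe <- cfg
      for (v in r) probe <- set_config_param(probe, nm, v)
    }
  }
  class(cfg) <- c("model_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of model cycles implied by a configuration
#' @param cfg A `model_config`.
#' @export
n_cycles <- function(cfg) {
  as.integer(ceiling(cfg$horizon_years * 365.25 / cfg$cycle_length_days))
}

#' Load / write a model configuration as YAML
#'
#' `load_config()` parses and fully validates; invalid or unknown
#' fields raise errors naming the field, and no partially-valid config
#' is returned.
#'
#' @param path Path to a YAML file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("model_config", "list")
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg A `model_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "model_config"))
  out <- unclass(cfg)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Model config: %d arms (%s), %d x %g-day cycles, discount %.1f%%/yr\n",
              length(x$arms), paste(names(x$arms), collapse = ", "),
              n_cycles(x), x$cycle_length_days, 100 * x$discount_annual))
  invisible(x)
}

# ---- parameter addressing for sensitivity analyses ----------------------

#' Get or set a named scalar model parameter
#'
#' Flat parameter names used by the one-way and probabilistic
#' sensitivity analyses: `u_pfs`, `u_dp`, `discount_annual`,
#' `followup_cost`, `docetaxel_ampule_cost`, `drug_cost.<arm>`,
#' `adr_cost.<event>`, `adr_prob.<arm>.<event>`.
#'
#' @param cfg A `model_config`.
#' @param name Parameter name.
#' @param value Replacement value (validated against the parameter's
#'   invariant).
#' @return `get_config_param()` the scalar value; `set_config_param()`
#'   the modified config.
#' @export
get_config_param <- function(cfg, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
  switch(parts[1L],
    u_pfs = cfg$shared$u_pfs,
    u_dp = cfg$shared$u_dp,
    discount_annual = cfg$discount_annual,
    followup_cost = cfg$shared$followup_cost_per_cycle,
    docetaxel_ampule_cost = cfg$shared$docetaxel_ampule_cost,
    drug_cost = {
      a <- cfg$arms[[parts[2L]]]
      a$drug_cost_per_cycle %||% (a$drug_unit_price * a$drug_units_per_cycle)
    },
    adr_cost = cfg$shared$adr_cost[[parts[2L]]],
    adr_prob = cfg$arms[[parts[2L]]]$adr_prob[[parts[3L]]],
    stop(sprintf("unknown parameter `%s`", name), call. = FALSE)
  )
}

#' @rdname get_config_param
#' @export
set_config_param <- function(cfg, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
  check <- function(lo, hi) {
    if (!is.numeric(value) || value < lo || value > hi) {
      stop(sprintf("parameter `%s` = %g violates its bounds [%g, %g]",
                   name, value, lo, hi), call. = FALSE)
    }
  }
  arm_exists <- function(arm) {
    if (is.null(cfg$arms[[arm]])) {
      stop(sprintf("unknown arm in parameter `%s`", name), call. = FALSE)
    }
  }
  switch(parts[1L],
    u_pfs = { check(0, 1); cfg$shared$u_pfs <- value },
    u_dp = { check(0, 1); cfg$shared$u_dp <- value },
    discount_annual = { check(0, 0.08); cfg$discount_annual <- value },
    followup_cost = { check(0, Inf); cfg$shared$followup_cost_per_cycle <- value },
    docetaxel_ampule_cost = { check(0, Inf); cfg$shared$docetaxel_ampule_cost <- value },
    drug_cost = {
      arm_exists(parts[2L]); check(0, Inf)
      cfg$arms[[parts[2L]]]$drug_cost_per_cycle <- value
    },
    adr_cost = {
      if (is.null(cfg$shared$adr_cost[[parts[2L]]])) {
        stop(sprintf("unknown ADR event in parameter `%s`", name), call. = FALSE)
      }
      check(0, Inf); cfg$shared$adr_cost[[parts[2L]]] <- value
    },
    adr_prob = {
      arm_exists(parts[2L])
      if (is.null(cfg$arms[[parts[2L]]]$adr_prob[[parts[3L]]])) {
        stop(sprintf("unknown ADR event in parameter `%s`", name), call. = FALSE)
      }
      check(0, 1); cfg$arms[[parts[2L]]]$adr_prob[[parts[3L]]] <- value
    },
    stop(sprintf("unknown parameter `%s`", name), call. = FALSE)
  )
  cfg
}

# ---- builders -----------------------------------------------------------

#' Extract per-arm model objects from a configuration
#'
#' @param cfg A `model_config`.
#' @param arm Arm name present in `cfg$arms`.
#' @return `arm_weibull()`: list of [weibull_params()] for `pfs` and
#'   `os`. `arm_econ()`: an [econ_params()].
#' @export
arm_weibull <- function(cfg, arm) {
  a <- cfg$arms[[arm]]
  if (is.null(a)) stop(sprintf("unknown arm `%s`", arm), call. = FALSE)
  lapply(a$weibull[c("pfs", "os")], function(w) {
    weibull_params(gamma = w$gamma, log_lambda = w$log_lambda)
  })
}

#' @rdname arm_weibull
#' @export
arm_econ <- function(cfg, arm) {
  a <- cfg$arms[[arm]]
  if (is.null(a)) stop(sprintf("unknown arm `%s`", arm), call. = FALSE)
  sh <- cfg$shared
  events <- names(a$adr_prob)
  adr <- data.frame(
    name = if (length(events)) events else character(),
    probability = vapply(events, function(e) a$adr_prob[[e]], numeric(1)),
    cost = vapply(events, function(e) sh$adr_cost[[e]], numeric(1)),
    utility = vapply(events, function(e) sh$adr_utility[[e]], numeric(1)),
    row.names = NULL
  )
  econ_params(
    arm = arm,
    drug_cost_per_cycle = a$drug_cost_per_cycle %||%
      (a$drug_unit_price * a$drug_units_per_cycle),
    free_drug_after_cycle = a$free_drug_after_cycle,
    followup_cost_per_cycle = sh$followup_cost_per_cycle,
    docetaxel_ampule_cost = sh$docetaxel_ampule_cost,
    docetaxel_ampules_per_cycle = sh$docetaxel_ampules_per_cycle,
    docetaxel_cycles = sh$docetaxel_cycles,
    adr_events = adr,
    u_pfs = sh$u_pfs, u_dp = sh$u_dp,
    discount_annual = cfg$discount_annual,
    cycle_length = cfg$cycle_length_days
  )
}

#' Evaluate one arm of the model
#'
#' Full pipeline for a single strategy: Weibull parameters -> transition
#' schedule -> cohort trace -> discounted accumulation.
#'
#' @param cfg A `model_config`.
#' @param arm Arm name.
#' @param adr_strict Passed to [expected_adr_adjustment()].
#' @return A [accumulate_outcomes()] `strategy_result`.
#' @export
evaluate_arm <- function(cfg, arm, adr_strict = TRUE) {
  w <- arm_weibull(cfg, arm)
  sched <- transition_schedule(w$pfs, w$os, n_cycles(cfg), cfg$cycle_length_days)
  trace <- run_cohort(sched)
  accumulate_outcomes(trace, arm_econ(cfg, arm),
                      half_cycle_correction = cfg$half_cycle_correction,
                      adr_strict = adr_strict)
}

#' Evaluate both arms and their incremental comparison
#'
#' @param cfg A `model_config` with (at least) two arms; the first is
#'   taken as the new strategy and the second as the comparator unless
#'   given explicitly.
#' @param new,comparator Arm names.
#' @param adr_strict Passed to [expected_adr_adjustment()].
#' @return List with per-arm `strategy_result`s and an `icur_result`.
#' @export
compare_strategies <- function(cfg, new = names(cfg$arms)[1L],
                               comparator = names(cfg$arms)[2L],
                               adr_strict = TRUE) {
  rn <- evaluate_arm(cfg, new, adr_strict = adr_strict)
  rc <- evaluate_arm(cfg, comparator, adr_strict = adr_strict)
  list(new = rn, comparator = rc, icur = compute_icur(rn, rc))
}
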