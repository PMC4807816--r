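#' Run the modelling pipeline and write its outputs
#'
#' Executes the requested stages against a validated configuration and
#' writes CSV outputs plus a JSON run manifest recording every
#' parameter value used. All outputs are deterministic given the
#' configuration and seed.
#'
#' Stages:
#' \describe{
#'   \item{`fit`}{Refit Weibull parameters from KM CSV files; requires
#'     `km_files`, a named list `arms.<arm>.<endpoint> = path`. Writes
#'     `weibull_fits.csv` and replaces the configured parameters for
#'     downstream stages.}
#'   \item{`run`}{Base-case two-arm evaluation. Writes `results.csv`
#'     (per arm: cost, QALYs, medians), `icur.csv`, and per-arm
#'     `trace_<arm>.csv` and `schedule_<arm>.csv`.}
#'   \item{`owsa`}{One-way sensitivity analysis. Writes `owsa.csv`.}
#'   \item{`psa`}{Probabilistic sensitivity analysis. Writes
#'     `psa_samples.csv`.}
#'   \item{`ceac`}{Acceptability curve over the configured WTP grid
#'     (requires `psa`). Writes `ceac.csv`.}
#' }
#'
#' @param cfg A `model_config`.
#' @param commands Character subset of
#'   `c("fit", "run", "owsa", "psa", "ceac")`.
#' @param out_dir Output directory (created if absent).
#' @param seed Optional integer overriding `cfg$psa$seed`.
#' @param km_files For `fit`: named list mapping `"<arm>.<endpoint>"`
#'   (endpoint `pfs` or `os`) to KM CSV paths.
#' @return Invisibly, a list with the computed objects and the manifest.
#' @export
run_pipeline <- function(cfg, commands = "run", out_dir = ".", seed = NULL,
                         km_files = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  commands <- match.arg(commands, c("fit", "run", "owsa", "psa", "ceac"),
                        several.ok = TRUE)
  if (!is.null(seed)) cfg$psa$seed <- seed
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character()
  produced <- list()
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
  }

  if ("fit" %in% commands) {
    if (is.null(km_files) || length(km_files) == 0L) {
      stop("`fit` requires `km_files` (named list '<arm>.<endpoint>' -> path)",
           call. = FALSE)
    }
    fits <- list()
    for (key in names(km_files)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !parts[2L] %in% c("pfs", "os") ||
          is.null(cfg$arms[[parts[1L]]])) {
        stop(sprintf("bad km_files key `%s`: expected '<arm>.<pfs|os>'", key),
             call. = FALSE)
      }
      fit <- fit_weibull_km(read_km_csv(km_files[[key]]))
      cfg$arms[[parts[1L]]]$weibull[[parts[2L]]] <-
        list(gamma = fit$gamma, log_lambda = fit$log_lambda)
      fits[[key]] <- data.frame(arm = parts[1L], endpoint = parts[2L],
                                gamma = fit$gamma, log_lambda = fit$log_lambda,
                                r2 = fit$fit_r2, corr = fit$fit_corr)
    }
    fits <- do.call(rbind, fits)
    rownames(fits) <- NULL
    emit(fits, "weibull_fits.csv")
    produced$fits <- fits
  }

  if ("run" %in% commands) {
    res <- compare_strategies(cfg)
    produced$run <- res
    arms <- list(res$new, res$comparator)
    emit(data.frame(
      arm = vapply(arms, `[[`, character(1), "arm"),
      total_cost_usd = vapply(arms, `[[`, numeric(1), "total_cost"),
      total_qaly = vapply(arms, `[[`, numeric(1), "total_qaly"),
      median_pfs_months = vapply(arms, `[[`, numeric(1), "median_pfs_months"),
      median_os_months = vapply(arms, `[[`, numeric(1), "median_os_months")
    ), "results.csv")
    emit(data.frame(
      new = res$icur$new_arm, comparator = res$icur$comparator_arm,
      delta_cost_usd = res$icur$delta_cost, delta_qaly = res$icur$delta_qaly,
      icur_usd_per_qaly = res$icur$icur, dominance = res$icur$dominance
    ), "icur.csv")
    for (r in arms) {
      tr <- as.data.frame(r$trace)
      emit(tr, sprintf("trace_%s.csv", r$arm))
      emit(as.data.frame(attr(r$trace, "schedule")),
           sprintf("schedule_%s.csv", r$arm))
    }
  }

  if ("owsa" %in% commands) {
    ow <- one_way_sa(cfg)
    produced$owsa <- ow
    emit(as.data.frame(ow), "owsa.csv")
  }

  psa_res <- NULL
  if ("psa" %in% commands || "ceac" %in% commands) {
    psa_res <- run_psa(cfg)
    produced$psa <- psa_res
    if ("psa" %in% commands) emit(psa_res$samples, "psa_samples.csv")
  }

  if ("ceac" %in% commands) {
    cc <- ceac(psa_res, wtp_grid(cfg))
    produced$ceac <- cc
    emit(as.data.frame(cc), "ceac.csv")
  }

  manifest <- list(
    package = "markovcua",
    version = as.character(utils::packageVersion("markovcua")),
    commands = commands,
    seed = cfg$psa$seed,
    n_cycles = n_cycles(cfg),
    config = unclass(cfg),
    outputs = basename(outputs)
  )
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  produced$manifest <- manifest
  produced$outputs <- c(outputs, manifest_path)
  invisible(produced)
}
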