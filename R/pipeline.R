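#' @title Configuration and the end-to-end pipeline
#' @description A single JSON configuration drives the whole analysis:
#'   either a synthetic-trial block or paths to digitized curve / risk-table
#'   CSVs, parameter overrides, and analysis settings. [run_pipeline()] chains
#'   simulate (or load) -> reconstruct -> fit -> cohort model -> economics and
#'   writes `results.json`, per-arm traces, and a run log.
#' @name pipeline
NULL

default_analysis <- function() {
  list(
    wtp = 37423,
    psa_n = 1000L,
    psa_seed = 20230831L,
    psa_sd_frac = 0.2,
    scenario_discounts = c(0.2, 0.5, 0.8165),
    ceac_grid = seq(0, 2e5, by = 2000)
  )
}

default_synthetic <- function() {
  list(
    n_total = 585L, allocation = c(2L, 1L), censor_time = 30, seed = 20230831L,
    medians = list(active = list(pfs = 5.7, os = 15.4),
                   control = list(pfs = 4.3, os = 10.9)),
    shapes = list(pfs = 1.2, os = 1.0),
    read_step = 1.5, risk_step = 3
  )
}

#' Load and validate a pipeline configuration
#'
#' The JSON document may contain the top-level keys `synthetic` (synthetic
#' trial generation block), `inputs` (paths to per-arm/endpoint `curve` and
#' `risk` CSVs), `params` (overrides of [ce_params()] fields), `analysis`
#' (`wtp`, `psa_n`, `psa_seed`, `psa_sd_frac`, `scenario_discounts`,
#' `ceac_grid`) and `output_dir`. Exactly one of `synthetic`/`inputs` must be
#' present; unknown keys, out-of-range values and missing input files are
#' reported together in one validation error. Omitted fields take the
#' base-case defaults.
#'
#' @param path path to a JSON configuration file.
#' @return A validated `ce_config` list with defaults filled in.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  problems <- character()
  known_top <- c("synthetic", "inputs", "params", "analysis", "output_dir")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) problems <- c(problems, paste0("unknown top-level key(s): ",
                                                  paste(bad, collapse = ", ")))
  has_syn <- !is.null(raw$synthetic)
  has_inp <- !is.null(raw$inputs)
  if (has_syn == has_inp) {
    problems <- c(problems, "exactly one of 'synthetic' or 'inputs' must be present")
  }
  cfg <- list()
  if (has_syn) {
    syn <- utils::modifyList(default_synthetic(), as.list(raw$synthetic))
    bad <- setdiff(names(raw$synthetic), names(default_synthetic()))
    if (length(bad)) problems <- c(problems, paste0("synthetic: unknown key(s): ",
                                                    paste(bad, collapse = ", ")))
    cfg$synthetic <- syn
  }
  if (has_inp) {
    inp <- as.list(raw$inputs)
    need <- c("curve_active_pfs", "risk_active_pfs", "curve_active_os",
              "risk_active_os", "curve_control_pfs", "risk_control_pfs",
              "curve_control_os", "risk_control_os")
    miss <- setdiff(need, names(inp))
    if (length(miss)) problems <- c(problems, paste0("inputs: missing path(s): ",
                                                     paste(miss, collapse = ", ")))
    for (nm in intersect(need, names(inp))) {
      if (!file.exists(inp[[nm]])) {
        problems <- c(problems, paste0("inputs$", nm, ": file not found: ", inp[[nm]]))
      }
    }
    cfg$inputs <- inp
  }
  params <- tryCatch(do.call(ce_params, as.list(raw$params %||% list())),
                     error = function(e) {
                       problems <<- c(problems, paste0("params: ", conditionMessage(e)))
                       NULL
                     })
  ana <- utils::modifyList(default_analysis(), as.list(raw$analysis %||% list()))
  bad <- setdiff(names(raw$analysis %||% list()), names(default_analysis()))
  if (length(bad)) problems <- c(problems, paste0("analysis: unknown key(s): ",
                                                  paste(bad, collapse = ", ")))
  if (ana$wtp < 0) problems <- c(problems, "analysis$wtp: must be >= 0")
  if (ana$psa_n < 1) problems <- c(problems, "analysis$psa_n: must be >= 1")
  if (any(ana$scenario_discounts < 0 | ana$scenario_discounts > 1)) {
    problems <- c(problems, "analysis$scenario_discounts: must lie in [0, 1]")
  }
  if (length(problems)) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  cfg$params <- params
  cfg$analysis <- ana
  cfg$output_dir <- raw$output_dir %||% NULL
  structure(cfg, class = "ce_config")
}

#' Write a configuration back to JSON
#'
#' Round-trips with [load_config()]: loading, dumping and re-loading yields an
#' identical configuration.
#'
#' @param config a `ce_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  out <- list()
  if (!is.null(config$synthetic)) out$synthetic <- config$synthetic
  if (!is.null(config$inputs)) out$inputs <- config$inputs
  out$params <- unclass(config$params)
  out$analysis <- config$analysis
  if (!is.null(config$output_dir)) out$output_dir <- config$output_dir
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Generate (or read) digitized curve + risk fixtures and reconstruct IPD for
# every arm/endpoint; returns list(ipd = list(active = list(pfs, os), ...)).
pipeline_ipd <- function(config) {
  arms <- c("active", "control")
  eps <- c("pfs", "os")
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    design <- trial_design(syn$n_total, unlist(syn$allocation),
                           syn$censor_time, syn$seed)
    n_by_arm <- c(active = design$n_active, control = design$n_control)
    read_times <- seq(0, syn$censor_time, by = syn$read_step)
    risk_times <- seq(0, syn$censor_time, by = syn$risk_step)
    out <- purrr::map(arms, function(arm) {
      purrr::map(eps, function(ep) {
        wp <- calibrate_to_median(syn$medians[[arm]][[ep]], syn$shapes[[ep]])
        fx <- gen_digitized_fixture(wp, read_times, n_by_arm[[arm]],
                                    risk_times = risk_times)
        reconstruct_ipd(fx$curve, fx$risk, arm = arm, endpoint = toupper(ep))
      }) |> setNames(eps)
    }) |> setNames(arms)
    return(out)
  }
  purrr::map(arms, function(arm) {
    purrr::map(eps, function(ep) {
      curve <- readr::read_csv(config$inputs[[paste0("curve_", arm, "_", ep)]],
                               show_col_types = FALSE)
      risk <- readr::read_csv(config$inputs[[paste0("risk_", arm, "_", ep)]],
                              show_col_types = FALSE)
      reconstruct_ipd(curve, risk, arm = arm, endpoint = toupper(ep))
    }) |> setNames(eps)
  }) |> setNames(arms)
}

#' Run the full analysis pipeline
#'
#' Chains every stage: simulate a synthetic trial (or load digitized inputs),
#' reconstruct pseudo-IPD, fit the five parametric families per arm and
#' endpoint and select by AIC/BIC, run the cohort model on both arms, and
#' perform the economic analyses (base-case ICER, tornado, PSA, CEAC, price
#' scenarios, threshold price). When `output_dir` is set, writes
#' `results.json`, `trace_active.csv`, `trace_control.csv`, `ipd.csv`,
#' `fits.json` and `log.txt`.
#'
#' @param config a `ce_config` from [load_config()], or a path to one.
#' @return A `ce_pipeline` list: `ipd`, `fits`, `selection`, `results`
#'   (per-arm totals), `base_case`, `tornado`, `psa`, `ceac`, `scenarios`,
#'   `threshold`, `traces`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "ce_config"))
  params <- config$params
  ana <- config$analysis

  ipd <- pipeline_ipd(config)
  fits <- purrr::map(ipd, function(arm_ipd) {
    purrr::map(arm_ipd, function(x) {
      select_model(fit_all_distributions(x))
    })
  })
  selection <- purrr::imap_dfr(fits, function(arm_fits, arm) {
    purrr::imap_dfr(arm_fits, function(f, ep) {
      dplyr::mutate(attr(f, "criteria"), arm = arm, endpoint = toupper(ep),
                    selected = .data$family == f$family)
    })
  })

  traces <- list(
    active = build_trace(fits$active, params, "active"),
    control = build_trace(fits$control, params, "control")
  )
  results <- dplyr::bind_rows(
    accrue(traces$active, params),
    accrue(traces$control, params)
  )
  base_case <- icer(results)
  tor <- tornado(fits$active, fits$control, params)
  psa <- run_psa(ana$psa_n, ana$psa_seed, fits$active, fits$control,
                 params, wtp = ana$wtp, sd_frac = ana$psa_sd_frac)
  ceac_tbl <- ceac(psa, wtp_grid = ana$ceac_grid)
  scenarios <- price_scenario(results, ana$scenario_discounts)
  threshold <- threshold_price(results, ana$wtp)

  bundle <- structure(
    list(ipd = ipd, fits = fits, selection = selection, results = results,
         base_case = base_case, tornado = tor, psa = psa, ceac = ceac_tbl,
         scenarios = scenarios, threshold = threshold, traces = traces,
         params = params, analysis = ana),
    class = "ce_pipeline"
  )
  if (!is.null(config$output_dir)) write_pipeline_outputs(bundle, config)
  bundle
}

write_pipeline_outputs <- function(bundle, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  results_json <- list(
    base_case = list(
      arms = dplyr::select(bundle$results, "arm", "cost", "ly", "qaly"),
      incremental = list(cost = bundle$base_case$delta_cost,
                         ly = bundle$base_case$delta_ly,
                         qaly = bundle$base_case$delta_qaly),
      icer_per_qaly = bundle$base_case$icer_per_qaly,
      icer_per_ly = bundle$base_case$icer_per_ly
    ),
    tornado = as.data.frame(bundle$tornado),
    psa = as.list(bundle$psa$summary),
    ceac = bundle$ceac,
    scenarios = bundle$scenarios,
    threshold = as.list(bundle$threshold)
  )
  jsonlite::write_json(results_json, out("results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (arm in c("active", "control")) {
    tr <- bundle$traces[[arm]]
    acc <- attr(accrue(tr, bundle$params), "cycles")
    full <- dplyr::left_join(tr, dplyr::select(acc, "cycle", "cost_disc",
                                               "ly_disc", "qaly_disc"),
                             by = "cycle")
    readr::write_csv(full, out(paste0("trace_", arm, ".csv")))
  }
  readr::write_csv(dplyr::bind_rows(purrr::map(bundle$ipd, dplyr::bind_rows)),
                   out("ipd.csv"))
  jsonlite::write_json(
    purrr::map(bundle$fits, function(af) purrr::map(af, function(f) {
      list(family = f$family, params = as.list(f$params), loglik = f$loglik,
           aic = f$aic, bic = f$bic, n = f$n, converged = f$converged)
    })),
    out("fits.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c(
    paste0("sclccea version: ", as.character(packageVersion("sclccea"))),
    paste0("R version: ", R.version.string),
    paste0("psa_seed: ", bundle$analysis$psa_seed),
    if (!is.null(config$synthetic)) paste0("synthetic seed: ", config$synthetic$seed),
    paste0("secondline_cycles (PD1 tunnel length): ", bundle$params$secondline_cycles),
    paste0("secondline_irinotecan_share: ", bundle$params$secondline_irinotecan_share),
    paste0("background_mortality_annual: ", bundle$params$background_mortality_annual),
    "AE burden: one-off at model entry; disutility duration one cycle"
  )
  writeLines(log_lines, out("log.txt"))
  invisible(config$output_dir)
}

#' @export
print.ce_pipeline <- function(x, ...) {
  cat("<ce_pipeline>\n")
  print(x$results)
  cat(sprintf("ICER: %.0f USD/QALY (%s)\n",
              x$base_case$icer_per_qaly, x$base_case$status))
  cat(sprintf("PSA: prob CE at WTP %.0f = %.3f\n",
              x$psa$summary$wtp, x$psa$summary$prob_ce))
  invisible(x)
}
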