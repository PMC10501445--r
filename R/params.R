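#' Base-case model parameters
#'
#' Builds the full parameter set of the cost-effectiveness model with the
#' base-case values used throughout: per-cycle drug acquisition costs,
#' adverse-event (AE) management costs, health-state utilities and AE
#' disutilities, grade >= 3 AE risks per arm, the annual discount rate, the
#' model time horizon, cohort demographics used for dose auditing, and the
#' willingness-to-pay (WTP) threshold (three times China's 2022 per-capita
#' GDP). All monetary values are 2022 USD; times are months unless the name
#' says otherwise.
#'
#' Any field can be overridden by name. Structural settings that the source
#' evidence does not pin down are exposed the same way: the number of
#' second-line ("tunnel") cycles spent in first progression before moving to
#' best supportive care (`secondline_cycles`), the irinotecan share of the
#' second-line chemotherapy mix (`secondline_irinotecan_share`), the shares of
#' progressed patients who continue immunotherapy/placebo
#' (`immuno_share_active`, `immuno_share_control`), and the background annual
#' mortality probability (`background_mortality_annual`).
#'
#' @param ... named overrides of any default listed below.
#'
#' @return An object of class `ce_params`: a named list of scalar parameters.
#' @examples
#' p <- ce_params()
#' p$utility_pfs
#' ce_params(discount_annual = 0, horizon_years = 2)$horizon_years
#' @export
ce_params <- function(...) {
  defaults <- list(
    # per-cycle treatment costs (USD / 21-day cycle)
    cost_serplulimab = 2382.65,
    cost_etoposide   = 362.36,
    cost_irinotecan  = 312.03,
    cost_carboplatin = 55.41,
    cost_bsc         = 344.76,
    cost_followup    = 87.42,
    # one-off grade >=3 AE management costs (USD / episode)
    cost_ae_anemia     = 533.61,
    cost_ae_wbc        = 489.30,
    cost_ae_neutrophil = 88.42,
    cost_ae_platelet   = 1106.70,
    # health-state utilities
    utility_pfs   = 0.673,
    utility_pd    = 0.473,
    utility_death = 0,
    # AE disutilities (applied for one cycle at model entry)
    disutility_anemia     = 0.073,
    disutility_wbc        = 0.200,
    disutility_neutrophil = 0.200,
    disutility_platelet   = 0.190,
    # grade >=3 AE risks, serplulimab arm
    risk_anemia_active     = 0.054,
    risk_wbc_active        = 0.085,
    risk_neutrophil_active = 0.141,
    risk_platelet_active   = 0.062,
    # grade >=3 AE risks, placebo arm
    risk_anemia_control     = 0.056,
    risk_wbc_control        = 0.087,
    risk_neutrophil_control = 0.138,
    risk_platelet_control   = 0.082,
    # discounting and horizon
    discount_annual = 0.05,
    horizon_years   = 7.44,
    cycle_days      = 21,
    # treatment pathway structure
    induction_cycles            = 4,
    secondline_cycles           = 4,
    secondline_irinotecan_share = 0.5,
    immuno_share_active  = 0.5523,
    immuno_share_control = 0.5023,
    background_mortality_annual = 0.00718,
    # cohort demographics (dose auditing)
    weight_kg              = 65,
    bsa_m2                 = 1.72,
    serum_creatinine_mg_dl = 1,
    age_years              = 61.1,
    # decision threshold
    wtp_per_qaly = 37423
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  validate_ce_params(structure(defaults, class = "ce_params"))
}

validate_ce_params <- function(p) {
  problems <- character()
  num1 <- function(field) {
    x <- p[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
      problems <<- c(problems, paste0(field, ": must be a single number"))
      FALSE
    } else TRUE
  }
  reg <- param_registry()
  for (nm in reg$name[reg$class == "cost"]) {
    if (num1(nm) && p[[nm]] < 0) problems <- c(problems, paste0(nm, ": cost must be >= 0"))
  }
  for (nm in c(reg$name[reg$class %in% c("utility", "probability")], "utility_death")) {
    if (num1(nm) && (p[[nm]] < 0 || p[[nm]] > 1)) {
      problems <- c(problems, paste0(nm, ": must lie in [0, 1]"))
    }
  }
  for (nm in c("horizon_years", "cycle_days", "weight_kg", "bsa_m2",
               "serum_creatinine_mg_dl", "age_years", "induction_cycles",
               "secondline_cycles")) {
    if (num1(nm) && p[[nm]] <= 0) problems <- c(problems, paste0(nm, ": must be > 0"))
  }
  if (num1("discount_annual") && p$discount_annual < 0) {
    problems <- c(problems, "discount_annual: must be >= 0")
  }
  if (num1("wtp_per_qaly") && p$wtp_per_qaly < 0) {
    problems <- c(problems, "wtp_per_qaly: must be >= 0")
  }
  if (length(problems)) {
    abort(paste0("invalid model parameters:\n", paste0("  - ", problems, collapse = "\n")))
  }
  p
}

# Registry of every parameter varied in sensitivity analyses, with its
# distributional class for the PSA (cost -> Gamma, utility/probability -> Beta)
# and its one-way range (costs/utilities/probabilities +-20%; discount and
# horizon use their stated special ranges).
param_registry <- function() {
  cost <- c("cost_serplulimab", "cost_etoposide", "cost_irinotecan",
            "cost_carboplatin", "cost_bsc", "cost_followup",
            "cost_ae_anemia", "cost_ae_wbc", "cost_ae_neutrophil",
            "cost_ae_platelet")
  utility <- c("utility_pfs", "utility_pd",
               "disutility_anemia", "disutility_wbc",
               "disutility_neutrophil", "disutility_platelet")
  probability <- c("risk_anemia_active", "risk_wbc_active",
                   "risk_neutrophil_active", "risk_platelet_active",
                   "risk_anemia_control", "risk_wbc_control",
                   "risk_neutrophil_control", "risk_platelet_control",
                   "immuno_share_active", "immuno_share_control",
                   "background_mortality_annual")
  tibble(
    name  = c(cost, utility, probability, "discount_annual", "horizon_years"),
    class = c(rep("cost", length(cost)), rep("utility", length(utility)),
              rep("probability", length(probability)), "special", "special")
  )
}

# One-way sensitivity ranges: +-20% except discount (0-8%) and horizon
# (2.00-7.44 years).
oneway_ranges <- function(params) {
  reg <- param_registry()
  reg |>
    dplyr::mutate(
      base = purrr::map_dbl(.data$name, ~ params[[.x]]),
      low  = dplyr::if_else(.data$name == "discount_annual", 0,
             dplyr::if_else(.data$name == "horizon_years", 2.00, .data$base * 0.8)),
      high = dplyr::if_else(.data$name == "discount_annual", 0.08,
             dplyr::if_else(.data$name == "horizon_years", 7.44, .data$base * 1.2))
    )
}

#' @export
print.ce_params <- function(x, ...) {
  cat("<ce_params> ", length(x), " parameters\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a parameter set into a two-column tibble
#'
#' @param x a [ce_params()] object.
#' @param ... unused.
#' @return A tibble with columns `parameter` and `value`.
#' @exportS3Method
tidy.ce_params <- function(x, ...) {
  tibble(parameter = names(x), value = unlist(x, use.names = FALSE))
}
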