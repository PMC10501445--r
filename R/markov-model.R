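#' @title Four-state cohort state-transition engine
#' @description States: progression-free (PFS), first progression (PD1, a
#'   second-line treatment "tunnel"), second-and-later progression (PD2+, best
#'   supportive care), and death. Transitions are derived per 21-day cycle
#'   from fitted PFS and OS curves; accruals use a half-cycle correction and
#'   annual discounting.
#' @name markov-model
NULL

# months per 21-day model cycle
cycle_months <- function(cycle_days = 21) cycle_days * 12 / 365.25

#' Per-cycle progression probability from the PFS curve
#'
#' Probability of leaving progression-free survival during a cycle,
#' `(P(t) - P(t + 1)) / P(t)` with `P` the PFS survival function at successive
#' cycle boundaries. An empty PFS state (`P(t) = 0`) progresses nobody.
#'
#' @param p_t PFS survival at the cycle start.
#' @param p_next PFS survival at the cycle end; must not exceed `p_t`.
#' @return Progression probability in \[0, 1\] (vectorized).
#' @examples
#' prob_progress(1, 0.9195)  # 0.0805
#' @export
prob_progress <- function(p_t, p_next) {
  if (any(p_t < 0 | p_t > 1 | p_next < 0)) abort("survival probabilities must lie in [0, 1]")
  if (any(p_next > p_t + 1e-12)) abort("p_next must not exceed p_t (PFS is non-increasing)")
  ifelse(p_t == 0, 0, pmin(pmax((p_t - p_next) / p_t, 0), 1))
}

#' Per-cycle death probability for progressed patients
#'
#' Deaths over a cycle all occur in the progressed states, so the conditional
#' death probability there is the OS decrement over the cycle divided by the
#' progressed occupancy implied by the two curves:
#' `(O(t) - O(t+1)) / (O(t) - P(t))`. Values outside \[0, 1\] (possible when
#' digitized curves cross or nearly touch) are clipped with a warning; an
#' empty progressed state (`O(t) - P(t)` below `1e-12`) returns 0 with a
#' warning.
#'
#' @param p_t PFS survival at the cycle start.
#' @param o_t,o_next OS survival at the cycle start and end.
#' @return Death probability in \[0, 1\] (vectorized).
#' @examples
#' prob_pd_death(0.4, 0.8, 0.7)  # 0.25
#' @export
prob_pd_death <- function(p_t, o_t, o_next) {
  denom <- o_t - p_t
  raw <- ifelse(denom < 1e-12, 0, (o_t - o_next) / denom)
  if (any(denom < 1e-12 & (o_t - o_next) > 1e-12)) {
    warn("empty progressed state: Prob(PD -> death) set to 0 where O(t) - P(t) < 1e-12",
         class = "sclccea_pd_warning")
  }
  if (any(raw < -1e-12 | raw > 1 + 1e-12)) {
    warn("Prob(PD -> death) outside [0, 1] (crossing curves); value clipped",
         class = "sclccea_pd_warning")
  }
  pmin(pmax(raw, 0), 1)
}

# Evaluate expr, collapsing engine warnings (PD clipping etc.) into one
# summary warning — used by loops that re-run the model many times with the
# same fixed survival curves.
collapse_pd_warnings <- function(expr) {
  msgs <- character()
  out <- withCallingHandlers(expr, sclccea_pd_warning = function(w) {
    msgs <<- unique(c(msgs, conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
  if (length(msgs)) {
    warn(paste0("model engine (repeated across runs): ",
                paste(msgs, collapse = "; ")))
  }
  out
}

#' Convert an annual mortality probability to a per-cycle probability
#'
#' @param annual_prob annual probability of death in `[0, 1)`.
#' @param cycle_days model cycle length in days.
#' @return Per-cycle probability `1 - (1 - annual_prob)^(cycle_days/365.25)`.
#' @examples
#' background_mortality_cycle(0.00718)
#' @export
background_mortality_cycle <- function(annual_prob, cycle_days = 21) {
  if (any(annual_prob < 0 | annual_prob >= 1)) abort("annual_prob must lie in [0, 1)")
  1 - (1 - annual_prob)^(cycle_days / 365.25)
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-administration drug doses implied by the cohort demographics
#'
#' Audit helper: serplulimab 4.5 mg/kg; etoposide 100 mg/m2 on days 1-3;
#' carboplatin dosed to AUC 5 mg/mL/min by the Calvert formula with creatinine
#' clearance from Cockcroft-Gault (male form, serum creatinine in mg/dL). All
#' doses rounded to the nearest milligram (half-up). Cycle costs in
#' [ce_params()] are taken as given; this function exists for unit-price
#' workflows and cross-checks.
#'
#' @param params a [ce_params()] object supplying `weight_kg`, `bsa_m2`,
#'   `serum_creatinine_mg_dl`, `age_years`.
#' @return A tibble `drug`, `dose_mg` (per administration), `admins_per_cycle`,
#'   `mg_per_cycle`.
#' @examples
#' compute_doses(ce_params())
#' @export
compute_doses <- function(params = ce_params()) {
  crcl <- (140 - params$age_years) * params$weight_kg /
    (72 * params$serum_creatinine_mg_dl)
  tibble(
    drug = c("serplulimab", "etoposide", "carboplatin"),
    dose_mg = c(
      round_half_up(4.5 * params$weight_kg),
      round_half_up(100 * params$bsa_m2),
      round_half_up(5 * (crcl + 25))
    ),
    admins_per_cycle = c(1, 3, 1)
  ) |>
    dplyr::mutate(mg_per_cycle = .data$dose_mg * .data$admins_per_cycle)
}

# Core occupancy recursion on precomputed survival vectors. P, O are survival
# at cycle boundaries 0..n_cycles; returns occupancy matrix with rows
# 0..n_cycles.
trace_engine <- function(P, O, p_bg, K, n_cycles) {
  p_prog <- prob_progress(P[-length(P)], P[-1])
  # cycle 1 starts with an empty progressed state by construction (the whole
  # cohort enters progression-free), so no PD death probability is defined yet
  p_ptd <- if (n_cycles >= 2) {
    c(0, prob_pd_death(P[2:n_cycles], O[2:n_cycles], O[3:(n_cycles + 1)]))
  } else 0
  # PFS exits: background mortality keeps its floor; progression renormalized
  over <- p_prog + p_bg > 1
  if (any(over)) {
    warn("PFS exit probabilities exceed 1; progression renormalized")
    p_prog[over] <- 1 - p_bg
  }
  pfs <- 1; pd1 <- numeric(K); pd2 <- 0; death <- 0
  occ <- matrix(0, n_cycles + 1, 4,
                dimnames = list(NULL, c("pfs", "pd1", "pd2", "death")))
  occ[1, ] <- c(1, 0, 0, 0)
  for (k in seq_len(n_cycles)) {
    stay <- 1 - p_ptd[k]
    new_pd1 <- c(pfs * p_prog[k], pd1[-K] * stay)
    new_pd2 <- (pd2 + pd1[K]) * stay
    death <- death + pfs * p_bg + (sum(pd1) + pd2) * p_ptd[k]
    pfs <- pfs * (1 - p_prog[k] - p_bg)
    pd1 <- new_pd1
    pd2 <- new_pd2
    occ[k + 1, ] <- c(pfs, sum(pd1), pd2, death)
  }
  occ
}

#' Run the cohort through the state-transition model
#'
#' The cohort enters 100% progression-free. Each 21-day cycle: PFS moves to
#' first progression with [prob_progress()] from the PFS fit and to death with
#' the background mortality per cycle; both progressed states move to death
#' with [prob_pd_death()] from the two fits; first-progression residents
#' advance to PD2+ (best supportive care) after `secondline_cycles` cycles;
#' death is absorbing. The number of cycles is
#' `floor(horizon_years * 365.25 / 21)`.
#'
#' @param fits list with elements `pfs` and `os`, each a `parsurv_fit`.
#' @param params a [ce_params()] object.
#' @param arm `"active"` or `"control"` (label carried into the trace).
#' @return A `ce_trace` tibble: `cycle`, `t_months`, `t_years`, `occ_pfs`,
#'   `occ_pd1`, `occ_pd2`, `occ_death`.
#' @examples
#' fits <- list(pfs = weibull_fit(log(2) / 5.7, 1.2),
#'              os  = weibull_fit(log(2) / 15.4, 1.0))
#' tr <- build_trace(fits, ce_params(), arm = "active")
#' head(tr)
#' @export
build_trace <- function(fits, params, arm = c("active", "control")) {
  arm <- match.arg(arm)
  n_cycles <- n_model_cycles(params)
  cm <- cycle_months(params$cycle_days)
  t_bound <- (0:n_cycles) * cm
  P <- survival_at(fits$pfs, t_bound)
  O <- survival_at(fits$os, t_bound)
  p_bg <- background_mortality_cycle(params$background_mortality_annual,
                                     params$cycle_days)
  occ <- trace_engine(P, O, p_bg, params$secondline_cycles, n_cycles)
  structure(
    tibble(
      cycle = 0:n_cycles,
      t_months = t_bound,
      t_years = t_bound / 12,
      occ_pfs = occ[, "pfs"], occ_pd1 = occ[, "pd1"],
      occ_pd2 = occ[, "pd2"], occ_death = occ[, "death"]
    ),
    arm = arm, class = c("ce_trace", class(tibble())))
}

n_model_cycles <- function(params) {
  as.integer(floor(params$horizon_years * 365.25 / params$cycle_days))
}

# Per-cycle unit costs for one arm, length n_cycles each.
arm_cycle_costs <- function(params, arm, n_cycles) {
  serp <- params$cost_serplulimab
  chemo <- params$cost_etoposide + params$cost_carboplatin
  induction <- seq_len(n_cycles) <= params$induction_cycles
  drug_pfs <- if (arm == "active") {
    ifelse(induction, serp + chemo, serp)
  } else {
    ifelse(induction, chemo, 0)
  }
  mix <- params$secondline_irinotecan_share
  secondline <- mix * (params$cost_irinotecan + params$cost_carboplatin) +
    (1 - mix) * (params$cost_etoposide + params$cost_carboplatin)
  immuno <- if (arm == "active") params$immuno_share_active * serp else 0
  list(
    pfs = drug_pfs + params$cost_followup,
    pd1 = rep(secondline + immuno + params$cost_followup, n_cycles),
    pd2 = rep(params$cost_bsc, n_cycles),
    # serplulimab-attributable share, for price scenarios
    serp_pfs = if (arm == "active") rep(serp, n_cycles) else rep(0, n_cycles),
    serp_pd1 = rep(immuno, n_cycles)
  )
}

arm_ae <- function(params, arm) {
  sfx <- if (arm == "active") "_active" else "_control"
  risks <- unlist(params[paste0(c("risk_anemia", "risk_wbc", "risk_neutrophil",
                                  "risk_platelet"), sfx)])
  costs <- unlist(params[c("cost_ae_anemia", "cost_ae_wbc",
                           "cost_ae_neutrophil", "cost_ae_platelet")])
  disut <- unlist(params[c("disutility_anemia", "disutility_wbc",
                           "disutility_neutrophil", "disutility_platelet")])
  list(cost = sum(risks * costs), disutility = sum(risks * disut))
}

#' Accrue costs, life-years and QALYs over a cohort trace
#'
#' Applies the half-cycle correction (every accrual is weighted by the mean of
#' adjacent-boundary occupancies), per-cycle costing by state and treatment
#' phase (induction combination for the first `induction_cycles` cycles, then
#' maintenance; second-line chemotherapy plus the continued-immunotherapy
#' share in first progression; best supportive care afterwards; routine
#' follow-up while on treatment), a one-off adverse-event cost and QALY
#' decrement at model entry, and annual discounting at `discount_annual`
#' with model time measured at cycle start.
#'
#' @param trace a [build_trace()] result.
#' @param params a [ce_params()] object (the same one used for the trace).
#' @param arm `"active"` or `"control"`; defaults to the trace's arm.
#' @return A one-row `ce_result` tibble: `arm`, `cost`, `ly`, `qaly`
#'   (discounted), `cost_undisc`, `ly_undisc`, `qaly_undisc`, and
#'   `cost_serplulimab` (the discounted serplulimab-attributable cost, 0 for
#'   the control arm). Per-cycle accruals are attached as attribute
#'   `"cycles"`.
#' @export
accrue <- function(trace, params, arm = attr(trace, "arm")) {
  n_cycles <- nrow(trace) - 1
  cyc_years <- params$cycle_days / 365.25
  avg <- function(x) (x[-length(x)] + x[-1]) / 2
  a_pfs <- avg(trace$occ_pfs); a_pd1 <- avg(trace$occ_pd1)
  a_pd2 <- avg(trace$occ_pd2)
  disc <- (1 + params$discount_annual)^(-(seq_len(n_cycles) - 1) * cyc_years)

  uc <- arm_cycle_costs(params, arm, n_cycles)
  ae <- arm_ae(params, arm)
  cost_cycle <- a_pfs * uc$pfs + a_pd1 * uc$pd1 + a_pd2 * uc$pd2
  cost_cycle[1] <- cost_cycle[1] + ae$cost
  serp_cycle <- a_pfs * uc$serp_pfs + a_pd1 * uc$serp_pd1

  alive <- a_pfs + a_pd1 + a_pd2
  ly_cycle <- alive * cyc_years
  qaly_cycle <- (a_pfs * params$utility_pfs +
                 (a_pd1 + a_pd2) * params$utility_pd) * cyc_years
  qaly_cycle[1] <- qaly_cycle[1] - ae$disutility * cyc_years

  cycles <- tibble(
    cycle = seq_len(n_cycles),
    t_years = (seq_len(n_cycles) - 1) * cyc_years,
    cost = cost_cycle, ly = ly_cycle, qaly = qaly_cycle,
    cost_disc = cost_cycle * disc, ly_disc = ly_cycle * disc,
    qaly_disc = qaly_cycle * disc
  )
  out <- tibble(
    arm = arm,
    cost = sum(cycles$cost_disc),
    ly = sum(cycles$ly_disc),
    qaly = sum(cycles$qaly_disc),
    cost_undisc = sum(cycles$cost),
    ly_undisc = sum(cycles$ly),
    qaly_undisc = sum(cycles$qaly),
    cost_serplulimab = sum(serp_cycle * disc)
  )
  attr(out, "cycles") <- cycles
  class(out) <- c("ce_result", class(out))
  out
}

#' Run both arms through the model
#'
#' @param fits_active,fits_control lists with `pfs` and `os` fits per arm.
#' @param params a [ce_params()] object.
#' @return A two-row `ce_result` tibble (active then control), see [accrue()].
#' @export
run_arms <- function(fits_active, fits_control, params = ce_params()) {
  act <- accrue(build_trace(fits_active, params, "active"), params)
  ctl <- accrue(build_trace(fits_control, params, "control"), params)
  out <- dplyr::bind_rows(act, ctl)
  class(out) <- c("ce_result", class(tibble()))
  out
}
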