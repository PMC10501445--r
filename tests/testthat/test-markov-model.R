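test_that("per-cycle transition probabilities follow the curve identities", {
  expect_equal(prob_progress(1, 1), 0)
  expect_equal(prob_progress(0.5, 0), 1)
  expect_equal(prob_progress(1, 0.9195), 0.0805, tolerance = 1e-12)
  expect_equal(prob_progress(0, 0), 0)  # empty state progresses nobody
  expect_error(prob_progress(0.5, 0.6), "non-increasing")

  expect_equal(prob_pd_death(0.4, 0.8, 0.7), 0.25)
  expect_equal(prob_pd_death(0.4, 0.8, 0.8), 0)
  # crossing curves: raw value 1.2 clipped to 1 with a warning
  expect_warning(p <- prob_pd_death(0.75, 0.8, 0.74), "clipped")
  expect_equal(p, 1)
  # empty progressed state: zero with a warning
  expect_warning(p0 <- prob_pd_death(0.8, 0.8, 0.7), "empty progressed")
  expect_equal(p0, 0)
})

test_that("background mortality converts annual to per-cycle probability", {
  expect_equal(background_mortality_cycle(0), 0)
  expect_equal(background_mortality_cycle(0.00718),
               1 - (1 - 0.00718)^(21 / 365.25))
  expect_equal(background_mortality_cycle(0.00718), 4.141e-4, tolerance = 1e-3)
  # inverse identity round-trips the annual probability
  q <- 0.0123
  p_cyc <- background_mortality_cycle(q)
  expect_equal(1 - (1 - p_cyc)^(365.25 / 21), q, tolerance = 1e-12)
  expect_error(background_mortality_cycle(1), "\\[0, 1\\)")
})

test_that("doses follow the dosing rules and Calvert/Cockcroft-Gault", {
  doses <- compute_doses(ce_params())
  expect_equal(doses$dose_mg[doses$drug == "serplulimab"], 293)  # 4.5 * 65 = 292.5, half-up
  expect_equal(doses$dose_mg[doses$drug == "etoposide"], 172)    # 100 * 1.72
  expect_equal(doses$mg_per_cycle[doses$drug == "etoposide"], 516)
  # CrCl = (140 - 61.1) * 65 / 72 = 71.23; dose = 5 * (71.23 + 25)
  crcl <- (140 - 61.1) * 65 / 72
  expect_equal(doses$dose_mg[doses$drug == "carboplatin"], floor(5 * (crcl + 25) + 0.5))
  expect_equal(doses$dose_mg[doses$drug == "carboplatin"], 481)
})

test_that("cohort trace conserves occupancy and absorbs into death", {
  fits <- calibrated_fits()
  tr <- quiet_trace(build_trace(fits$active, ce_params(), "active"))
  expect_equal(nrow(tr), floor(7.44 * 365.25 / 21) + 1)  # 129 cycles + baseline
  occ_sum <- tr$occ_pfs + tr$occ_pd1 + tr$occ_pd2 + tr$occ_death
  expect_true(all(abs(occ_sum - 1) < 1e-9))
  expect_true(all(diff(tr$occ_death) >= -1e-12))
  expect_true(all(as.matrix(tr[, c("occ_pfs", "occ_pd1", "occ_pd2", "occ_death")]) >= -1e-12))
  expect_equal(tr$occ_pfs[1], 1)
})

test_that("with no transitions the cohort stays progression-free for the horizon", {
  null_fit <- weibull_fit(1e-300, 1)  # survival is numerically 1 forever
  fits <- list(pfs = null_fit, os = null_fit)
  p <- ce_params(background_mortality_annual = 0, discount_annual = 0)
  tr <- build_trace(fits, p, "active")
  expect_true(all(tr$occ_pfs == 1))
  res <- accrue(tr, p)
  n_cycles <- floor(7.44 * 365.25 / 21)
  expect_equal(res$ly_undisc, n_cycles * 21 / 365.25, tolerance = 1e-9)
})

test_that("coincident PFS and OS curves leave the progressed states empty", {
  lam <- log(2) / 12
  fits <- list(pfs = weibull_fit(lam * (1 + 1e-9), 1), os = weibull_fit(lam, 1))
  tr <- quiet_trace(build_trace(fits, ce_params(background_mortality_annual = 0),
                                "active"))
  # everyone leaving PFS dies within one cycle of progressing: PD occupancy
  # never exceeds a single cycle's inflow
  max_inflow <- max(-diff(survival_at(fits$pfs, tr$t_months)))
  expect_lt(max(tr$occ_pd1 + tr$occ_pd2), max_inflow + 1e-9)
})

test_that("trace life-years match the closed-form survival integral", {
  # put all mortality on the background channel so PFS occupancy decays
  # exponentially, then compare accrued LY with the exact integral
  q_annual <- 0.2
  p <- ce_params(background_mortality_annual = q_annual, discount_annual = 0,
                 horizon_years = 20)
  null_fit <- weibull_fit(1e-300, 1)
  tr <- build_trace(list(pfs = null_fit, os = null_fit), p, "active")
  res <- accrue(tr, p)
  lam_yr <- -log(1 - q_annual)
  T_yr <- floor(20 * 365.25 / 21) * 21 / 365.25
  expect_equal(res$ly_undisc, (1 - exp(-lam_yr * T_yr)) / lam_yr,
               tolerance = 1e-3)
})

test_that("cohort survival tracks the OS curve when background mortality is off", {
  fits <- list(pfs = weibull_fit(log(2) / 5, 1), os = weibull_fit(log(2) / 15, 1))
  p <- ce_params(background_mortality_annual = 0)
  tr <- quiet_trace(build_trace(fits, p, "active"))
  O <- survival_at(fits$os, tr$t_months)
  # deaths lag the OS decrement by at most one cycle (the progressed state
  # starts empty), so agreement is within the largest single-cycle decrement
  expect_lt(max(abs((1 - tr$occ_death) - O)), max(-diff(O)) + 1e-12)
})

test_that("accruals are linear in costs and monotone in horizon and discount", {
  fits <- calibrated_fits()
  p <- ce_params()
  res <- quiet_trace(run_arms(fits$active, fits$control, p))

  cost_names <- grep("^cost_", names(unclass(p)), value = TRUE)
  doubled <- do.call(ce_params, setNames(lapply(cost_names, function(nm) 2 * p[[nm]]),
                                         cost_names))
  res2 <- quiet_trace(run_arms(fits$active, fits$control, doubled))
  expect_equal(res2$cost, 2 * res$cost, tolerance = 1e-12)
  expect_equal(res2$qaly, res$qaly, tolerance = 1e-12)

  short <- quiet_trace(run_arms(fits$active, fits$control, ce_params(horizon_years = 2)))
  expect_true(all(short$cost <= res$cost & short$ly <= res$ly & short$qaly <= res$qaly))

  undisc <- quiet_trace(run_arms(fits$active, fits$control, ce_params(discount_annual = 0)))
  expect_true(all(res$cost < undisc$cost & res$qaly < undisc$qaly))
  expect_equal(undisc$cost, undisc$cost_undisc, tolerance = 1e-12)
})

test_that("QALYs reduce to LYs under unit utilities and no adverse events", {
  fits <- calibrated_fits()
  risk_names <- grep("^risk_", names(unclass(ce_params())), value = TRUE)
  args <- c(list(utility_pfs = 1, utility_pd = 1),
            setNames(as.list(rep(0, length(risk_names))), risk_names))
  p <- do.call(ce_params, args)
  res <- quiet_trace(run_arms(fits$active, fits$control, p))
  expect_equal(res$qaly, res$ly, tolerance = 1e-12)
  expect_true(all(quiet_trace(run_arms(fits$active, fits$control, ce_params()))$qaly <
                    quiet_trace(run_arms(fits$active, fits$control, ce_params()))$ly))
})

test_that("an empty progressed state accrues only progression-free costs", {
  null_fit <- weibull_fit(1e-300, 1)
  p <- ce_params(cost_etoposide = 0, cost_carboplatin = 0, cost_followup = 0,
                 risk_anemia_control = 0, risk_wbc_control = 0,
                 risk_neutrophil_control = 0, risk_platelet_control = 0,
                 background_mortality_annual = 0)
  tr <- build_trace(list(pfs = null_fit, os = null_fit), p, "control")
  res <- accrue(tr, p)
  expect_equal(res$cost, 0)  # BSC cost never accrues without PD occupancy
})
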