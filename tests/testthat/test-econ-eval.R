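test_that("ICER arithmetic, dominance flags and undefined ratios", {
  a <- ce_result("active", cost = 100, ly = 1.2, qaly = 1.0)
  b <- ce_result("control", cost = 0, ly = 0.6, qaly = 0.5)
  ic <- icer(a, b)
  expect_equal(ic$icer_per_qaly, 200)
  expect_equal(ic$status, "ok")

  dom <- icer(ce_result("active", 50, 1.2, 1.0), ce_result("control", 80, 0.6, 0.5))
  expect_equal(dom$status, "dominant")
  expect_true(is.na(dom$icer_per_qaly))

  dted <- icer(ce_result("active", 90, 0.5, 0.4), ce_result("control", 80, 0.6, 0.5))
  expect_equal(dted$status, "dominated")

  undef <- icer(ce_result("active", 90, 0.6, 0.5), ce_result("control", 80, 0.6, 0.5))
  expect_equal(undef$status, "undefined")

  expect_error(ce_result("active", 10, 0.5, 0.6), "qaly cannot exceed ly")
})

test_that("NMB identities: sign agrees with ICER vs WTP whenever dQ > 0", {
  expect_equal(nmb(ce_result("x", 120, 1, 0.8), 0), -120)
  withr::with_seed(99, {
    for (i in 1:50) {
      ca <- runif(1, 0, 5e4); cc <- runif(1, 0, 5e4)
      qa <- runif(1, 0.5, 2); qc <- runif(1, 0.1, qa - 0.01)
      wtp <- runif(1, 1, 1e5)
      a <- ce_result("active", ca, qa + 1, qa)
      b <- ce_result("control", cc, qc + 1, qc)
      inmb <- nmb(a, wtp) - nmb(b, wtp)
      ic <- icer(a, b)
      if (ic$status == "ok") {
        expect_equal(inmb > 0, ic$icer_per_qaly < wtp)
      }
    }
  })
  # the published scenario row: dQ implied by the ICER, dC = 26,402
  dq <- 26402 / 179161
  inmb <- 37423 * dq - 26402
  expect_equal(inmb, -20887, tolerance = 1e-3)
})

test_that("price scenarios are affine in the discount and reproduce bounds", {
  res <- derived_results()
  sc <- price_scenario(res, c(0, 0.25, 0.5, 0.75, 1))
  # d = 0 leaves the base case untouched
  expect_equal(sc$icer_per_qaly[1], icer(res)$icer_per_qaly)
  # strictly decreasing in d while dQ > 0
  expect_true(all(diff(sc$icer_per_qaly) < 0))
  # three-point collinearity: ICER is affine in d
  slope1 <- (sc$icer_per_qaly[2] - sc$icer_per_qaly[1]) / 0.25
  slope2 <- (sc$icer_per_qaly[4] - sc$icer_per_qaly[2]) / 0.50
  expect_equal(slope1, slope2, tolerance = 1e-9)
  expect_error(price_scenario(res, 1.2), "\\[0, 1\\]")
})

test_that("threshold price: bisection agrees with the closed form and round-trips", {
  res <- derived_results()
  wtp <- 37423
  thr_b <- threshold_price(res, wtp)
  thr_c <- threshold_price(res, wtp, method = "closed_form")
  expect_equal(thr_b$status, "ok")
  expect_equal(thr_b$discount, thr_c$discount, tolerance = 1e-8)
  # plugging the root back reproduces the threshold
  expect_equal(price_scenario(res, thr_b$discount)$icer_per_qaly, wtp,
               tolerance = wtp * 1e-6)
  # bracket violations return statuses, not roots
  expect_equal(threshold_price(res, 1e9)$status, "no_discount_needed")
  expect_equal(threshold_price(res, 1)$status, "unreachable")
})

test_that("PSA draws are reproducible and centred on the base case", {
  base <- ce_params()
  d1 <- draw_psa_params(base, seed = 123, index = 7)
  d2 <- draw_psa_params(base, seed = 123, index = 7)
  expect_identical(unclass(d1), unclass(d2))
  expect_false(identical(d1$cost_serplulimab, base$cost_serplulimab))

  # zero dispersion collapses to the base case
  d0 <- draw_psa_params(base, seed = 1, index = 1, sd_frac = 0)
  expect_identical(unclass(d0), unclass(base))

  # CLT check: the mean of many Gamma cost draws is within 2 SE of the mean
  draws <- vapply(1:10000, function(i) {
    draw_psa_params(base, seed = 5, index = i)$cost_serplulimab
  }, numeric(1))
  se <- 0.2 * 2382.65 / sqrt(10000)
  expect_lt(abs(mean(draws) - 2382.65), 2 * se)
  # Beta draws stay inside [0, 1] with the right mean
  utils_draws <- vapply(1:2000, function(i) {
    draw_psa_params(base, seed = 5, index = i)$utility_pfs
  }, numeric(1))
  expect_true(all(utils_draws > 0 & utils_draws < 1))
  expect_lt(abs(mean(utils_draws) - 0.673), 3 * 0.2 * 0.673 / sqrt(2000))
})

test_that("PSA summaries are internally consistent and seed-stable", {
  fits <- calibrated_fits()
  psa1 <- quiet_trace(run_psa(30, seed = 77, fits$active, fits$control))
  psa2 <- quiet_trace(run_psa(30, seed = 77, fits$active, fits$control))
  expect_identical(psa1$samples, psa2$samples)
  expect_identical(psa1$summary, psa2$summary)
  expect_equal(psa1$summary$icer_of_means,
               mean(psa1$samples$delta_cost) / mean(psa1$samples$delta_qaly))

  # a single draw with zero dispersion equals the deterministic base case
  psa0 <- quiet_trace(run_psa(1, seed = 1, fits$active, fits$control, sd_frac = 0))
  base <- quiet_trace(run_arms(fits$active, fits$control))
  expect_equal(psa0$samples$cost_active, base$cost[base$arm == "active"],
               tolerance = 1e-12)
  expect_equal(psa0$samples$delta_qaly,
               diff(rev(base$qaly)), tolerance = 1e-12)
})

test_that("the acceptability curve is a proper probability curve", {
  fits <- calibrated_fits()
  psa <- quiet_trace(run_psa(40, seed = 3, fits$active, fits$control))
  cc <- ceac(psa, wtp_grid = seq(0, 4e5, 5e4))
  expect_true(all(cc$prob_ce >= 0 & cc$prob_ce <= 1))
  # all draws gain QALYs here, so the curve is non-decreasing in WTP
  expect_true(all(psa$samples$delta_qaly > 0))
  expect_true(all(diff(cc$prob_ce) >= 0))
  # limits: at wtp 0 the probability is the fraction of cost-saving draws;
  # at very large wtp it is the fraction of QALY-gaining draws
  expect_equal(cc$prob_ce[1], mean(psa$samples$delta_cost < 0))
  expect_equal(ceac(psa, 1e12)$prob_ce, mean(psa$samples$delta_qaly > 0))
})

test_that("tornado entries bracket the base ICER and rank by spread", {
  fits <- calibrated_fits()
  tor <- suppressWarnings(tornado(fits$active, fits$control, ce_params()))
  expect_true(all(diff(tor$spread) <= 1e-9))
  expect_equal(tor$spread, abs(tor$icer_high - tor$icer_low))
  base_icer <- attr(tor, "base_icer")

  # an active-arm-only cost varied symmetrically straddles the base ICER
  serp <- tor[tor$parameter == "cost_serplulimab", ]
  expect_true(min(serp$icer_low, serp$icer_high) < base_icer &&
                base_icer < max(serp$icer_low, serp$icer_high))
  # serplulimab cost dominates all +-20% parameters
  pm20 <- tor[!tor$parameter %in% c("discount_annual", "horizon_years"), ]
  expect_equal(pm20$parameter[1], "cost_serplulimab")

  # a cost entering both arms with equal risk weights cancels out of the ICER:
  # equalize the anemia risks and vary its management cost
  p_eq <- ce_params(risk_anemia_control = 0.054)
  tor_eq <- suppressWarnings(tornado(fits$active, fits$control, p_eq))
  anemia <- tor_eq[tor_eq$parameter == "cost_ae_anemia", ]
  expect_equal(anemia$spread, 0, tolerance = 1e-9)
})
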