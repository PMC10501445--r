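#' @title Comparative economics
#' @description ICER/NMB, one-way (tornado) sensitivity analysis,
#'   probabilistic sensitivity analysis with Gamma/Beta parameter
#'   distributions, the cost-effectiveness acceptability curve, price-discount
#'   scenarios and threshold-price solving.
#' @name econ-eval
NULL

get_arm <- function(results, arm) {
  row <- results[results$arm == arm, , drop = FALSE]
  if (nrow(row) != 1) abort(paste0("expected exactly one '", arm, "' row"))
  row
}

#' Incremental cost-effectiveness ratio
#'
#' Computes incremental cost, life-years and QALYs of the active versus
#' control arm and the resulting ICERs per QALY and per LY. Dominance is
#' flagged instead of reporting a ratio when the signs differ (`"dominant"`:
#' cheaper and more effective; `"dominated"`: costlier and less effective);
#' an incremental QALY below `1e-12` in magnitude yields status
#' `"undefined"`.
#'
#' @param active,control one-row `ce_result` tibbles (or a single two-row
#'   tibble passed as `active` with `control` omitted).
#' @return A one-row tibble: `delta_cost`, `delta_ly`, `delta_qaly`,
#'   `icer_per_qaly`, `icer_per_ly`, `status`.
#' @examples
#' a <- ce_result("active", cost = 100, ly = 1.2, qaly = 1.0)
#' b <- ce_result("control", cost = 0, ly = 0.6, qaly = 0.5)
#' icer(a, b)$icer_per_qaly  # 200
#' @export
icer <- function(active, control = NULL) {
  if (is.null(control)) {
    control <- get_arm(active, "control")
    active <- get_arm(active, "active")
  }
  dc <- active$cost - control$cost
  dq <- active$qaly - control$qaly
  dl <- active$ly - control$ly
  status <- if (abs(dq) < 1e-12) "undefined"
    else if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else "ok"
  tibble(
    delta_cost = dc, delta_ly = dl, delta_qaly = dq,
    icer_per_qaly = if (status == "ok") dc / dq else NA_real_,
    icer_per_ly = if (status == "ok" && abs(dl) > 1e-12) dc / dl else NA_real_,
    status = status
  )
}

#' Construct a cost-effectiveness result from known totals
#'
#' Wraps per-arm discounted totals as a `ce_result` row, e.g. totals printed
#' in a report. `cost_serplulimab` is the serplulimab-attributable share of
#' `cost`, which price scenarios rescale.
#'
#' @param arm arm label.
#' @param cost,ly,qaly discounted totals (USD, years, QALYs).
#' @param cost_serplulimab serplulimab-attributable discounted cost.
#' @return A one-row `ce_result` tibble.
#' @export
ce_result <- function(arm, cost, ly, qaly, cost_serplulimab = 0) {
  if (qaly > ly + 1e-9) abort("qaly cannot exceed ly")
  out <- tibble(arm = arm, cost = cost, ly = ly, qaly = qaly,
                cost_undisc = NA_real_, ly_undisc = NA_real_,
                qaly_undisc = NA_real_, cost_serplulimab = cost_serplulimab)
  class(out) <- c("ce_result", class(out))
  out
}

#' Net monetary benefit
#'
#' @param result a `ce_result` row (or multi-row tibble; vectorized).
#' @param wtp willingness-to-pay per QALY (>= 0).
#' @return `wtp * qaly - cost`, in USD.
#' @export
nmb <- function(result, wtp) {
  if (any(wtp < 0)) abort("wtp must be >= 0")
  wtp * result$qaly - result$cost
}

#' Rescale the serplulimab price in a pair of arm results
#'
#' Total cost is affine in the serplulimab unit price, with slope equal to the
#' discounted serplulimab-attributable spend, so arm totals under a different
#' price are obtained exactly without re-running the model.
#'
#' @param results a two-row `ce_result` tibble with a `cost_serplulimab`
#'   column.
#' @param factor multiplier on the serplulimab price (>= 0); a price discount
#'   `d` corresponds to `factor = 1 - d`.
#' @return The rescaled `ce_result` tibble.
#' @export
scale_serp_price <- function(results, factor) {
  if (factor < 0) abort("price factor must be >= 0")
  dplyr::mutate(results,
    cost = .data$cost + (factor - 1) * .data$cost_serplulimab,
    cost_undisc = NA_real_,
    cost_serplulimab = factor * .data$cost_serplulimab
  )
}

#' Price-discount scenario analysis
#'
#' Re-evaluates the comparison with the serplulimab price reduced by each
#' discount fraction (everywhere the drug enters: induction, maintenance, and
#' the post-progression continuation share).
#'
#' @param results base-case two-row `ce_result` tibble.
#' @param discounts vector of price-discount fractions in \[0, 1\].
#' @return A tibble with one row per discount: `discount`, `cost_active`,
#'   `delta_cost`, `delta_qaly`, `icer_per_qaly`, `status`.
#' @export
price_scenario <- function(results, discounts) {
  if (any(discounts < 0 | discounts > 1)) abort("discounts must lie in [0, 1]")
  purrr::map_dfr(discounts, function(d) {
    res <- scale_serp_price(results, 1 - d)
    ic <- icer(res)
    tibble(discount = d,
           cost_active = get_arm(res, "active")$cost,
           delta_cost = ic$delta_cost, delta_qaly = ic$delta_qaly,
           icer_per_qaly = ic$icer_per_qaly, status = ic$status)
  })
}

#' Solve for the price discount that meets a willingness-to-pay threshold
#'
#' Finds the serplulimab price-discount fraction `d*` at which the ICER equals
#' the WTP threshold, by bisection to a relative tolerance of `1e-6` on the
#' ICER (the affine closed form is available as `method = "closed_form"` and
#' is used as a cross-check in the test suite). Requires
#' `ICER(d = 0) > wtp > ICER(d = 1)`; otherwise a status is returned instead
#' of a root (`"no_discount_needed"` / `"unreachable"`).
#'
#' @param results base-case two-row `ce_result` tibble.
#' @param wtp willingness-to-pay per QALY.
#' @param method `"bisection"` or `"closed_form"`.
#' @return A one-row tibble: `discount`, `icer_at_discount`, `status`.
#' @export
threshold_price <- function(results, wtp, method = c("bisection", "closed_form")) {
  method <- match.arg(method)
  icer_at <- function(d) icer(scale_serp_price(results, 1 - d))$icer_per_qaly
  i0 <- icer_at(0); i1 <- icer_at(1)
  if (is.na(i0) || is.na(i1)) abort("ICER undefined at the bracket ends")
  if (i0 <= wtp) {
    return(tibble(discount = 0, icer_at_discount = i0, status = "no_discount_needed"))
  }
  if (i1 >= wtp) {
    return(tibble(discount = NA_real_, icer_at_discount = NA_real_,
                  status = "unreachable"))
  }
  if (method == "closed_form") {
    base <- icer(results)
    slope <- get_arm(results, "active")$cost_serplulimab -
      get_arm(results, "control")$cost_serplulimab
    d <- (base$delta_cost - wtp * base$delta_qaly) / slope
    return(tibble(discount = d, icer_at_discount = icer_at(d), status = "ok"))
  }
  lo <- 0; hi <- 1
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (icer_at(mid) > wtp) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  im <- icer_at(mid)
  if (abs(im - wtp) / wtp >= 1e-6) {
    abort("bisection failed to reach the ICER tolerance")
  }
  tibble(discount = mid, icer_at_discount = im, status = "ok")
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full model with each parameter set to its low and high value
#' while all others stay at base: costs, utilities, disutilities and
#' probability parameters at +-20% of base, the annual discount rate over
#' 0-8%, and the time horizon over 2.00-7.44 years. Entries are sorted by
#' descending ICER spread.
#'
#' @param fits_active,fits_control per-arm `pfs`/`os` fits.
#' @param params base-case [ce_params()].
#' @return A `ce_tornado` tibble: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `spread`, plus the base ICER as attribute `"base_icer"`.
#' @export
tornado <- function(fits_active, fits_control, params = ce_params()) {
  ranges <- oneway_ranges(params)
  icer_with <- function(name, value) {
    p <- params
    p[[name]] <- value
    icer(run_arms(fits_active, fits_control, validate_ce_params(p)))$icer_per_qaly
  }
  ranges$icer_low <- collapse_pd_warnings(
    purrr::map2_dbl(ranges$name, ranges$low, icer_with))
  ranges$icer_high <- collapse_pd_warnings(
    purrr::map2_dbl(ranges$name, ranges$high, icer_with))
  out <- ranges |>
    dplyr::mutate(spread = abs(.data$icer_high - .data$icer_low)) |>
    dplyr::select(parameter = "name", "low", "high",
                  "icer_low", "icer_high", "spread") |>
    dplyr::arrange(dplyr::desc(.data$spread))
  structure(out,
            base_icer = collapse_pd_warnings(
              icer(run_arms(fits_active, fits_control, params))$icer_per_qaly),
            class = c("ce_tornado", class(tibble())))
}

# Gamma draw with mean m and SD = sd_frac * m (shape 1/sd_frac^2).
draw_gamma <- function(m, sd_frac) {
  if (m == 0 || sd_frac == 0) return(m)
  shape <- 1 / sd_frac^2
  rgamma(1, shape = shape, rate = shape / m)
}

# Beta draw with mean m and SD = sd_frac * m by method of moments; if the
# requested SD is infeasible (variance >= m(1-m)) it is shrunk to 95% of the
# feasibility bound, with a warning.
draw_beta <- function(m, sd_frac) {
  if (m == 0 || m == 1 || sd_frac == 0) return(m)
  v <- (sd_frac * m)^2
  vmax <- m * (1 - m)
  if (v >= vmax) {
    warn(sprintf("Beta SD infeasible for mean %.4g; shrunk to the feasibility bound", m))
    v <- 0.95^2 * vmax
  }
  common <- m * (1 - m) / v - 1
  rbeta(1, shape1 = m * common, shape2 = (1 - m) * common)
}

#' Draw one probabilistic-sensitivity parameter set
#'
#' Samples every cost parameter from a Gamma distribution and every
#' utility/disutility/probability parameter from a Beta distribution, each
#' with mean equal to the base-case value and standard deviation `sd_frac`
#' times the mean (method of moments). The discount rate, time horizon,
#' survival parameters and structural settings stay fixed; parameters
#' degenerate at 0 or 1 are kept fixed. The draw is fully reproducible from
#' `(seed, index)`.
#'
#' @param base base-case [ce_params()].
#' @param seed,index integers identifying the draw.
#' @param sd_frac SD as a fraction of the mean (default 0.2).
#' @return A [ce_params()] object.
#' @export
draw_psa_params <- function(base, seed, index, sd_frac = 0.2) {
  reg <- param_registry()
  withr::with_seed(psa_substream(seed, index), {
    p <- base
    for (i in seq_len(nrow(reg))) {
      nm <- reg$name[i]
      p[[nm]] <- switch(reg$class[i],
        cost = draw_gamma(base[[nm]], sd_frac),
        utility = ,
        probability = draw_beta(base[[nm]], sd_frac),
        special = base[[nm]]
      )
    }
    validate_ce_params(p)
  })
}

psa_substream <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index)) %% 2147483647)
}

#' Probabilistic sensitivity analysis
#'
#' Re-evaluates the full model on both arms for `n_draws` parameter sets from
#' [draw_psa_params()], and summarizes the mean incremental cost and QALYs,
#' the ICER of the means, and the probability that the active arm is
#' cost-effective at the given WTP (fraction of draws with positive
#' incremental net monetary benefit).
#'
#' @param n_draws number of Monte Carlo draws (default 1000).
#' @param seed integer seed; the run is bit-reproducible from it.
#' @param fits_active,fits_control per-arm `pfs`/`os` fits (held fixed across
#'   draws).
#' @param params base-case [ce_params()].
#' @param wtp willingness-to-pay per QALY; defaults to the parameter set's.
#' @param sd_frac PSA dispersion, SD as a fraction of the mean.
#' @return A `ce_psa` list with `samples` (one row per draw: per-arm totals,
#'   incrementals, `inmb`) and `summary` (one row: `n_draws`, `mean_delta_cost`,
#'   `mean_delta_qaly`, `mean_delta_ly`, `icer_of_means`, `prob_ce`, `wtp`).
#' @export
run_psa <- function(n_draws = 1000, seed = 20230831, fits_active, fits_control,
                    params = ce_params(), wtp = params$wtp_per_qaly,
                    sd_frac = 0.2) {
  if (n_draws < 1) abort("n_draws must be >= 1")
  samples <- collapse_pd_warnings(purrr::map_dfr(seq_len(n_draws), function(i) {
    p_i <- draw_psa_params(params, seed, i, sd_frac)
    res <- run_arms(fits_active, fits_control, p_i)
    act <- get_arm(res, "active"); ctl <- get_arm(res, "control")
    tibble(
      draw = i,
      cost_active = act$cost, qaly_active = act$qaly, ly_active = act$ly,
      cost_control = ctl$cost, qaly_control = ctl$qaly, ly_control = ctl$ly,
      delta_cost = act$cost - ctl$cost,
      delta_qaly = act$qaly - ctl$qaly,
      delta_ly = act$ly - ctl$ly,
      inmb = wtp * (act$qaly - ctl$qaly) - (act$cost - ctl$cost)
    )
  }))
  summary <- tibble(
    n_draws = n_draws,
    mean_delta_cost = mean(samples$delta_cost),
    mean_delta_qaly = mean(samples$delta_qaly),
    mean_delta_ly = mean(samples$delta_ly),
    icer_of_means = mean(samples$delta_cost) / mean(samples$delta_qaly),
    prob_ce = mean(samples$inmb > 0),
    wtp = wtp
  )
  structure(list(samples = samples, summary = summary), class = "ce_psa")
}

#' @export
print.ce_psa <- function(x, ...) {
  cat("<ce_psa> ", x$summary$n_draws, " draws\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Glance method for PSA runs
#'
#' @param x a `ce_psa` object.
#' @param ... unused.
#' @return The one-row PSA summary tibble.
#' @exportS3Method
glance.ce_psa <- function(x, ...) x$summary

#' Tidy method for PSA runs
#'
#' @param x a `ce_psa` object.
#' @param ... unused.
#' @return The per-draw samples tibble.
#' @exportS3Method
tidy.ce_psa <- function(x, ...) x$samples

#' Cost-effectiveness acceptability curve
#'
#' For each WTP value, the fraction of PSA draws in which the active arm has
#' positive incremental net monetary benefit.
#'
#' @param psa a [run_psa()] result, or its `samples` tibble.
#' @param wtp_grid vector of WTP values (default 0 to 200,000 by 2,000).
#' @return A tibble `wtp`, `prob_ce`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2e5, by = 2000)) {
  samples <- if (inherits(psa, "ce_psa")) psa$samples else as_tibble(psa)
  if (nrow(samples) == 0) abort("no PSA samples")
  purrr::map_dfr(wtp_grid, function(w) {
    tibble(wtp = w, prob_ce = mean(w * samples$delta_qaly - samples$delta_cost > 0))
  })
}
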