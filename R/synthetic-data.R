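#' Trial design for the synthetic cohort
#'
#' Describes the simulated randomized trial that stands in for the source
#' evidence: total enrolment, active:control allocation ratio, administrative
#' censoring horizon, and the random seed. Defaults emulate a 585-patient
#' trial randomized 2:1 with 30 months of follow-up.
#'
#' @param n_total total number of patients across both arms.
#' @param allocation integer vector `c(active, control)` giving the
#'   randomization ratio.
#' @param censor_time months of follow-up after which survivors are
#'   administratively censored.
#' @param seed integer seed controlling event-time generation.
#'
#' @return A `trial_design` list with fields `n_total`, `allocation`,
#'   `n_active`, `n_control`, `censor_time`, `seed`.
#' @examples
#' trial_design()$n_active  # 390
#' @export
trial_design <- function(n_total = 585, allocation = c(2, 1),
                         censor_time = 30, seed = 20230831L) {
  stopifnot(length(allocation) == 2)
  if (n_total <= 0 || any(allocation <= 0) || censor_time <= 0) {
    abort("n_total, allocation components and censor_time must all be positive")
  }
  n_active <- round(n_total * allocation[1] / sum(allocation))
  structure(
    list(n_total = n_total, allocation = allocation,
         n_active = n_active, n_control = n_total - n_active,
         censor_time = censor_time, seed = as.integer(seed)),
    class = "trial_design"
  )
}

#' Calibrate a Weibull survival curve to a target median
#'
#' The model works with the rate-form Weibull survival function
#' `S(t) = exp(-lambda * t^gamma)` (`lambda > 0`, `gamma > 0`). Given a target
#' median survival time and a shape, this returns the rate that puts the
#' median exactly where stated: `lambda = log(2) / median^gamma`.
#'
#' @param median target median survival in months.
#' @param gamma Weibull shape parameter.
#' @return A `weibull_params` list with fields `lambda` and `gamma`.
#' @examples
#' wp <- calibrate_to_median(5.7, gamma = 1)
#' wp$lambda                      # log(2)/5.7
#' survival_at(weibull_fit(wp$lambda, wp$gamma), 5.7)  # 0.5
#' @export
calibrate_to_median <- function(median, gamma) {
  if (!is.numeric(median) || median <= 0 || !is.numeric(gamma) || gamma <= 0) {
    abort("median and gamma must be positive numbers")
  }
  structure(list(lambda = log(2) / median^gamma, gamma = gamma),
            class = "weibull_params")
}

#' Simulate pseudo individual patient data from Weibull event times
#'
#' Draws per-patient event times for each arm and endpoint from the stated
#' rate-form Weibull distributions, applying administrative censoring at
#' `censor_time`. This is the synthetic stand-in for pseudo-IPD reconstructed
#' from published survival curves.
#'
#' @param design a [trial_design()].
#' @param arm_params nested list `list(active = list(pfs = , os = ), control =
#'   list(pfs = , os = ))` of [calibrate_to_median()] /  `weibull_params`
#'   objects. Endpoints present may be any subset of `pfs`/`os`.
#' @param censor_time administrative censoring time in months; defaults to the
#'   design's. `Inf` disables censoring.
#'
#' @return A tibble with columns `time_months`, `event` (1 event, 0 censored),
#'   `arm` (`"active"`/`"control"`), `endpoint` (`"PFS"`/`"OS"`).
#' @examples
#' des <- trial_design(n_total = 60, seed = 1)
#' ipd <- gen_weibull_ipd(des,
#'   list(active  = list(pfs = calibrate_to_median(5.7, 1.2)),
#'        control = list(pfs = calibrate_to_median(4.3, 1.2))))
#' table(ipd$arm)
#' @export
gen_weibull_ipd <- function(design, arm_params, censor_time = design$censor_time) {
  stopifnot(inherits(design, "trial_design"))
  if (censor_time <= 0) abort("censor_time must be > 0")
  n_by_arm <- c(active = design$n_active, control = design$n_control)
  withr::with_seed(design$seed, {
    purrr::map_dfr(c("active", "control"), function(arm) {
      eps <- arm_params[[arm]]
      purrr::map_dfr(names(eps), function(ep) {
        wp <- eps[[ep]]
        n <- n_by_arm[[arm]]
        # S(t) = exp(-lambda t^gamma)  <=>  shape = gamma, scale = lambda^(-1/gamma)
        t <- rweibull(n, shape = wp$gamma, scale = wp$lambda^(-1 / wp$gamma))
        tibble(
          time_months = pmin(t, censor_time),
          event = as.integer(t <= censor_time),
          arm = arm,
          endpoint = toupper(ep)
        )
      })
    })
  })
}

#' Generate a digitized-curve fixture and matching numbers-at-risk table
#'
#' Emulates what plot digitization of a published Kaplan-Meier curve yields:
#' survival probabilities read at a grid of times, plus the at-risk counts
#' printed under the plot. Points are the exact parametric survival
#' `S(t) = exp(-lambda t^gamma)`, optionally perturbed by small additive
#' uniform plot-reading noise and re-monotonized; the risk table holds the
#' expected number still at risk (`round(n * S(t))` up to the censoring
#' horizon, 0 after).
#'
#' @param arm_params a `weibull_params` object for one arm/endpoint.
#' @param read_times strictly increasing times (months) starting at 0 where
#'   the curve is read.
#' @param n number of patients at risk at time 0.
#' @param risk_times times at which at-risk counts are reported; defaults to
#'   `read_times`.
#' @param censor_time administrative censoring horizon used for the risk
#'   table.
#' @param noise half-width of the additive uniform digitization error on
#'   survival (0 = exact, the default).
#' @param seed seed for the noise draw.
#'
#' @return A list with tibbles `curve` (`time_months`, `survival`) and `risk`
#'   (`time_months`, `n_risk`).
#' @examples
#' fx <- gen_digitized_fixture(calibrate_to_median(5.7, 1.2),
#'                             read_times = seq(0, 24, 2), n = 390)
#' fx$curve
#' @export
gen_digitized_fixture <- function(arm_params, read_times, n,
                                  risk_times = read_times,
                                  censor_time = Inf,
                                  noise = 0, seed = 1L) {
  if (length(read_times) < 2 || is.unsorted(read_times, strictly = TRUE)) {
    abort("read_times must be strictly increasing")
  }
  if (read_times[1] != 0) abort("read_times must start at 0")
  s_fun <- function(t) exp(-arm_params$lambda * t^arm_params$gamma)
  s <- s_fun(read_times)
  if (noise > 0) {
    withr::with_seed(seed, {
      s <- s + runif(length(s), -noise, noise)
    })
    s[1] <- 1
    s <- pmin(pmax(s, 0), 1)
    s <- cummin(s)  # re-monotonize after perturbation
  }
  risk <- round(n * s_fun(risk_times))
  risk[risk_times > censor_time] <- 0
  list(
    curve = tibble(time_months = read_times, survival = s),
    risk  = tibble(time_months = risk_times, n_risk = as.integer(risk))
  )
}
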