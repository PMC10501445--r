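#' Clean raw digitized survival coordinates
#'
#' Plot-read Kaplan-Meier coordinates carry small reading errors: survival
#' slightly above 1, tiny upticks, duplicated times, a missing origin. This
#' sorts by time, clamps survival to \[0, 1\], keeps the last of duplicated
#' times, prepends `(0, 1)` when absent, and enforces monotone non-increase by
#' a running minimum.
#'
#' @param raw_points a data frame with columns `time_months` (or `time`) and
#'   `survival`.
#' @return A tibble `time_months`, `survival` satisfying the digitized-curve
#'   invariants.
#' @examples
#' preprocess_curve(data.frame(time_months = c(0, 1, 2),
#'                             survival = c(1, 0.8, 0.85)))
#' @export
preprocess_curve <- function(raw_points) {
  pts <- as_tibble(raw_points)
  if ("time" %in% names(pts) && !"time_months" %in% names(pts)) {
    pts <- dplyr::rename(pts, time_months = "time")
  }
  stopifnot(all(c("time_months", "survival") %in% names(pts)))
  pts <- pts |>
    dplyr::filter(is.finite(.data$time_months), is.finite(.data$survival),
                  .data$time_months >= 0) |>
    dplyr::arrange(.data$time_months) |>
    dplyr::mutate(survival = pmin(pmax(.data$survival, 0), 1)) |>
    dplyr::group_by(.data$time_months) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  if (nrow(pts) < 2 && !(nrow(pts) == 1 && pts$time_months[1] > 0)) {
    abort("need at least 2 valid curve points")
  }
  if (pts$time_months[1] > 0) {
    pts <- dplyr::bind_rows(tibble(time_months = 0, survival = 1), pts)
  }
  if (nrow(pts) < 2) abort("need at least 2 valid curve points")
  dplyr::mutate(pts, survival = cummin(.data$survival))
}

# Step-function lookup: survival at the last digitized point with time <= t.
curve_step <- function(curve, t) {
  idx <- findInterval(t, curve$time_months)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

# Largest-remainder integer apportionment of fractional counts `x` to a given
# integer `total`; ties go to the earlier entry.
round_largest_remainder <- function(x, total) {
  if (length(x) == 0) return(integer(0))
  if (sum(x) <= 0) {
    out <- integer(length(x))
    if (total > 0) out[seq_len(length(x))[seq_len(min(total, length(x)))]] <- 1
    # distribute any excess evenly from the front
    rem <- total - sum(out)
    i <- 1
    while (rem > 0) { out[i] <- out[i] + 1; i <- i %% length(x) + 1; rem <- rem - 1 }
    return(out)
  }
  scaled <- x * total / sum(x)
  base <- floor(scaled)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- scaled - base
    ord <- order(-frac, seq_along(frac))  # ties to earlier position
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Interval-constrained reconstruction of per-patient `(time, event)` records
#' from digitized Kaplan-Meier coordinates anchored to a numbers-at-risk
#' table. Within each at-risk interval `(T_i, T_{i+1}]` the number leaving is
#' fixed by the risk table (`n_i - n_{i+1}`); the split between events and
#' censorings is chosen so the product-limit estimate over the reconstructed
#' records tracks the digitized survival ratio across the interval as closely
#' as integer rounding allows. Events are placed at the digitized drop times,
#' censorings uniformly within the interval (fractional counts resolved by
#' largest-remainder apportionment, ties to the earlier drop). Patients still
#' at risk past the last digitized time are censored there.
#'
#' @param curve a preprocessed digitized curve (see [preprocess_curve()]).
#' @param risk a tibble `time_months`, `n_risk` with strictly increasing times
#'   and non-increasing counts; the first count is the arm size.
#' @param arm,endpoint labels attached to the output records.
#' @return A pseudo-IPD tibble (`time_months`, `event`, `arm`, `endpoint`)
#'   with exactly `risk$n_risk[1]` rows.
#' @examples
#' curve <- tibble::tibble(time_months = c(0, 1, 2), survival = c(1, 0.75, 0.5))
#' risk  <- tibble::tibble(time_months = c(0, 1, 2), n_risk = c(4L, 3L, 2L))
#' reconstruct_ipd(curve, risk)
#' @export
reconstruct_ipd <- function(curve, risk, arm = "active", endpoint = "PFS") {
  curve <- preprocess_curve(curve)
  risk <- as_tibble(risk)
  stopifnot(all(c("time_months", "n_risk") %in% names(risk)))
  if (is.unsorted(risk$time_months, strictly = TRUE)) {
    abort("risk table times must be strictly increasing")
  }
  if (any(diff(risk$n_risk) > 0)) {
    i <- which(diff(risk$n_risk) > 0)[1]
    abort(sprintf("infeasible risk table: n_risk increases between t=%g and t=%g",
                  risk$time_months[i], risk$time_months[i + 1]))
  }
  if (min(risk$time_months) < min(curve$time_months) ||
      max(risk$time_months) > max(curve$time_months)) {
    abort("risk table times must lie within the digitized curve's time range")
  }

  event_times <- numeric(0)
  censor_times <- numeric(0)

  # digitized drop points (strict decreases)
  drops <- curve |>
    dplyr::mutate(prev = dplyr::lag(.data$survival)) |>
    dplyr::filter(!is.na(.data$prev), .data$survival < .data$prev)

  n_entries <- nrow(risk)
  m_carry <- risk$n_risk[1]

  process_interval <- function(t0, t1, n0, n1_target) {
    s0 <- curve_step(curve, t0)
    dd <- drops[drops$time_months > t0 & drops$time_months <= t1, ]
    u <- dd$time_months
    # conditional ratio at each drop, walking the step function from s0
    s_seq <- c(s0, dd$survival)
    r <- s_seq[-1] / s_seq[-length(s_seq)]
    r[!is.finite(r)] <- 1
    leave <- n0 - n1_target

    frac_events <- function(C) {
      m <- n0
      gap_c <- C / (length(u) + 1)
      d <- numeric(length(u))
      for (k in seq_along(u)) {
        m <- m - gap_c
        d[k] <- max(m, 0) * (1 - r[k])
        m <- m - d[k]
      }
      d
    }

    if (length(u) == 0) {
      d_int <- integer(0)
      c_total <- leave
    } else {
      D0 <- sum(frac_events(0))
      if (D0 >= leave) {
        # curve implies at least as many events as patients leaving: all leavers
        # are events, apportioned across drops
        c_total <- 0L
        d_int <- round_largest_remainder(frac_events(0), leave)
      } else {
        g <- function(C) sum(frac_events(C)) + C - leave
        C_star <- if (leave == 0) 0 else uniroot(g, c(0, leave), tol = 1e-9)$root
        c_total <- as.integer(round(C_star))
        c_total <- max(0L, min(c_total, leave))
        d_int <- round_largest_remainder(frac_events(c_total), leave - c_total)
      }
    }
    if (length(u)) event_times <<- c(event_times, rep(u, d_int))
    if (c_total > 0) {
      censor_times <<- c(censor_times,
                         t0 + (seq_len(c_total) - 0.5) / c_total * (t1 - t0))
    }
    n0 - sum(d_int) - c_total
  }

  if (n_entries >= 2) {
    for (i in seq_len(n_entries - 1)) {
      m_carry <- process_interval(risk$time_months[i], risk$time_months[i + 1],
                                  m_carry, risk$n_risk[i + 1])
    }
  }

  # tail beyond the last at-risk entry: events at remaining drops, residual
  # patients censored at the last digitized time
  t_last <- max(curve$time_months)
  t_risk_end <- risk$time_months[n_entries]
  if (t_last > t_risk_end && m_carry > 0) {
    dd <- drops[drops$time_months > t_risk_end & drops$time_months <= t_last, ]
    s_seq <- c(curve_step(curve, t_risk_end), dd$survival)
    r <- s_seq[-1] / s_seq[-length(s_seq)]
    r[!is.finite(r)] <- 1
    m <- m_carry
    for (k in seq_len(nrow(dd))) {
      d_k <- min(m, round(m * (1 - r[k])))
      if (d_k > 0) event_times <- c(event_times, rep(dd$time_months[k], d_k))
      m <- m - d_k
    }
    m_carry <- m
  }
  if (m_carry > 0) censor_times <- c(censor_times, rep(t_last, m_carry))

  out <- dplyr::bind_rows(
    tibble(time_months = event_times, event = 1L),
    tibble(time_months = censor_times, event = 0L)
  ) |>
    dplyr::arrange(.data$time_months, dplyr::desc(.data$event)) |>
    dplyr::mutate(arm = arm, endpoint = endpoint)
  stopifnot(nrow(out) == risk$n_risk[1])
  out
}

#' Product-limit (Kaplan-Meier) estimate of a pseudo-IPD sample
#'
#' Thin wrapper around [survival::survfit()] returning the step function as a
#' digitized-curve tibble with the origin `(0, 1)` prepended. The input should
#' be a single arm/endpoint.
#'
#' @param ipd a pseudo-IPD tibble with columns `time_months` and `event`.
#' @return A tibble `time_months`, `survival`.
#' @examples
#' ipd <- tibble::tibble(time_months = c(1, 2), event = c(1L, 1L))
#' km_estimate(ipd)
#' @export
km_estimate <- function(ipd) {
  if (nrow(ipd) == 0) abort("empty pseudo-IPD")
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = as.data.frame(ipd))
  out <- tibble(time_months = fit$time, survival = fit$surv)
  if (nrow(out) == 0 || out$time_months[1] > 0) {
    out <- dplyr::bind_rows(tibble(time_months = 0, survival = 1), out)
  }
  out
}
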