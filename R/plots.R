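#' Plot a cohort trace
#'
#' State occupancy over model time for a [build_trace()] result.
#'
#' @param trace a `ce_trace` tibble.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  long <- trace |>
    tidyr::pivot_longer(dplyr::starts_with("occ_"),
                        names_to = "state", values_to = "occupancy") |>
    dplyr::mutate(state = factor(sub("occ_", "", .data$state),
                                 levels = c("pfs", "pd1", "pd2", "death"),
                                 labels = c("PFS", "1st PD", "2nd+ PD", "Death")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_years, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Years", y = "State occupancy", colour = "State") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trace
#' @param object,... autoplot arguments.
#' @exportS3Method
autoplot.ce_trace <- function(object, ...) plot_trace(object)

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_tbl a [ceac()] tibble.
#' @param wtp optional WTP threshold to mark with a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_tbl, wtp = NULL) {
  p <- ggplot2::ggplot(ceac_tbl, ggplot2::aes(x = .data$wtp, y = .data$prob_ce)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (USD/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = 2)
  p
}

#' Tornado diagram of one-way sensitivity results
#'
#' @param tornado_tbl a [tornado()] result.
#' @param n_top number of highest-spread parameters shown.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado_tbl, n_top = 15) {
  base_icer <- attr(tornado_tbl, "base_icer")
  dat <- tornado_tbl |>
    dplyr::slice_head(n = n_top) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(.data$parameter)))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay a fitted survival curve on the Kaplan-Meier estimate
#'
#' @param fit a `parsurv_fit`.
#' @param ipd optional pseudo-IPD tibble; when given, its product-limit
#'   estimate is drawn as a step function under the fitted curve.
#' @param max_time right edge of the time axis (months); defaults to the last
#'   observed time (or the fitted 1% survival time without data).
#' @return A ggplot object.
#' @export
plot_survival_fit <- function(fit, ipd = NULL, max_time = NULL) {
  if (is.null(max_time)) {
    max_time <- if (!is.null(ipd)) max(ipd$time_months) else {
      t <- 1
      while (survival_at(fit, t) > 0.01 && t < 1e6) t <- t * 2
      t
    }
  }
  grid <- tibble(time_months = seq(0, max_time, length.out = 200))
  grid$survival <- survival_at(fit, grid$time_months)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$time_months,
                                          y = .data$survival)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival") +
    ggplot2::theme_minimal()
  if (!is.null(ipd)) {
    km <- km_estimate(ipd)
    p <- p + ggplot2::geom_step(data = km, colour = "grey30")
  }
  p
}

#' Incremental cost-effectiveness plane from PSA draws
#'
#' @param psa a [run_psa()] result.
#' @param wtp WTP threshold drawn as a line through the origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = psa$summary$wtp) {
  ggplot2::ggplot(psa$samples, ggplot2::aes(x = .data$delta_qaly,
                                            y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
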