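#' Plot per-period trends of RT and physiological features
#'
#' Period means with standard-error bars for reaction time, alpha power,
#' meanRR and RMSSD — the standard at-a-glance view of how driver state
#' evolves over a session.
#'
#' @param features Feature tibble (see [build_trial_features()]).
#' @return A ggplot object (facetted by measure).
#' @export
plot_period_trends <- function(features) {
  long <- features |>
    dplyr::select(dplyr::any_of(c("period", "rt", "alpha_db", "mean_rr",
                                  "rmssd"))) |>
    tidyr::pivot_longer(-"period", names_to = "measure") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$measure, .data$period) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Time period", y = NULL,
                  title = "Per-period feature trends (mean ± SE)") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted RT model
#'
#' Fixed-effect estimates with approximate 95% intervals
#' (estimate ± 1.96 SE), intercept omitted.
#'
#' @param object An `rt_lme` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rt_lme
#' @export
autoplot.rt_lme <- function(object, ...) {
  td <- tidy.rt_lme(object)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std_error,
                   xmax = .data$estimate + 1.96 * .data$std_error)) +
    ggplot2::labs(x = "Estimate (response units per SD)", y = NULL,
                  title = "Fixed effects") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of R-peak detection
#'
#' Raw ECG trace with detected peaks overplotted; useful for spot checks
#' on short windows.
#'
#' @param ecg An ECG [signal_stream()].
#' @param peaks Peak times from [detect_r_peaks()].
#' @param t_start,t_end Optional plotting window, s.
#' @return A ggplot object.
#' @export
plot_r_peaks <- function(ecg, peaks, t_start = -Inf, t_end = Inf) {
  w <- ecg[ecg$time_s >= t_start & ecg$time_s < t_end, , drop = FALSE]
  p <- peaks[peaks >= t_start & peaks < t_end]
  marks <- tibble::tibble(
    time_s = p,
    value = purrr::map_dbl(p, function(t) w$value[which.min(abs(w$time_s - t))])
  )
  ggplot2::ggplot(w, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = marks, colour = "red", size = 2) +
    ggplot2::labs(x = "Time (s)", y = "ECG (mV)",
                  title = "Detected R peaks") +
    ggplot2::theme_minimal()
}
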