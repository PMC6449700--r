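#' Extract reaction times and detection outcomes from a response log
#'
#' A `U` press is attributed to the most recent arrow whose response window
#' `(onset, next onset]` contains it. For unreliable arrows the first such
#' press is a hit with RT = press time - onset (ms), winsorized at `cap`
#' (responses above the ceiling are set *equal* to it, not discarded); no
#' press means a miss with missing RT. A `U` press inside a reliable
#' arrow's window is a false alarm. The first subsequent `N`/`I`/`C` press
#' in the same window is matched against the event's outcome for
#' lane-change report accuracy.
#'
#' @param events Event tibble (see [generate_event_schedule()]).
#' @param responses Response tibble with `time_s`, `key`.
#' @param cap RT ceiling, ms (2600 by default).
#' @return A list with `trials` (one row per unreliable arrow:
#'   `participant`, `period`, `trial`, `rt`, `hit`, `second_key`,
#'   `second_correct`) and `counts` (per period: `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`, `hit_rate`, `fa_rate`).
#' @export
extract_rt <- function(events, responses, cap = 2600) {
  stopifnot(!is.unsorted(events$onset_s, strictly = TRUE))
  if (any(responses$time_s < events$onset_s[1])) {
    warning("responses before the first event are ignored", call. = FALSE)
  }
  win_end <- c(events$onset_s[-1], Inf)
  key_map <- c(no_change = "N", incorrect_change = "I", correct_change = "C")

  per_event <- purrr::map(seq_len(nrow(events)), function(i) {
    r <- responses[responses$time_s > events$onset_s[i] &
                     responses$time_s <= win_end[i], , drop = FALSE]
    u <- which(r$key == "U")
    first_u <- if (length(u)) r$time_s[u[1]] else NA_real_
    second <- NA_character_
    if (length(u)) {
      after <- r[r$time_s > first_u & r$key %in% c("N", "I", "C"), , drop = FALSE]
      if (nrow(after)) second <- after$key[1]
    }
    list(first_u = first_u, second = second)
  })
  first_u <- vapply(per_event, `[[`, numeric(1), "first_u")
  second <- vapply(per_event, `[[`, character(1), "second")

  unrel <- events$arrow_type == "unreliable"
  rt <- (first_u - events$onset_s) * 1000
  rt <- pmin(rt, cap)
  trials <- tibble::tibble(
    participant = events$participant[unrel],
    period = events$period[unrel],
    trial = events$trial_index[unrel],
    rt = rt[unrel],
    hit = !is.na(first_u[unrel]),
    second_key = second[unrel],
    second_correct = second[unrel] == unname(key_map[events$outcome[unrel]])
  )
  counts <- tibble::tibble(
    period = events$period, unrel = unrel,
    responded = !is.na(first_u)
  ) |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      hits = sum(.data$unrel & .data$responded),
      misses = sum(.data$unrel & !.data$responded),
      false_alarms = sum(!.data$unrel & .data$responded),
      correct_rejections = sum(!.data$unrel & !.data$responded),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      hit_rate = .data$hits / pmax(.data$hits + .data$misses, 1),
      fa_rate = .data$false_alarms /
        pmax(.data$false_alarms + .data$correct_rejections, 1)
    )
  list(trials = trials, counts = counts)
}

#' Non-parametric sensitivity: the A statistic
#'
#' `a_sensitivity()` evaluates the closed-form piecewise expression for A,
#' the average of the areas under the minimum-area and maximum-area proper
#' ROC curves constrained to pass through the observed (false-alarm, hit)
#' pair. Unlike d', it needs no z-transform and is defined at hit or
#' false-alarm rates of exactly 0 or 1. For H < F the point is reflected
#' (`A = 1 - A(F, H)`); `A = 0.5` whenever `H = F`.
#'
#' `a_sensitivity_roc()` is an independent numeric construction of the
#' same quantity: the minimum-area proper ROC through (F, H) is the
#' concave two-chord curve (0,0)-(F,H)-(1,1); the maximum-area curve is
#' found by numerically optimizing, over the supergradient slope at
#' (F, H), the area under the concave envelope `min(1, H + s(x - F))`.
#' The two agree to ~1e-7, and the numeric route serves as the oracle for
#' the closed form.
#'
#' @param H Hit rate in `[0, 1]`.
#' @param F False-alarm rate in `[0, 1]`.
#' @return The A value in `[0, 1]`.
#' @export
#' @examples
#' a_sensitivity(0.8, 0.2) # 0.86
a_sensitivity <- function(H, F) {
  stopifnot(H >= 0, H <= 1, F >= 0, F <= 1)
  if (H == F) return(0.5)
  if (H < F) return(1 - a_sensitivity(F, H))
  if (F <= 0.5 && H >= 0.5) {
    3 / 4 + (H - F) / 4 - F * (1 - H)
  } else if (H < 0.5) {
    if (H == 0) return(0.5)  # degenerate H = F = 0
    3 / 4 + (H - F) / 4 - F / (4 * H)
  } else {
    3 / 4 + (H - F) / 4 - (1 - H) / (4 * (1 - F))
  }
}

#' @rdname a_sensitivity
#' @export
a_sensitivity_roc <- function(H, F) {
  stopifnot(H >= 0, H <= 1, F >= 0, F <= 1)
  if (H < F) return(1 - a_sensitivity_roc(F, H))
  if (H == F) return(0.5)
  # minimum-area proper ROC: chords (0,0) -> (F,H) -> (1,1)
  a_min <- F * H / 2 + (1 - F) * (H + 1) / 2
  # maximum-area proper ROC: for supergradient slope s at (F,H), the curve
  # is min(1, H + s (x - F)); feasibility requires it to reach (1,1)
  # (s >= (1-H)/(1-F)) and stay non-negative at 0 (s <= H/F).
  area_s <- function(s) {
    if (s <= 0) return(if (H >= 1) 1 else -Inf)
    x1 <- F + (1 - H) / s
    if (x1 >= 1) {
      H + s * (0.5 - F)
    } else {
      H * x1 + s * (x1^2 / 2 - F * x1) + (1 - x1)
    }
  }
  lo <- if (H >= 1) 0 else (1 - H) / (1 - F)
  hi <- if (F <= 0) 1e8 else H / F
  if (hi <= lo) {
    a_max <- area_s(lo)
  } else {
    opt <- stats::optimize(area_s, c(lo, hi), maximum = TRUE, tol = 1e-10)
    a_max <- max(opt$objective, area_s(lo), area_s(hi))
  }
  (a_min + a_max) / 2
}

#' Per-period performance summaries
#'
#' For each time period: hit and false-alarm rates against unreliable vs.
#' reliable arrows, the A sensitivity statistic for that (H, F) pair, and
#' mean accuracy of the second (lane-change type) press. Periods with no
#' unreliable trials are flagged undefined.
#'
#' @inheritParams extract_rt
#' @return A tibble with one row per period: counts, `hit_rate`,
#'   `fa_rate`, `a_value`, `second_press_accuracy`, `defined`.
#' @export
period_performance <- function(events, responses, cap = 2600) {
  ex <- extract_rt(events, responses, cap)
  acc <- ex$trials |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      second_press_accuracy = mean(.data$second_correct, na.rm = TRUE),
      .groups = "drop")
  ex$counts |>
    dplyr::left_join(acc, by = "period") |>
    dplyr::mutate(
      defined = (.data$hits + .data$misses) > 0,
      a_value = ifelse(.data$defined,
                       purrr::map2_dbl(.data$hit_rate, .data$fa_rate,
                                       a_sensitivity),
                       NA_real_)
    )
}
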