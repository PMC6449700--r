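#' Build the per-trial feature table for one session
#'
#' Time-locks every modality to the unreliable-arrow onsets and assembles
#' one row per trial: pre-stimulus alpha power in dB (1-s EEG epoch,
#' Hamming-windowed spectrum, bin nearest 10 Hz), meanRR and RMSSD from the
#' R peaks inside the 10-s pre-stimulus window (the detector runs once on
#' the full record), log gaze dispersion from the confidence-filtered 3-s
#' window, and the winsorized reaction time. Every unreliable event yields
#' a row; per-feature validity flags mark what could not be computed
#' (missing stream, artifactual epoch, too few beats or gaze samples)
#' rather than dropping trials silently.
#'
#' @param events Event tibble for the session.
#' @param responses Response tibble (`time_s`, `key`).
#' @param ecg,eeg,gaze Streams for the session; any may be `NULL`, in which
#'   case that modality's features are missing but the run continues.
#' @param ecg_window,eeg_epoch,gaze_window Pre-stimulus window lengths, s.
#' @param rt_cap RT ceiling, ms.
#' @param amp_limit EEG artifact rejection limit, µV.
#' @param filter Whether to band-pass filter the EEG record first.
#' @return A tibble with one row per unreliable event: identifiers,
#'   `alpha_db`, `mean_rr`, `rmssd`, `ln_x`, `ln_y`, `rt`, `hit`, and
#'   logical `valid_alpha`, `valid_hrv`, `valid_gaze`.
#' @export
build_trial_features <- function(events, responses, ecg = NULL, eeg = NULL,
                                 gaze = NULL, ecg_window = 10, eeg_epoch = 1,
                                 gaze_window = 3, rt_cap = 2600,
                                 amp_limit = 100, filter = TRUE) {
  unrel <- dplyr::filter(events, .data$arrow_type == "unreliable")
  n <- nrow(unrel)
  out <- tibble::tibble(
    participant = unrel$participant, period = unrel$period,
    trial = unrel$trial_index,
    alpha_db = NA_real_, mean_rr = NA_real_, rmssd = NA_real_,
    ln_x = NA_real_, ln_y = NA_real_,
    valid_alpha = FALSE, valid_hrv = FALSE, valid_gaze = FALSE
  )

  if (!is.null(ecg)) {
    peaks <- detect_r_peaks(ecg)
    hrv <- purrr::map_dfr(unrel$onset_s, function(on) {
      hrv_metrics(peaks, on - ecg_window, on)
    })
    out$mean_rr <- hrv$mean_rr
    out$rmssd <- hrv$rmssd
    out$valid_hrv <- hrv$valid
  }

  if (!is.null(eeg)) {
    rec <- if (filter) filter_eeg(eeg) else eeg
    epochs <- epoch_prestimulus(rec, unrel$onset_s, eeg_epoch) |>
      screen_artifacts(amp_limit = amp_limit)
    fs <- stream_rate(eeg)
    out$alpha_db <- purrr::map2_dbl(epochs$samples, epochs$valid, function(v, ok) {
      if (!ok) NA_real_ else as.numeric(alpha_power_db(v, fs))
    })
    out$valid_alpha <- epochs$valid
  }

  if (!is.null(gaze)) {
    disp <- purrr::map_dfr(unrel$onset_s, function(on) {
      w <- suppressWarnings(extract_window(gaze, on - gaze_window, on))
      gaze_dispersion(w)
    })
    out$ln_x <- disp$ln_x
    out$ln_y <- disp$ln_y
    out$valid_gaze <- disp$valid
  }

  rts <- extract_rt(events, responses, cap = rt_cap)
  out$rt <- rts$trials$rt
  out$hit <- rts$trials$hit
  out
}

#' Feature table for a simulated multi-participant study
#'
#' Runs [simulate_session()] and [build_trial_features()] for each
#' participant and row-binds the results; the corresponding ground-truth
#' latents are attached as attribute `ground_truth`.
#'
#' @param config A [generator_config()].
#' @return The combined feature tibble.
#' @export
simulate_study_features <- function(config = generator_config()) {
  pieces <- purrr::map(seq_len(config$n_participants), function(pp) {
    s <- simulate_session(config, participant = pp)
    list(
      features = build_trial_features(s$events, s$responses, s$ecg, s$eeg,
                                      s$gaze),
      truth = s$ground_truth
    )
  })
  out <- dplyr::bind_rows(purrr::map(pieces, "features"))
  attr(out, "ground_truth") <- dplyr::bind_rows(purrr::map(pieces, "truth"))
  out
}
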