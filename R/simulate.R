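#' Generator configuration for synthetic driving sessions
#'
#' Returns the full parameter set for the synthetic multimodal session
#' generator, with defaults matching the study conditions the analysis
#' assumes: five 10-min fully automated drives per participant, 50 arrow
#' stimuli per drive arriving every 13 s (+/- 2 s uniform jitter), 20%
#' unreliable (automation-failure) arrows with a 6/2/2 split of
#' no-change / incorrect-change / correct-change outcomes, ECG with
#' configurable meanRR and RMSSD, single-channel ("Pz") EEG with 1/f
#' background plus a per-trial latent 10-Hz alpha amplitude, 120-fps gaze
#' scatter with confidence dropout, and reaction times generated from a
#' linear model with participant and trial random intercepts coupled to the
#' standardized latent features.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `generator_config`.
#' @details Reaction-time coefficients in `beta` are named by feature
#'   (`alpha_db`, `mean_rr`, `rmssd`, `ln_x`, `period`) with `:` for
#'   interactions, and apply to *standardized* latent features (period is
#'   centered at 3); units are those of `beta[["intercept"]]` (ms for the
#'   defaults). `sd_participant`, `sd_trial`, `sd_resid` are the random
#'   intercept and residual SDs on the same scale.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_participants = 25L,
    n_periods = 5L,
    period_duration = 600,
    n_arrows = 50L,
    mean_iei = 13,
    iei_jitter = 2,
    p_unreliable = 0.2,
    outcome_split = c(no_change = 6L, incorrect_change = 2L, correct_change = 2L),
    # ECG
    ecg_fs = 250,
    rr_mean = 800,
    rr_rmssd_target = 30,
    rr_trial_sd = 40,
    rmssd_trial_sd = 8,
    r_amplitude = 1,
    t_amplitude_frac = 0.3,
    ecg_noise_sd = 0.05,
    # EEG
    eeg_fs = 500,
    alpha_base = 4,
    alpha_trial_sd = 1.2,
    alpha_freq = 10,
    eeg_noise_sd = 10,
    eeg_noise_exponent = 1,
    # gaze
    gaze_fps = 120,
    gaze_sigma_x = 50,
    gaze_sigma_y = 40,
    gaze_sigma_trial_cv = 0.3,
    p_low_confidence = 0.1,
    screen_center = c(x = 960, y = 600),
    # reaction-time model (ms scale)
    beta = c(intercept = 900, alpha_db = 30, mean_rr = -15, rmssd = -20,
             ln_x = 0, period = 40, "alpha_db:rmssd" = -25,
             "alpha_db:period" = 15, "rmssd:period" = -12,
             "alpha_db:rmssd:period" = 12),
    sd_participant = 100,
    sd_trial = 30,
    sd_resid = 150,
    rt_floor = 150,
    miss_rate = 0.04,
    false_alarm_rate = 0.01,
    second_press_accuracy = 0.95,
    second_press_delay = 0.6,
    measurement_sd = 0
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_generator_config(structure(cfg, class = "generator_config"))
}

validate_generator_config <- function(cfg) {
  props <- c("p_unreliable", "p_low_confidence", "miss_rate",
             "false_alarm_rate", "second_press_accuracy")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must be in [0, 1]", call. = FALSE)
    }
  }
  pos <- c("period_duration", "mean_iei", "ecg_fs", "rr_mean", "eeg_fs",
           "gaze_fps", "sd_participant", "sd_trial", "sd_resid")
  for (p in pos) {
    if (cfg[[p]] < 0) stop(p, " must be non-negative", call. = FALSE)
  }
  n_unrel <- round(cfg$p_unreliable * cfg$n_arrows)
  if (sum(cfg$outcome_split) != n_unrel) {
    stop(sprintf(
      "outcome_split sums to %d but p_unreliable * n_arrows = %d",
      sum(cfg$outcome_split), n_unrel), call. = FALSE)
  }
  if (cfg$period_duration < cfg$n_arrows) {
    stop("period too short for the requested arrow count", call. = FALSE)
  }
  cfg
}

#' Generate an arrow event schedule
#'
#' Per period, exactly `n_arrows` arrows with inter-event intervals drawn
#' uniformly on `mean_iei +/- iei_jitter` and then rescaled so the schedule
#' fits the period (the arrow *count* takes precedence over the nominal
#' spacing); exactly `round(p_unreliable * n_arrows)` arrows are unreliable,
#' at randomized positions, with the configured outcome split.
#'
#' @param config A [generator_config()].
#' @param participant Participant id recorded in the output.
#' @return A tibble with columns `participant`, `period`, `onset_s`,
#'   `arrow_type` (`reliable`/`unreliable`), `outcome` (`normal` for
#'   reliable arrows; `no_change`/`incorrect_change`/`correct_change` for
#'   unreliable), and `trial_index` (1..n within period, unreliable only).
#' @export
generate_event_schedule <- function(config = generator_config(), participant = 1L) {
  n <- config$n_arrows
  n_unrel <- round(config$p_unreliable * n)
  purrr::map_dfr(seq_len(config$n_periods), function(p) {
    iei <- stats::runif(n, config$mean_iei - config$iei_jitter,
                        config$mean_iei + config$iei_jitter)
    # rescale so the last arrow leaves roughly one nominal interval of slack
    scale <- config$period_duration / (sum(iei) + config$mean_iei)
    onsets <- (p - 1) * config$period_duration + cumsum(iei) * scale
    unrel_pos <- sort(sample.int(n, n_unrel))
    outcomes <- rep("normal", n)
    outcomes[unrel_pos] <- sample(rep(names(config$outcome_split),
                                      times = config$outcome_split))
    trial_index <- rep(NA_integer_, n)
    trial_index[unrel_pos] <- seq_len(n_unrel)
    tibble::tibble(
      participant = participant,
      period = p,
      onset_s = onsets,
      arrow_type = ifelse(outcomes == "normal", "reliable", "unreliable"),
      outcome = outcomes,
      trial_index = trial_index
    )
  })
}

#' Generate an RR-interval series with a target RMSSD
#'
#' Intervals are `mean_rr` plus i.i.d. Gaussian deviations with
#' `sd = rmssd_target / sqrt(2)`, which makes the expected RMSSD of the
#' series equal the target; non-positive draws are resampled.
#'
#' @param mean_rr Mean RR interval, ms.
#' @param rmssd_target Target RMSSD, ms (>= 0).
#' @param n_beats Number of beats (>= 2); the series has `n_beats - 1`
#'   intervals.
#' @return Numeric vector of RR intervals in ms.
#' @export
generate_rr_series <- function(mean_rr, rmssd_target, n_beats) {
  stopifnot(mean_rr > 0, rmssd_target >= 0, n_beats >= 2)
  sigma <- rmssd_target / sqrt(2)
  if (sigma > 0 && stats::pnorm(0, mean_rr, sigma) > 0.01) {
    stop("rmssd_target too large relative to mean_rr: >1% of intervals ",
         "would be non-positive", call. = FALSE)
  }
  n <- n_beats - 1L
  rr <- mean_rr + stats::rnorm(n, 0, sigma)
  while (any(bad <- rr <= 0)) {
    rr[bad] <- mean_rr + stats::rnorm(sum(bad), 0, sigma)
  }
  rr
}

#' Synthesize an ECG waveform from RR intervals
#'
#' Baseline Gaussian noise plus a stereotyped biphasic QRS template
#' (Mexican-hat pulse, ~80 ms wide) centered at the cumulative RR times,
#' with an optional smaller T-wave hump ~250 ms after each R peak. The
#' ground-truth R-peak times are attached as attribute `r_peaks`.
#'
#' @param rr RR intervals in ms (see [generate_rr_series()]).
#' @param fs Sampling rate, Hz (>= 100).
#' @param r_amplitude R-peak amplitude, mV.
#' @param t_amplitude_frac T-wave amplitude as a fraction of `r_amplitude`.
#' @param noise_sd Additive white-noise SD, mV.
#' @param start_time Stream start time, s.
#' @return An ECG [signal_stream()] (mV) with attribute `r_peaks` (s).
#' @export
synthesize_ecg <- function(rr, fs = 250, r_amplitude = 1,
                           t_amplitude_frac = 0.3, noise_sd = 0,
                           start_time = 0) {
  stopifnot(fs >= 100, all(rr > 0))
  r_times <- start_time + 0.4 + c(0, cumsum(rr / 1000))
  ecg_waveform(r_times, duration = max(r_times) - start_time + 0.6, fs = fs,
               r_amplitude = r_amplitude, t_amplitude_frac = t_amplitude_frac,
               noise_sd = noise_sd, start_time = start_time)
}

ecg_waveform <- function(r_times, duration, fs, r_amplitude = 1,
                         t_amplitude_frac = 0.3, noise_sd = 0,
                         start_time = 0) {
  n <- round(duration * fs)
  t <- start_time + (seq_len(n) - 1) / fs
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  qrs_sigma <- 0.013  # main lobe ~ 80 ms
  t_sigma <- 0.05
  for (rt in r_times) {
    i <- which(t >= rt - 0.06 & t <= rt + 0.06)
    if (length(i)) {
      u <- (t[i] - rt) / qrs_sigma
      x[i] <- x[i] + r_amplitude * (1 - u^2) * exp(-u^2 / 2)
    }
    if (t_amplitude_frac > 0) {
      j <- which(t >= rt + 0.1 & t <= rt + 0.4)
      if (length(j)) {
        x[j] <- x[j] + r_amplitude * t_amplitude_frac *
          exp(-(t[j] - rt - 0.25)^2 / (2 * t_sigma^2))
      }
    }
  }
  out <- set_stream_meta(
    tibble::tibble(time_s = t, value = x), fs, "ECG", "mV")
  attr(out, "r_peaks") <- r_times[r_times >= start_time &
                                    r_times < start_time + duration]
  out
}

# 1/f^exponent-shaped Gaussian noise via spectral shaping, normalized to sd
one_over_f_noise <- function(n, exponent, sd, fs) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (exponent == 0) return(w * sd / stats::sd(w))
  W <- stats::fft(w)
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided
  scale <- ifelse(freq > 0, freq^(-exponent / 2), 0)
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Synthesize single-channel EEG with per-trial pre-stimulus alpha bursts
#'
#' 1/f-shaped background noise plus a sinusoid at `alpha_freq` whose
#' amplitude equals each trial's latent value throughout the 1-s window
#' preceding that trial's onset, with 0.2-s raised-cosine on/off ramps
#' outside the window.
#'
#' @param onsets Unreliable-arrow onset times, s.
#' @param alpha_amp Latent alpha amplitude per onset, µV.
#' @param duration Stream duration, s.
#' @param fs Sampling rate, Hz (500 by default).
#' @param noise_sd Background RMS amplitude, µV.
#' @param noise_exponent 1/f spectral slope of the background.
#' @param alpha_freq Alpha frequency, Hz.
#' @param start_time Stream start time, s.
#' @return An EEG [signal_stream()] (µV).
#' @export
synthesize_eeg <- function(onsets, alpha_amp, duration, fs = 500,
                           noise_sd = 10, noise_exponent = 1,
                           alpha_freq = 10, start_time = 0) {
  stopifnot(length(onsets) == length(alpha_amp))
  n <- round(duration * fs)
  t <- start_time + (seq_len(n) - 1) / fs
  x <- one_over_f_noise(n, noise_exponent, noise_sd, fs)
  ramp <- 0.2
  env <- numeric(n)
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    lo <- on - 1
    i <- which(t >= lo - ramp & t < on + ramp)
    if (!length(i)) next
    ti <- t[i]
    e <- ifelse(ti < lo, 0.5 * (1 + cos(pi * (lo - ti) / ramp)),
                ifelse(ti < on, 1, 0.5 * (1 + cos(pi * (ti - on) / ramp))))
    env[i] <- pmax(env[i], alpha_amp[k] * e)
  }
  x <- x + env * sin(2 * pi * alpha_freq * t)
  set_stream_meta(tibble::tibble(time_s = t, value = x), fs, "Pz", "uV")
}

#' Synthesize a gaze stream with confidence dropout
#'
#' x and y are i.i.d. Gaussian about the screen center with the given
#' dispersions; a fraction `p_low_confidence` of samples receives a
#' confidence value below 0.8 (uniform on `[0, 0.8)`), the rest uniform on
#' `[0.8, 1]`.
#'
#' @param duration Stream duration, s.
#' @param sigma_x,sigma_y Gaze dispersion, px.
#' @param fps Frame rate, Hz.
#' @param p_low_confidence Proportion of low-confidence samples.
#' @param center Screen center, px (named x, y).
#' @param start_time Stream start time, s.
#' @return A gaze stream tibble (see [gaze_stream()]).
#' @export
synthesize_gaze <- function(duration, sigma_x, sigma_y, fps = 120,
                            p_low_confidence = 0.1,
                            center = c(x = 960, y = 600), start_time = 0) {
  stopifnot(fps > 0, sigma_x >= 0, sigma_y >= 0)
  n <- round(duration * fps)
  low <- stats::runif(n) < p_low_confidence
  conf <- ifelse(low, stats::runif(n, 0, 0.8), stats::runif(n, 0.8, 1))
  gaze_stream(
    x = center[["x"]] + stats::rnorm(n, 0, sigma_x),
    y = center[["y"]] + stats::rnorm(n, 0, sigma_y),
    confidence = conf, sampling_rate = fps, start_time = start_time
  )
}

# Parse a beta term name like "alpha_db:rmssd:period" into its factors and
# evaluate the product of the corresponding standardized latent columns.
eval_beta_terms <- function(beta, z) {
  eta <- rep(0, nrow(z))
  for (term in names(beta)) {
    if (term == "intercept") {
      eta <- eta + beta[[term]]
      next
    }
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    bad <- setdiff(parts, names(z))
    if (length(bad)) {
      stop("beta term refers to unknown feature(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    eta <- eta + beta[[term]] * Reduce(`*`, z[parts])
  }
  eta
}

# Per-trial latent draws for one participant's unreliable events.
draw_trial_latents <- function(events, config) {
  unrel <- dplyr::filter(events, .data$arrow_type == "unreliable")
  n <- nrow(unrel)
  cv <- config$gaze_sigma_trial_cv
  z_alpha <- stats::rnorm(n)
  z_rr <- stats::rnorm(n)
  z_hrv <- stats::rnorm(n)
  z_lnx <- stats::rnorm(n)
  tibble::tibble(
    participant = unrel$participant,
    period = unrel$period,
    trial = unrel$trial_index,
    onset_s = unrel$onset_s,
    outcome = unrel$outcome,
    alpha_amp = pmax(config$alpha_base + config$alpha_trial_sd * z_alpha, 0.2),
    trial_mean_rr = pmax(config$rr_mean + config$rr_trial_sd * z_rr, 300),
    trial_rmssd = pmax(config$rr_rmssd_target + config$rmssd_trial_sd * z_hrv, 1),
    trial_sigma_x = config$gaze_sigma_x * exp(cv * z_lnx),
    trial_sigma_y = config$gaze_sigma_y * exp(cv * z_lnx),
    alpha_db = z_alpha, mean_rr = z_rr, rmssd = z_hrv, ln_x = z_lnx,
    period_c = unrel$period - 3
  )
}

#' Generate button-press responses from ground-truth latents
#'
#' For every non-missed unreliable arrow: a `U` press at onset + RT, where
#' RT is the configured linear model of the standardized latent features
#' plus participant and trial random intercepts and Gaussian residual,
#' floored at `rt_floor`; then a second press reporting the lane-change
#' outcome (`N`/`I`/`C`) with the configured accuracy. Reliable arrows draw
#' a false alarm at `false_alarm_rate`.
#'
#' @param events Event schedule (one participant).
#' @param latents Per-trial latent tibble from the generator (one row per
#'   unreliable event, in onset order).
#' @param config A [generator_config()].
#' @param b_participant,b_trial Random intercepts: a scalar for the
#'   participant and a length-10 vector indexed by trial position.
#' @return A list with `responses` (tibble `time_s`, `key`) and
#'   `ground_truth` (latents plus `eta`, `rt_true`, `missed`).
#' @export
generate_responses <- function(events, latents, config,
                               b_participant = stats::rnorm(1, 0, config$sd_participant),
                               b_trial = stats::rnorm(max(latents$trial), 0, config$sd_trial)) {
  z <- latents[c("alpha_db", "mean_rr", "rmssd", "ln_x")]
  z$period <- latents$period_c
  eta <- eval_beta_terms(config$beta, z)
  n <- nrow(latents)
  rt_true <- pmax(eta + b_participant + b_trial[latents$trial] +
                    stats::rnorm(n, 0, config$sd_resid), config$rt_floor)
  missed <- stats::runif(n) < config$miss_rate
  key_map <- c(no_change = "N", incorrect_change = "I", correct_change = "C")

  hit_rows <- which(!missed)
  press_u <- tibble::tibble(
    time_s = latents$onset_s[hit_rows] + rt_true[hit_rows] / 1000,
    key = "U"
  )
  correct2 <- stats::runif(length(hit_rows)) < config$second_press_accuracy
  key2 <- vapply(seq_along(hit_rows), function(i) {
    truth <- key_map[[latents$outcome[hit_rows[i]]]]
    if (correct2[i]) truth else sample(setdiff(c("N", "I", "C"), truth), 1)
  }, character(1))
  press_2 <- tibble::tibble(
    time_s = press_u$time_s + config$second_press_delay,
    key = key2
  )
  reliable <- dplyr::filter(events, .data$arrow_type == "reliable")
  fa <- reliable$onset_s[stats::runif(nrow(reliable)) < config$false_alarm_rate]
  press_fa <- tibble::tibble(time_s = fa + 0.5, key = "U")

  responses <- dplyr::arrange(
    dplyr::bind_rows(press_u, press_2, press_fa), .data$time_s)
  ground_truth <- dplyr::mutate(latents,
    b_participant = b_participant,
    b_trial = b_trial[.data$trial],
    eta = eta, rt_true = rt_true, missed = missed)
  list(responses = responses, ground_truth = ground_truth)
}

#' Simulate a full multimodal session for one participant
#'
#' Generates the arrow schedule, per-trial latent state, and raw ECG, EEG
#' and gaze streams whose pre-stimulus windows carry that latent state:
#' RR-interval statistics switch to the trial's latent (meanRR, RMSSD)
#' inside each 10-s pre-stimulus window, EEG alpha amplitude equals the
#' trial's latent amplitude inside the 1-s window, and gaze dispersion
#' equals the trial's latent sigma inside the 3-s window. Responses are
#' generated from the same latents, so every feature the pipeline extracts
#' has a known ground truth.
#'
#' @param config A [generator_config()].
#' @param participant Participant id.
#' @return A list with `events`, `responses`, `ecg`, `eeg`, `gaze`,
#'   `ground_truth`, and `config`.
#' @export
simulate_session <- function(config = generator_config(), participant = 1L) {
  events <- generate_event_schedule(config, participant)
  latents <- draw_trial_latents(events, config)
  duration <- config$n_periods * config$period_duration

  # --- ECG: beat-by-beat walk with per-trial RR statistics in pre-windows
  pre_lo <- latents$onset_s - 10
  pre_hi <- latents$onset_s
  sigma_base <- config$rr_rmssd_target / sqrt(2)
  r_times <- numeric(0)
  t <- 0.4
  while (t < duration) {
    r_times[length(r_times) + 1L] <- t
    k <- which(t >= pre_lo & t < pre_hi)
    if (length(k)) {
      m <- latents$trial_mean_rr[k[1]]
      s <- latents$trial_rmssd[k[1]] / sqrt(2)
    } else {
      m <- config$rr_mean
      s <- sigma_base
    }
    step <- -1
    while (step <= 0) step <- (m + stats::rnorm(1, 0, s)) / 1000
    t <- t + step
  }
  ecg <- ecg_waveform(r_times, duration, config$ecg_fs,
                      r_amplitude = config$r_amplitude,
                      t_amplitude_frac = config$t_amplitude_frac,
                      noise_sd = config$ecg_noise_sd)

  # --- EEG
  eeg <- synthesize_eeg(latents$onset_s, latents$alpha_amp, duration,
                        fs = config$eeg_fs, noise_sd = config$eeg_noise_sd,
                        noise_exponent = config$eeg_noise_exponent,
                        alpha_freq = config$alpha_freq)

  # --- gaze: per-sample sigma envelope (trial sigma inside 3-s pre-windows)
  n_g <- round(duration * config$gaze_fps)
  tg <- (seq_len(n_g) - 1) / config$gaze_fps
  sx <- rep(config$gaze_sigma_x, n_g)
  sy <- rep(config$gaze_sigma_y, n_g)
  for (k in seq_len(nrow(latents))) {
    i <- which(tg >= latents$onset_s[k] - 3 & tg < latents$onset_s[k])
    sx[i] <- latents$trial_sigma_x[k]
    sy[i] <- latents$trial_sigma_y[k]
  }
  low <- stats::runif(n_g) < config$p_low_confidence
  gaze <- gaze_stream(
    x = config$screen_center[["x"]] + stats::rnorm(n_g, 0, 1) * sx,
    y = config$screen_center[["y"]] + stats::rnorm(n_g, 0, 1) * sy,
    confidence = ifelse(low, stats::runif(n_g, 0, 0.8),
                        stats::runif(n_g, 0.8, 1)),
    sampling_rate = config$gaze_fps
  )

  resp <- generate_responses(events, latents, config)
  list(events = events, responses = resp$responses, ecg = ecg, eeg = eeg,
       gaze = gaze, ground_truth = resp$ground_truth, config = config)
}

#' Simulate a study-level feature table directly from the latent model
#'
#' Skips raw-signal synthesis and returns the per-trial feature table the
#' mixed-model stage consumes, generated from exactly the model family it
#' fits: standardized latent features, the configured fixed-effect
#' coefficients (including interactions), crossed participant and trial
#' random intercepts, and Gaussian residual. This is the fast path for
#' parameter-recovery and calibration studies; `measurement_sd` adds
#' optional feature measurement noise (0 by default, so coefficient
#' recovery is unbiased).
#'
#' @param config A [generator_config()].
#' @return A list with `trials` (tibble: `participant`, `period`, `trial`,
#'   `alpha_db`, `mean_rr`, `rmssd`, `ln_x`, `ln_y`, `rt`; `rt` is `NA` for
#'   missed trials) and `ground_truth` (adds the random intercepts and the
#'   noiseless linear predictor `eta`).
#' @export
simulate_feature_table <- function(config = generator_config()) {
  n_trials <- round(config$p_unreliable * config$n_arrows)
  b_trial <- stats::rnorm(n_trials, 0, config$sd_trial)
  out <- purrr::map(seq_len(config$n_participants), function(pp) {
    grid <- tidyr::expand_grid(period = seq_len(config$n_periods),
                               trial = seq_len(n_trials))
    n <- nrow(grid)
    z <- tibble::tibble(
      alpha_db = stats::rnorm(n), mean_rr = stats::rnorm(n),
      rmssd = stats::rnorm(n), ln_x = stats::rnorm(n),
      period = grid$period - 3
    )
    eta <- eval_beta_terms(config$beta, z)
    b_p <- stats::rnorm(1, 0, config$sd_participant)
    rt <- pmax(eta + b_p + b_trial[grid$trial] +
                 stats::rnorm(n, 0, config$sd_resid), config$rt_floor)
    missed <- stats::runif(n) < config$miss_rate
    meas <- function(v) v + stats::rnorm(n, 0, config$measurement_sd)
    tibble::tibble(
      participant = pp, period = grid$period, trial = grid$trial,
      alpha_db = meas(z$alpha_db), mean_rr = meas(z$mean_rr),
      rmssd = meas(z$rmssd), ln_x = meas(z$ln_x),
      ln_y = meas(z$ln_x),
      rt = ifelse(missed, NA_real_, rt),
      z_alpha = z$alpha_db, z_rr = z$mean_rr, z_hrv = z$rmssd,
      z_lnx = z$ln_x, b_participant = b_p, b_trial = b_trial[grid$trial],
      eta = eta, rt_true = rt, missed = missed
    )
  })
  all <- dplyr::bind_rows(out)
  feature_cols <- c("participant", "period", "trial", "alpha_db", "mean_rr",
                    "rmssd", "ln_x", "ln_y", "rt")
  list(trials = all[feature_cols], ground_truth = all)
}
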