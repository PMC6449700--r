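test_that("a generated drive has 50 arrows, 10 unreliable, 6/2/2 outcomes", {
  set.seed(1)
  ev <- generate_event_schedule(generator_config(n_periods = 1))
  expect_equal(nrow(ev), 50)
  expect_equal(sum(ev$arrow_type == "unreliable"), 10)
  expect_equal(sum(ev$outcome == "no_change"), 6)
  expect_equal(sum(ev$outcome == "incorrect_change"), 2)
  expect_equal(sum(ev$outcome == "correct_change"), 2)
  expect_true(all(ev$outcome[ev$arrow_type == "reliable"] == "normal"))
})

test_that("schedules are strictly increasing, fit the period, and are seed-reproducible", {
  set.seed(2)
  cfg <- generator_config()
  ev <- generate_event_schedule(cfg)
  expect_false(is.unsorted(ev$onset_s, strictly = TRUE))
  for (p in seq_len(cfg$n_periods)) {
    on <- ev$onset_s[ev$period == p]
    expect_true(all(on > (p - 1) * cfg$period_duration))
    expect_true(all(on < p * cfg$period_duration))
  }
  # unreliable trial bookkeeping: indices 1..10 in onset order per period
  idx <- ev$trial_index[ev$arrow_type == "unreliable" & ev$period == 1]
  expect_equal(idx, 1:10)
  set.seed(99); a <- generate_event_schedule(cfg)
  set.seed(99); b <- generate_event_schedule(cfg)
  expect_identical(a, b)
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(period_duration = 40), "too short")
  expect_error(generator_config(outcome_split = c(no_change = 5L,
                                                  incorrect_change = 2L,
                                                  correct_change = 2L)),
               "outcome_split")
  expect_error(generator_config(p_unreliable = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(nonsense = 1), "unknown")
})

test_that("RR series hit their mean and RMSSD targets", {
  expect_equal(generate_rr_series(800, 0, 10), rep(800, 9))
  set.seed(3)
  rr <- generate_rr_series(800, 30, 1000)
  expect_true(all(rr > 0))
  expect_lt(abs(mean(rr) - 800) / 800, 0.01)
  expect_lt(abs(rmssd_loop(rr) - 30) / 30, 0.05)
  expect_error(generate_rr_series(800, 600, 100), "non-positive")
})

test_that("synthetic ECG places QRS templates at the RR-derived times", {
  set.seed(4)
  rr <- c(800, 800)
  ecg <- synthesize_ecg(rr, fs = 250, noise_sd = 0, start_time = 0.6)
  truth <- attr(ecg, "r_peaks")
  expect_equal(truth, c(1.0, 1.8, 2.6))
  # noiseless: global maxima occur at the template centers
  for (tt in truth) {
    i <- which(ecg$time_s >= tt - 0.2 & ecg$time_s < tt + 0.2)
    expect_lt(abs(ecg$time_s[i][which.max(ecg$value[i])] - tt), 0.04)
  }
  # linearity in r_amplitude
  set.seed(4)
  ecg2 <- synthesize_ecg(rr, fs = 250, noise_sd = 0, r_amplitude = 2,
                         start_time = 0.6)
  expect_equal(max(ecg2$value), 2 * max(ecg$value), tolerance = 1e-9)
})

test_that("synthetic EEG carries a 10-Hz peak scaled by the latent amplitude", {
  set.seed(5)
  eeg <- synthesize_eeg(onsets = 10, alpha_amp = 8, duration = 12,
                        noise_sd = 1)
  ep <- epoch_prestimulus(eeg, 10)
  spec <- eeg_spectrum(ep$samples[[1]], 500)
  expect_equal(spec$freq_hz[which.max(spec$power)], 500 / 512 * 10)
})

test_that("zero-alpha EEG shows no spectral peak above the 1/f trend near 10 Hz", {
  set.seed(6)
  onsets <- seq(5, by = 3, length.out = 20)
  eeg <- synthesize_eeg(onsets, rep(0, 20), duration = max(onsets) + 1,
                        noise_sd = 10)
  specs <- purrr::map(epoch_prestimulus(eeg, onsets)$samples,
                      eeg_spectrum, fs = 500)
  avg <- rowMeans(do.call(cbind, purrr::map(specs, "power")))
  f <- specs[[1]]$freq_hz
  db <- 10 * log10(avg)
  fit_band <- f >= 2 & f <= 45 & !(f >= 8 & f <= 12)
  trend <- lm(db[fit_band] ~ log10(f[fit_band]))
  i10 <- which.min(abs(f - 10))
  resid10 <- db[i10] - unname(
    coef(trend)[1] + coef(trend)[2] * log10(f[i10]))
  expect_lt(resid10, 3)
})

test_that("synthetic gaze matches its dispersion and dropout parameters", {
  set.seed(7)
  g <- synthesize_gaze(10000 / 120, sigma_x = 50, sigma_y = 40,
                       p_low_confidence = 0.2)
  hi <- g[g$confidence >= 0.8, ]
  expect_lt(abs(sd(hi$x_px) - 50) / 50, 0.03)
  expect_lt(abs(mean(g$confidence < 0.8) - 0.2), 0.02)
  g0 <- synthesize_gaze(1, sigma_x = 0, sigma_y = 0)
  expect_true(all(g0$x_px == 960), all(g0$y_px == 600))
})

test_that("responses reduce to the intercept when all noise and slopes are zero", {
  set.seed(8)
  cfg <- generator_config(beta = c(intercept = 900), sd_participant = 0,
                          sd_trial = 0, sd_resid = 0, miss_rate = 0,
                          false_alarm_rate = 0)
  ev <- generate_event_schedule(cfg, participant = 1)
  lat <- driverattn:::draw_trial_latents(ev, cfg)
  resp <- generate_responses(ev, lat, cfg)
  expect_true(all(resp$ground_truth$rt_true == 900))
  u <- resp$responses[resp$responses$key == "U", ]
  expect_equal(u$time_s, lat$onset_s + 0.9, tolerance = 1e-9)
})

test_that("miss rate is honored and large residuals push RTs past the cap", {
  set.seed(9)
  ft <- simulate_feature_table(generator_config(n_participants = 5,
                                                miss_rate = 0.1))
  expect_equal(nrow(ft$trials), 5 * 5 * 10)
  expect_lt(abs(mean(is.na(ft$trials$rt)) - 0.1), 0.03)
  set.seed(10)
  big <- simulate_feature_table(generator_config(n_participants = 2,
                                                 sd_resid = 1500,
                                                 miss_rate = 0))
  expect_gt(sum(big$trials$rt > 2600), 0)
})

test_that("feature-table simulation is seed-reproducible and conserves trials", {
  cfg <- generator_config(n_participants = 3)
  set.seed(42); a <- simulate_feature_table(cfg)
  set.seed(42); b <- simulate_feature_table(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$trials),
               3 * cfg$n_periods * round(cfg$p_unreliable * cfg$n_arrows))
})
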