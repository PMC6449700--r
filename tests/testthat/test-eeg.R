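test_that("the band-pass kills DC and passes 10 Hz at unit gain", {
  fs <- 500
  t <- seq_len(10 * fs) / fs
  dc <- signal_stream(rep(5, length(t)), fs)
  out <- filter_eeg(dc)
  expect_lt(max(abs(out$value)), 0.05)  # < 1% of the DC level

  tone <- signal_stream(sin(2 * pi * 10 * t), fs)
  y <- filter_eeg(tone)$value
  mid <- seq(2 * fs, 8 * fs)  # avoid edges
  gain <- sqrt(mean(y[mid]^2) / mean(tone$value[mid]^2))
  expect_lt(abs(gain - 1), 0.01)
})

test_that("a 60-Hz tone is attenuated by at least 40 dB", {
  fs <- 500
  t <- seq_len(10 * fs) / fs
  tone <- signal_stream(sin(2 * pi * 60 * t), fs)
  y <- filter_eeg(tone)$value
  mid <- seq(2 * fs, 8 * fs)
  atten_db <- -20 * log10(sqrt(mean(y[mid]^2) / mean(tone$value[mid]^2)))
  expect_gte(atten_db, 40)
})

test_that("records shorter than the filter are fatal", {
  short <- signal_stream(rnorm(200), 500)
  expect_error(filter_eeg(short), "shorter")
})

test_that("zero-phase filtering does not shift a pre-stimulus burst", {
  fs <- 500
  eeg <- synthesize_eeg(onsets = 5, alpha_amp = 10, duration = 10,
                        noise_sd = 0)
  y <- filter_eeg(eeg)
  # alpha envelope is centered on [4, 5); energy must stay there, not lag
  in_win <- sum(y$value[y$time_s >= 4 & y$time_s < 5]^2)
  after <- sum(y$value[y$time_s >= 5.3 & y$time_s < 6.3]^2)
  expect_gt(in_win, 50 * after)
})

test_that("mastoid re-referencing is exact sample-wise arithmetic", {
  mk <- function(v) signal_stream(rep(v, 100), 500)
  ch <- list(Pz = mk(5), Cz = mk(3), A1 = mk(2), A2 = mk(4))
  out <- rereference(ch)
  expect_true(all(out$Pz$value == 2))
  expect_true(all(out$Cz$value == 0))
  expect_true(all(out$A1$value == 2))  # references untouched

  zero_ref <- rereference(list(Pz = mk(5), A1 = mk(0), A2 = mk(0)))
  expect_true(all(zero_ref$Pz$value == 5))
  expect_error(rereference(list(Pz = mk(1), A1 = mk(0))), "missing")
})

test_that("the ±100 µV rule invalidates epochs and spares clean ones", {
  clean <- list(rep(99, 500), c(rep(0, 250), 150, rep(0, 249)),
                rep(-99.5, 500))
  epochs <- tibble::tibble(onset_s = 1:3, samples = clean, n = 500,
                           complete = TRUE)
  out <- screen_artifacts(epochs)
  expect_equal(out$valid, c(TRUE, FALSE, TRUE))
})

test_that("a channel with inflated variance is flagged at 2 SD", {
  set.seed(30)
  chans <- purrr::map(1:8, function(i) {
    signal_stream(rnorm(2000, sd = if (i == 3) 10 else 1), 500)
  })
  names(chans) <- paste0("ch", 1:8)
  expect_equal(flag_bad_channels(chans), "ch3")
})

test_that("the alpha bin at 500 Hz / nfft 512 is 9.7656 Hz, printing as 9.76", {
  x <- sin(2 * pi * 9.765625 * seq_len(500) / 500)
  db <- alpha_power_db(x, 500)
  expect_equal(attr(db, "freq_hz"), 500 / 512 * 10)
  expect_equal(trunc(attr(db, "freq_hz") * 100) / 100, 9.76)
  spec <- eeg_spectrum(x, 500)
  expect_equal(spec$freq_hz[which.max(spec$power)], 500 / 512 * 10)
})

test_that("alpha power in dB is linear in log amplitude", {
  t <- seq_len(500) / 500
  a1 <- alpha_power_db(2.0 * sin(2 * pi * 10 * t), 500)
  a2 <- alpha_power_db(4.0 * sin(2 * pi * 10 * t), 500)
  expect_equal(as.numeric(a2 - a1), 20 * log10(2), tolerance = 0.1)
})

test_that("degenerate epochs hit the power floor instead of -Inf", {
  db <- alpha_power_db(rep(0, 500), 500)
  expect_equal(as.numeric(db), 10 * log10(1e-12))
})

test_that("linear detrending makes alpha power ramp-invariant", {
  set.seed(31)
  t <- seq_len(500) / 500
  x <- 3 * sin(2 * pi * 10 * t) + rnorm(500)
  base <- as.numeric(alpha_power_db(x, 500))
  for (ab in list(c(5, 0), c(0, 40), c(-7, 25))) {
    ramped <- x + ab[1] + ab[2] * t
    expect_lt(abs(as.numeric(alpha_power_db(ramped, 500)) - base), 0.01)
  }
})

test_that("epoching yields 1-s pre-stimulus windows flagged for completeness", {
  s <- signal_stream(rnorm(5000), 500)
  ep <- epoch_prestimulus(s, c(2, 9.9999, 0.2))
  expect_equal(ep$n[1], 500)
  expect_true(ep$complete[1])
  expect_false(ep$complete[3])  # window starts before the record
})
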