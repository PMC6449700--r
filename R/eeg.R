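#' Band-pass filter a continuous EEG record
#'
#' Zero-phase FIR filtering of the continuous record before epoching:
#' a windowed-sinc (Hamming) high-pass with 1-Hz cutoff and 2-Hz
#' transition bandwidth followed by a low-pass with 40-Hz cutoff and 10-Hz
#' transition bandwidth. Cutoffs are -6 dB points; filter order is
#' `ceiling(3.3 * fs / transition)` rounded up to even, the standard
#' Hamming design rule. Each linear-phase filter is applied once and its
#' group delay compensated exactly, so pre-stimulus timing does not shift;
#' edges are handled by reflection padding. Output length equals input
#' length.
#'
#' @param stream An EEG [signal_stream()] (rate >= 100 Hz).
#' @param high_pass,low_pass Cutoff frequencies, Hz. `NULL` disables a stage.
#' @param transition_hp,transition_lp Transition bandwidths, Hz.
#' @return The filtered stream.
#' @export
filter_eeg <- function(stream, high_pass = 1, low_pass = 40,
                       transition_hp = 2, transition_lp = 10) {
  fs <- stream_rate(stream)
  stopifnot(fs >= 100)
  x <- stream$value
  if (!is.null(high_pass)) {
    h <- fir_hamming(fs, high_pass, transition_hp, type = "high")
    x <- filt_zerophase(x, h)
  }
  if (!is.null(low_pass)) {
    h <- fir_hamming(fs, low_pass, transition_lp, type = "low")
    x <- filt_zerophase(x, h)
  }
  out <- stream
  out$value <- x
  out
}

fir_hamming <- function(fs, cutoff, transition, type = c("low", "high")) {
  type <- match.arg(type)
  order <- ceiling(3.3 * fs / transition)
  if (order %% 2 == 1) order <- order + 1  # even order (type-I linear phase)
  lp <- signal::fir1(order, cutoff / (fs / 2), type = "low",
                     window = signal::hamming(order + 1))
  lp <- lp / sum(lp)  # exact unit DC gain
  if (type == "low") return(lp)
  # spectral inversion: exact zero at DC, -6 dB at the cutoff
  hp <- -lp
  hp[order / 2 + 1] <- hp[order / 2 + 1] + 1
  hp
}

# single-pass zero-phase application of a symmetric odd-length FIR
filt_zerophase <- function(x, h) {
  n <- length(x)
  half <- (length(h) - 1L) %/% 2L
  if (n <= length(h)) {
    stop("record shorter than the filter; cannot filter", call. = FALSE)
  }
  pad_l <- rev(x[2:(half + 1L)])
  pad_r <- rev(x[(n - half):(n - 1L)])
  xp <- c(pad_l, x, pad_r)
  y <- signal::fftfilt(h, xp)
  # fftfilt introduces the causal delay of length(h)-1; with the reflect
  # padding of `half` samples the zero-phase output starts at 2*half + 1
  y[(2L * half + 1L):(2L * half + n)]
}

#' Re-reference channels to the mastoid average
#'
#' Subtracts, sample-wise, the mean of two reference channels (typically
#' the left and right mastoids) from every data channel.
#'
#' @param channels Named list of [signal_stream()]s of equal length.
#' @param ref_ids Names of the two reference channels.
#' @return The list with every non-reference channel re-referenced.
#' @export
rereference <- function(channels, ref_ids = c("A1", "A2")) {
  if (!all(ref_ids %in% names(channels))) {
    stop("reference channel(s) missing: ",
         paste(setdiff(ref_ids, names(channels)), collapse = ", "),
         call. = FALSE)
  }
  ref <- (channels[[ref_ids[1]]]$value + channels[[ref_ids[2]]]$value) / 2
  data_ids <- setdiff(names(channels), ref_ids)
  for (id in data_ids) {
    channels[[id]]$value <- channels[[id]]$value - ref
  }
  channels
}

#' Epoch a continuous record into 1-s pre-stimulus windows
#'
#' @param stream A filtered EEG [signal_stream()].
#' @param onsets Stimulus onset times, s.
#' @param duration Epoch duration, s (window is `[onset - duration, onset)`).
#' @return A tibble with one row per onset: `onset_s`, `samples`
#'   (list-column of numeric vectors), `n`, `complete` (whether the full
#'   window was inside the record).
#' @export
epoch_prestimulus <- function(stream, onsets, duration = 1) {
  fs <- stream_rate(stream)
  purrr::map_dfr(onsets, function(on) {
    w <- suppressWarnings(extract_window(stream, on - duration, on))
    tibble::tibble(
      onset_s = on, samples = list(w$value), n = nrow(w),
      complete = abs(nrow(w) - round(duration * fs)) <= 1
    )
  })
}

#' Screen epochs and channels for artifacts
#'
#' An epoch is invalid if any sample magnitude exceeds `amp_limit` (100 µV
#' by default). Separately, a channel is flagged as artifactual when its
#' record-level amplitude summary (SD) lies more than `z_limit` standard
#' deviations from the across-channel mean; flagged channels are reported,
#' not interpolated.
#'
#' @param epochs Epoch tibble from [epoch_prestimulus()].
#' @param amp_limit Absolute amplitude limit, µV.
#' @return `screen_artifacts()`: the epoch tibble with a logical `valid`
#'   column. `flag_bad_channels()`: character vector of flagged channel
#'   names.
#' @export
screen_artifacts <- function(epochs, amp_limit = 100) {
  epochs$valid <- purrr::map_lgl(epochs$samples, function(v) {
    length(v) > 0 && all(abs(v) <= amp_limit)
  }) & epochs$complete
  epochs
}

#' @rdname screen_artifacts
#' @param channels Named list of [signal_stream()]s.
#' @param z_limit Across-channel z-score limit.
#' @export
flag_bad_channels <- function(channels, z_limit = 2) {
  sds <- vapply(channels, function(s) stats::sd(s$value), numeric(1))
  z <- (sds - mean(sds)) / stats::sd(sds)
  names(channels)[abs(z) > z_limit]
}

#' Hamming-windowed power spectral density of one epoch
#'
#' The epoch is linearly detrended (least-squares line removed), Hamming
#' windowed, and transformed with length `nfft` = the next power of two at
#' or above the epoch length (512 for a 1-s epoch at 500 Hz); power is
#' scaled as a one-sided PSD. On that grid the bin nearest 10 Hz lies at
#' `500/512 * 10 = 9.7656 Hz`, i.e. 9.76 Hz to two truncated decimals.
#'
#' @param samples Numeric vector (one epoch).
#' @param fs Sampling rate, Hz.
#' @param nfft Transform length; default next power of two >= epoch length.
#' @return A tibble `freq_hz`, `power` (µV²/Hz).
#' @export
eeg_spectrum <- function(samples, fs, nfft = NULL) {
  n <- length(samples)
  stopifnot(n >= 8)
  if (is.null(nfft)) nfft <- next_pow2(n)
  t <- seq_len(n)
  x <- stats::lm.fit(cbind(1, t), samples)$residuals  # linear detrend
  w <- as.numeric(signal::hamming(n))
  xw <- c(x * w, numeric(nfft - n))
  X <- stats::fft(xw)[seq_len(nfft / 2 + 1)]
  p <- (Mod(X)^2) / (fs * sum(w^2))
  p[2:(nfft / 2)] <- 2 * p[2:(nfft / 2)]  # one-sided
  tibble::tibble(freq_hz = (seq_len(nfft / 2 + 1) - 1) * fs / nfft, power = p)
}

#' Pre-stimulus alpha power in dB at the bin nearest 10 Hz
#'
#' Computes the epoch's PSD with [eeg_spectrum()], floors the power at
#' `power_floor` to keep the log finite on degenerate input, converts to
#' `10 * log10(power)`, and returns the value at the grid frequency
#' nearest `alpha_freq`.
#'
#' @inheritParams eeg_spectrum
#' @param alpha_freq Target frequency, Hz.
#' @param power_floor Minimum power before the log.
#' @return A scalar dB value, with attribute `freq_hz` (the bin used).
#' @export
alpha_power_db <- function(samples, fs, nfft = NULL, alpha_freq = 10,
                           power_floor = 1e-12) {
  spec <- eeg_spectrum(samples, fs, nfft)
  i <- which.min(abs(spec$freq_hz - alpha_freq))
  db <- 10 * log10(max(spec$power[i], power_floor))
  attr(db, "freq_hz") <- spec$freq_hz[i]
  db
}
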