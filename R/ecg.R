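#' Detect R peaks by MODWT band selection
#'
#' The ECG is decomposed with the MODWT (sym4); the detail levels whose
#' octave pass-bands have midpoints inside the QRS energy band (~8-25 Hz at
#' the stream's sampling rate; the lower edge sits above the T wave's
#' spectral content) are summed into a band-limited
#' reconstruction, which is squared and scanned for local maxima above an
#' adaptive threshold (a fraction of a rolling amplitude estimate),
#' enforcing a 250-ms refractory period. Each candidate is then refined to
#' the raw-signal maximum within +/-50 ms, so reported times are
#' amplitude-scale invariant and land on the R wave itself.
#'
#' @param ecg An ECG [signal_stream()] (any sampling rate >= 100 Hz).
#' @param qrs_band Frequency band (Hz) whose MODWT levels are retained.
#' @param threshold_frac Threshold as a fraction of the rolling 95th
#'   percentile (2-s blocks) of the squared reconstruction.
#' @param refractory Minimum peak separation, s.
#' @param wavelet Wavelet family for the MODWT.
#' @return Numeric vector of peak times in seconds (empty, with a warning,
#'   for degenerate input).
#' @export
detect_r_peaks <- function(ecg, qrs_band = c(8, 25), threshold_frac = 0.3,
                           refractory = 0.25, wavelet = "sym4") {
  fs <- stream_rate(ecg)
  x <- ecg$value
  n <- length(x)
  if (n < 2 * fs || stats::sd(x) == 0) {
    warning("ECG record too short or constant; no peaks detected",
            call. = FALSE)
    return(numeric(0))
  }
  # level j detail spans [fs/2^(j+1), fs/2^j]; keep levels whose band
  # midpoint falls in the QRS band
  j_max <- floor(log2(n))
  mids <- vapply(seq_len(j_max), function(j) {
    (fs / 2^(j + 1) + fs / 2^j) / 2
  }, numeric(1))
  levels_keep <- which(mids >= qrs_band[1] & mids <= qrs_band[2])
  if (!length(levels_keep)) {
    stop("sampling rate too low to resolve the QRS band", call. = FALSE)
  }
  mra <- modwt_mra(x, max(levels_keep), wavelet)
  band <- Reduce(`+`, mra[levels_keep])
  sq <- band^2

  thr <- rolling_block_stat(sq, block = round(2 * fs),
                            fun = function(v) stats::quantile(v, 0.95))
  thr <- threshold_frac * thr

  is_max <- c(FALSE, diff(sq) > 0) & c(diff(sq) < 0, FALSE)
  cand <- which(is_max & sq > thr & thr > 0)
  if (!length(cand)) return(numeric(0))
  # greedy refractory enforcement, strongest candidates first
  keep <- logical(length(sq))
  min_gap <- round(refractory * fs)
  taken <- integer(0)
  for (i in cand[order(sq[cand], decreasing = TRUE)]) {
    if (!length(taken) || all(abs(taken - i) >= min_gap)) {
      keep[i] <- TRUE
      taken <- c(taken, i)
    }
  }
  peaks <- sort(which(keep))
  # refine to raw-amplitude maximum within +/-50 ms
  half <- round(0.05 * fs)
  half <- as.integer(half)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  sort(unique(ecg$time_s[refined]))
}

# blockwise statistic extended to a step function over the full series
rolling_block_stat <- function(x, block, fun) {
  n <- length(x)
  starts <- seq(1L, n, by = block)
  vals <- vapply(starts, function(s) fun(x[s:min(n, s + block - 1L)]),
                 numeric(1))
  rep(vals, times = diff(c(starts, n + 1L)))
}

#' Heart-rate metrics from peak times in a pre-stimulus window
#'
#' meanRR is the arithmetic mean of successive R-peak differences inside
#' the half-open window; RMSSD is the root mean square of successive
#' differences of those RR intervals. Both are reported in ms. At least 3
#' peaks (2 intervals) are required; otherwise the metrics are `NA` and
#' `valid` is `FALSE` so the trial can be excluded rather than silently
#' dropped.
#'
#' @param peaks Peak times, s (typically from [detect_r_peaks()] run once
#'   on the full record).
#' @param t_start,t_end Window bounds, s (half-open).
#' @return A one-row tibble: `mean_rr`, `rmssd` (ms), `n_intervals`,
#'   `valid`.
#' @export
hrv_metrics <- function(peaks, t_start, t_end) {
  p <- peaks[peaks >= t_start & peaks < t_end]
  if (length(p) < 3) {
    return(tibble::tibble(mean_rr = NA_real_, rmssd = NA_real_,
                          n_intervals = max(0L, length(p) - 1L),
                          valid = FALSE))
  }
  rr <- diff(p) * 1000
  tibble::tibble(
    mean_rr = mean(rr),
    rmssd = sqrt(mean(diff(rr)^2)),
    n_intervals = length(rr),
    valid = TRUE
  )
}
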