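#' Construct a uniformly sampled signal stream
#'
#' A signal stream is a tibble with a `time_s` column and one or more value
#' columns, uniformly sampled on a shared session clock. The sampling rate,
#' channel label and units travel as attributes so that downstream windowing
#' and spectral code never has to re-infer them.
#'
#' @param values Numeric vector of samples (µV for EEG, mV for ECG).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample, seconds on the session clock.
#' @param channel Channel label, e.g. `"Pz"` or `"ECG"`.
#' @param units Unit string, e.g. `"uV"`.
#'
#' @return A tibble with columns `time_s`, `value` and attributes
#'   `sampling_rate`, `channel`, `units`.
#' @export
#' @examples
#' s <- signal_stream(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), 500, channel = "Pz")
#' stream_rate(s)
signal_stream <- function(values, sampling_rate, start_time = 0,
                          channel = "ch", units = "uV") {
  stopifnot(is.numeric(values), length(sampling_rate) == 1, sampling_rate > 0)
  n <- length(values)
  df <- tibble::tibble(
    time_s = start_time + seq_len(n) / sampling_rate - 1 / sampling_rate,
    value = as.numeric(values)
  )
  set_stream_meta(df, sampling_rate, channel, units)
}

#' Construct a 2-D gaze stream with per-sample confidence
#'
#' @param x,y Gaze position in pixels.
#' @param confidence Per-sample confidence in `[0, 1]`.
#' @param sampling_rate Frame rate in Hz (default 120 fps).
#' @inheritParams signal_stream
#' @return A tibble with columns `time_s`, `x_px`, `y_px`, `confidence`.
#' @export
gaze_stream <- function(x, y, confidence, sampling_rate = 120, start_time = 0) {
  stopifnot(length(x) == length(y), length(x) == length(confidence),
            sampling_rate > 0, all(confidence >= 0 & confidence <= 1))
  n <- length(x)
  df <- tibble::tibble(
    time_s = start_time + seq_len(n) / sampling_rate - 1 / sampling_rate,
    x_px = as.numeric(x), y_px = as.numeric(y),
    confidence = as.numeric(confidence)
  )
  set_stream_meta(df, sampling_rate, "gaze", "px")
}

set_stream_meta <- function(df, sampling_rate, channel, units) {
  attr(df, "sampling_rate") <- sampling_rate
  attr(df, "channel") <- channel
  attr(df, "units") <- units
  df
}

#' @rdname signal_stream
#' @param stream A stream tibble.
#' @export
stream_rate <- function(stream) {
  r <- attr(stream, "sampling_rate", exact = TRUE)
  if (is.null(r)) {
    dt <- diff(stream$time_s)
    if (!length(dt)) stop("cannot infer sampling rate from an empty stream")
    r <- 1 / stats::median(dt)
  }
  r
}

#' Extract a half-open time window from a stream
#'
#' Returns the samples whose timestamps satisfy `t_start <= t < t_end`. The
#' half-open convention means the sample at a stimulus onset is *excluded*
#' from a pre-stimulus window, so no stimulus-evoked activity leaks in.
#'
#' @param stream A stream tibble (see [signal_stream()]).
#' @param t_start,t_end Window bounds in seconds, `t_start < t_end`.
#' @return The windowed stream; zero rows (with a warning) when the window
#'   contains no samples. Sampling-rate metadata is preserved.
#' @export
#' @examples
#' s <- signal_stream(rnorm(3000), 500)
#' nrow(extract_window(s, 1, 2)) # 500
extract_window <- function(stream, t_start, t_end) {
  stopifnot(t_start < t_end)
  # tolerance guards against accumulated float error on long sessions
  eps <- 0.25 / stream_rate(stream)
  keep <- stream$time_s >= t_start - eps & stream$time_s < t_end - eps
  out <- stream[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning(sprintf("no samples in window [%g, %g)", t_start, t_end),
            call. = FALSE)
  }
  out <- set_stream_meta(out, stream_rate(stream),
                         attr(stream, "channel", exact = TRUE) %||% "ch",
                         attr(stream, "units", exact = TRUE) %||% "")
  attr(out, "window") <- c(t_start = t_start, t_end = t_end)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

next_pow2 <- function(n) 2L^ceiling(log2(n))
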