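#' Read and write session CSV files
#'
#' Plain-CSV interchange for the four session components. Stream files carry
#' `time_s,value` (plus `x_px,y_px,confidence` for gaze), event logs carry
#' `onset_s,arrow_type,outcome,period,trial_index`, response logs carry
#' `time_s,key`. Headers are required; files are UTF-8.
#'
#' @param path File path.
#' @param sampling_rate Sampling rate in Hz for the stream being read.
#' @param channel,units Metadata attached to the returned stream.
#' @return `read_stream_csv()` and `read_gaze_csv()` return stream tibbles;
#'   `read_events_csv()` and `read_responses_csv()` return plain tibbles.
#' @name session_io
NULL

#' @rdname session_io
#' @export
read_stream_csv <- function(path, sampling_rate, channel = "ch", units = "") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req_cols(df, c("time_s", "value"), path)
  set_stream_meta(tibble::as_tibble(df), sampling_rate, channel, units)
}

#' @rdname session_io
#' @export
read_gaze_csv <- function(path, sampling_rate = 120) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req_cols(df, c("time_s", "x_px", "y_px", "confidence"), path)
  set_stream_meta(tibble::as_tibble(df), sampling_rate, "gaze", "px")
}

#' @rdname session_io
#' @export
read_events_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req_cols(df, c("onset_s", "arrow_type", "outcome", "period"), path)
  if (is.unsorted(df$onset_s, strictly = TRUE)) {
    stop(sprintf("%s: event onsets must be strictly increasing", path),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname session_io
#' @export
read_responses_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req_cols(df, c("time_s", "key"), path)
  tibble::as_tibble(df)
}

#' @rdname session_io
#' @param x Object to write.
#' @export
write_session_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

req_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
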