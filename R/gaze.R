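#' Gaze dispersion over a confidence-filtered pre-stimulus window
#'
#' Discards samples with confidence below 0.8, computes the sample
#' standard deviation (n-1 denominator) of the retained horizontal and
#' vertical positions, and returns their natural logs (lnX, lnY). The
#' trial is flagged invalid when fewer than `min_samples` samples survive
#' the confidence filter or when a dispersion is exactly zero (the log
#' would be undefined); invalid trials carry `NA` rather than being
#' dropped.
#'
#' @param gaze_window A gaze stream tibble (columns `x_px`, `y_px`,
#'   `confidence`), typically the 3-s pre-stimulus extract.
#' @param min_confidence Minimum confidence retained (inclusive).
#' @param min_samples Minimum retained samples for a valid estimate.
#' @return A one-row tibble: `sd_x`, `sd_y` (px), `ln_x`, `ln_y`,
#'   `n_used`, `valid`.
#' @export
#' @examples
#' g <- gaze_stream(c(100, 102), c(50, 50), c(0.9, 0.95))
#' gaze_dispersion(g, min_samples = 2) # sd_x = sqrt(2), ln_x = 0.3466
gaze_dispersion <- function(gaze_window, min_confidence = 0.8,
                            min_samples = 10) {
  keep <- gaze_window$confidence >= min_confidence
  x <- gaze_window$x_px[keep]
  y <- gaze_window$y_px[keep]
  n <- length(x)
  if (n < min_samples) {
    return(tibble::tibble(sd_x = NA_real_, sd_y = NA_real_, ln_x = NA_real_,
                          ln_y = NA_real_, n_used = n, valid = FALSE))
  }
  sd_x <- stats::sd(x)
  sd_y <- stats::sd(y)
  # ln defined per axis only where the dispersion is strictly positive
  ln_x <- if (sd_x > 0) log(sd_x) else NA_real_
  ln_y <- if (sd_y > 0) log(sd_y) else NA_real_
  tibble::tibble(sd_x = sd_x, sd_y = sd_y, ln_x = ln_x, ln_y = ln_y,
                 n_used = n, valid = sd_x > 0 && sd_y > 0)
}
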