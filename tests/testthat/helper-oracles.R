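# explicit-loop RMSSD, kept deliberately naive as an independent oracle
rmssd_loop <- function(intervals) {
  acc <- 0
  for (i in 2:length(intervals)) {
    acc <- acc + (intervals[i] - intervals[i - 1])^2
  }
  sqrt(acc / (length(intervals) - 1))
}

# small event/response builders for behavior tests
make_events <- function(onsets, types, outcomes, period = 1) {
  tibble::tibble(
    participant = 1L, period = period, onset_s = onsets,
    arrow_type = types, outcome = outcomes,
    trial_index = ifelse(types == "unreliable",
                         cumsum(types == "unreliable"), NA_integer_)
  )
}

presses <- function(times, keys) tibble::tibble(time_s = times, key = keys)

# standardized-scale generator configs for model calibration studies
recovery_config <- function(...) {
  generator_config(
    beta = c(intercept = 0, alpha_db = 0.2, rmssd = -0.2, period = 0.1,
             "alpha_db:rmssd" = 0.5),
    sd_participant = 0.6, sd_trial = 0.2, sd_resid = 0.75,
    rt_floor = -Inf, ...)
}

null_coupling_config <- function(...) {
  generator_config(
    beta = c(intercept = 0, period = 0.1),
    sd_participant = 0.6, sd_trial = 0.2, sd_resid = 0.75,
    rt_floor = -Inf, ...)
}
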