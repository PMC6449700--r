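#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the whole analysis from a single declarative YAML config:
#' either simulates a study (section `simulate`, holding
#' [generator_config()] overrides) or reads session CSVs (section `data`,
#' with per-participant stream/event/response paths), extracts the
#' per-trial features, runs the staged [model_search()], and writes
#' `features.csv` and `model_report.json` to `out_dir`. All randomness
#' flows from `seed`, so a fixed config + seed gives identical outputs.
#' A missing stream for one modality leaves that modality's features
#' missing and the run continues; a malformed CSV is fatal with a file
#' diagnostic.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param seed Integer seed for every stochastic step.
#' @return Invisibly, a list with `features` and `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1L) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  set.seed(seed)

  if (!is.null(cfg$simulate)) {
    gen <- do.call(generator_config, normalize_config(cfg$simulate))
    features <- simulate_study_features(gen)
  } else if (!is.null(cfg$data)) {
    features <- purrr::map_dfr(cfg$data$sessions, function(s) {
      events <- read_events_csv(s$events)
      responses <- read_responses_csv(s$responses)
      ecg <- if (!is.null(s$ecg)) {
        read_stream_csv(s$ecg, s$ecg_fs %||% 250, "ECG", "mV")
      }
      eeg <- if (!is.null(s$eeg)) {
        read_stream_csv(s$eeg, s$eeg_fs %||% 500, "Pz", "uV")
      }
      gaze <- if (!is.null(s$gaze)) read_gaze_csv(s$gaze, s$gaze_fps %||% 120)
      build_trial_features(events, responses, ecg, eeg, gaze)
    })
  } else {
    stop("config needs a `simulate` or `data` section", call. = FALSE)
  }

  report <- NULL
  if (!isFALSE(cfg$model$run)) {
    report <- model_search(features, rt_cap = cfg$model$rt_cap %||% 2600)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(features, file.path(out_dir, "features.csv"),
                     progress = FALSE)
    if (!is.null(report)) {
      write_model_report(report, file.path(out_dir, "model_report.json"))
    }
  }
  invisible(list(features = features, report = report))
}

# YAML scalars arrive untyped in places; coerce known vector fields
normalize_config <- function(lst) {
  if (!is.null(lst$outcome_split)) {
    lst$outcome_split <- stats::setNames(
      as.integer(unlist(lst$outcome_split)),
      names(unlist(lst$outcome_split)) %||%
        c("no_change", "incorrect_change", "correct_change"))
  }
  if (!is.null(lst$beta)) {
    lst$beta <- unlist(lst$beta)
  }
  if (!is.null(lst$screen_center)) {
    lst$screen_center <- stats::setNames(as.numeric(unlist(lst$screen_center)),
                                         c("x", "y"))
  }
  lst
}

#' Write a simulated session to CSV files
#'
#' Materializes one participant's simulated session as the plain-CSV
#' interchange files the pipeline reads back (`events.csv`,
#' `responses.csv`, `ecg.csv`, `eeg.csv`, `gaze.csv`, plus
#' `ground_truth.csv`).
#'
#' @param session Output of [simulate_session()].
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(session$events, file.path(dir, "events.csv"),
                   progress = FALSE)
  readr::write_csv(session$responses, file.path(dir, "responses.csv"),
                   progress = FALSE)
  readr::write_csv(session$ecg, file.path(dir, "ecg.csv"), progress = FALSE)
  readr::write_csv(session$eeg, file.path(dir, "eeg.csv"), progress = FALSE)
  readr::write_csv(session$gaze, file.path(dir, "gaze.csv"), progress = FALSE)
  readr::write_csv(session$ground_truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(dir)
}
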