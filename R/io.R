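#' @title Cohort export
#' @description Writes a synthetic cohort to the package's plain-text
#'   interchange layout: `schedule.csv` (trial list plus events),
#'   `pupil_raw.csv`, `rr.csv`, `emg.csv`, `truth.json`, and
#'   `eeg_header.json` (sampling rate, channel names, 2-D coordinates).
#'   EEG sample data are intentionally not materialized here (they are
#'   orders of magnitude larger than every other modality); analyses
#'   regenerate them from `(config, seed)`.
#' @name cohort-io
NULL

#' Write a cohort's raw data as CSV/JSON files
#'
#' @param config a [cohort_config()]
#' @param dir output directory (created if needed)
#' @param participants which participants to export (default: all)
#' @param modalities subset of `c("schedule", "pupil", "rr", "emg")`
#' @return invisibly, the vector of files written
#' @export
write_cohort_csvs <- function(config, dir,
                              participants = seq_len(config$n_participants),
                              modalities = c("schedule", "pupil", "rr", "emg")) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- draw_cohort_truth(config)
  files <- character(0)
  sched_rows <- list(); pupil_rows <- list(); rr_rows <- list(); emg_rows <- list()
  for (p in participants) {
    sched <- generate_schedule(config, p)
    tr <- sched$trials
    ev <- sched$events
    sched_rows[[length(sched_rows) + 1]] <- cbind(participant = p,
      merge(tr, ev, by = "trial_id", all.x = TRUE))
    for (i in seq_len(nrow(tr))) {
      row <- tr[i, ]
      if ("pupil" %in% modalities) {
        raw <- simulate_pupil_trial(
          truth$participants$pupil_baseline_mm[p],
          .truth_value(truth, p, row$condition, "pupil_delta_mm"),
          baseline_s = row$baseline_s, modulation_s = row$modulation_s,
          noise_sd = config$pupil_noise_sd,
          blink_rate_hz = config$blink_rate_hz,
          spike_rate_hz = config$spike_rate_hz,
          seed = derive_seed(config$seed, p, row$trial_id, 31L)
        )
        pupil_rows[[length(pupil_rows) + 1]] <-
          cbind(participant = p, trial_id = row$trial_id,
                raw[, c("t_ms", "left_mm", "right_mm", "gaze_x_deg",
                        "gaze_y_deg", "valid_left", "valid_right")])
      }
      if ("rr" %in% modalities) {
        peaks <- simulate_rr_series(
          .truth_value(truth, p, row$condition, "hr_bpm"),
          .truth_value(truth, p, row$condition, "rmssd_ms"),
          duration_s = row$modulation_s,
          jitter_sd_ms = config$rr_jitter_sd_ms,
          seed = derive_seed(config$seed, p, row$trial_id, 33L)
        )
        rr_rows[[length(rr_rows) + 1]] <- data.frame(
          participant = p, trial_id = row$trial_id, phase = "modulation",
          r_peak_s = peaks)
      }
      if ("emg" %in% modalities && config$experiment == "exp1") {
        pe <- ev[ev$trial_id == row$trial_id, ]
        emg <- simulate_emg_trial(
          pe$onset_s, .truth_value(truth, p, row$condition, "mep_mv"),
          bg_rms_mv = config$bg_emg_rms_mv,
          seed = derive_seed(config$seed, p, row$trial_id, 32L)
        )
        emg_rows[[length(emg_rows) + 1]] <- cbind(
          participant = p, trial_id = row$trial_id,
          emg[, c("pulse_index", "t_ms", "amplitude_mv")])
      }
    }
  }
  wr <- function(rows, name) {
    if (length(rows) == 0) return(invisible(NULL))
    path <- file.path(dir, name)
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    files <<- c(files, path)
  }
  if ("schedule" %in% modalities) wr(sched_rows, "schedule.csv")
  if ("pupil" %in% modalities) wr(pupil_rows, "pupil_raw.csv")
  if ("rr" %in% modalities) wr(rr_rows, "rr.csv")
  if ("emg" %in% modalities) wr(emg_rows, "emg.csv")
  mont <- standard_montage(config$channels)
  hdr <- file.path(dir, "eeg_header.json")
  jsonlite::write_json(
    list(fs_hz = 250, channels = mont$channel,
         xy = mont[, c("x", "y")]),
    hdr, auto_unbox = TRUE, digits = NA)
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(participants = truth$participants, conditions = truth$conditions),
    tj, auto_unbox = TRUE, digits = NA)
  invisible(c(files, hdr, tj))
}
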