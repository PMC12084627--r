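# Synthetic cohort generator: schedules, oddball sequences, signals, truth.

test_that("schedules reproduce each experiment's trial structure", {
  c1 <- cohort_config("exp1", n_participants = 3, seed = 5)
  s1 <- generate_schedule(c1, 1)
  expect_equal(nrow(s1$trials), 60)
  expect_equal(as.integer(table(s1$trials$condition)), rep(20L, 3))
  expect_equal(nrow(s1$events), 120)  # 2 pulses x 20 trials x 3 conditions
  per_cond <- table(s1$trials$condition[match(s1$events$trial_id,
                                              s1$trials$trial_id)])
  expect_equal(as.integer(per_cond), rep(40L, 3))  # 40 MEPs per condition
  p1 <- s1$events$onset_s[seq(1, 120, 2)]
  expect_true(all(p1 >= 3 & p1 <= 4))
  expect_true(all(s1$events$onset_s[seq(2, 120, 2)] == 11))

  c2 <- cohort_config("exp2", n_participants = 2, seed = 5)
  s2 <- generate_schedule(c2, 2)
  expect_equal(as.integer(table(s2$trials$condition)), c(30L, 30L))
  expect_equal(nrow(s2$events), 0)

  c3 <- cohort_config("exp3", n_participants = 2, seed = 5)
  s3 <- generate_schedule(c3, 1)
  expect_equal(nrow(s3$trials), 117)
  expect_equal(max(s3$trials$block), 9)
  expect_equal(as.integer(table(s3$trials$block)), rep(13L, 9))
  expect_equal(nrow(s3$events), 117 * 8)
  expect_equal(sum(s3$events$label == "tone_target"), 186)

  # determinism: same config + participant twice
  expect_identical(generate_schedule(c1, 2), generate_schedule(c1, 2))
  expect_error(generate_schedule(c1, 9), "out of range")
})

test_that("oddball sequences satisfy every stated constraint", {
  od <- generate_oddball_sequence(117, seed = 3)
  expect_equal(sum(od$label == "tone_target"), 186)
  expect_equal(sum(od$label == "tone_standard"), 750)
  per_trial <- tapply(od$label == "tone_target", od$trial, sum)
  expect_true(all(per_trial %in% 1:2))
  expect_equal(sum(per_trial == 2), 69)
  expect_equal(sum(per_trial == 1), 48)
  expect_true(all(od$label[od$tone_index == 1] == "tone_standard"))
  # >= 2 standards between consecutive targets, across the whole session
  flat <- od$label[order(od$trial, od$tone_index)]
  tpos <- which(flat == "tone_target")
  expect_true(all(diff(tpos) >= 3))
  # tone gaps within the stated jitter band
  gaps <- tapply(od$onset_s, od$trial, function(x) diff(x))
  expect_true(all(unlist(gaps) >= 1.8 & unlist(gaps) <= 2.2))
  # single trial: first tone standard
  od1 <- generate_oddball_sequence(1, seed = 4)
  expect_equal(od1$label[1], "tone_standard")
  expect_identical(generate_oddball_sequence(20, seed = 6),
                   generate_oddball_sequence(20, seed = 6))
})

test_that("pupil trials hit their plateau and carry artifact ground truth", {
  tr <- simulate_pupil_trial(3.5, 0.3, noise_sd = 0, blink_rate_hz = 0,
                             spike_rate_hz = 0, seed = 1)
  plateau <- tr$left_mm[tr$t_ms > 6000]
  expect_equal(max(abs(plateau - 3.8)), 0, tolerance = 1e-9)
  expect_true(all(tr$left_mm[tr$t_ms < 4000] == 3.5))

  trb <- simulate_pupil_trial(3.5, 0.3, blink_rate_hz = 1, seed = 2)
  expect_gt(sum(!trb$valid_left), 0)
  expect_true(all(is.na(trb$left_mm[!trb$valid_left])))
  expect_identical(simulate_pupil_trial(3.5, 0.3, seed = 7),
                   simulate_pupil_trial(3.5, 0.3, seed = 7))
  expect_error(simulate_pupil_trial(1.0, 0.3), "\\[1.5, 9\\]")
})

test_that("EEG epochs carry the requested 1/f exponent", {
  e <- simulate_eeg_epochs(200, 2, "Cz", n_samples = 750, fs = 250,
                           noise_scale = 10, seed = 5)
  acc <- 0
  for (k in 1:200) acc <- acc + welch_psd(e$epochs[k, 1, ], 250)$power
  # oracle: plain least squares on the trial-averaged spectrum in log-log
  lf <- log10(1:45); lp <- log10(acc / 200)
  slope <- stats::.lm.fit(cbind(1, lf), lp)$coefficients[2]
  expect_equal(unname(slope), -2, tolerance = 0.1)
  expect_error(simulate_eeg_epochs(2, -1, "Cz", n_samples = 100), "chi")
})

test_that("evoked components and artifact flags behave as configured", {
  chans <- c("Cz", "Pz", "Fz")
  erp0 <- list(n100_uv = -3, late_uv = 0, late_channels = c("Cz", "Pz"))
  a <- simulate_eeg_epochs(60, 1, chans, n_samples = 225, fs = 250,
                           t_start_ms = -100, noise_scale = 10,
                           erp = erp0, seed = 6)
  b <- simulate_eeg_epochs(60, 1, chans, n_samples = 225, fs = 250,
                           t_start_ms = -100, noise_scale = 10,
                           erp = erp0, seed = 7)
  # zero late amplitude: condition averages differ only by noise
  diff_late <- apply(a$epochs, 3, mean) - apply(b$epochs, 3, mean)
  sel <- a$t_ms > 250 & a$t_ms < 450
  expect_lt(abs(mean(diff_late[sel])), 1.5)
  # nonzero late amplitude appears only on the named channels
  erp5 <- list(n100_uv = -3, late_uv = 5, late_channels = c("Cz", "Pz"))
  c5 <- simulate_eeg_epochs(100, 1, chans, n_samples = 225, fs = 250,
                            t_start_ms = -100, noise_scale = 5,
                            erp = erp5, seed = 8)
  m_cz <- apply(c5$epochs[, 1, ], 2, mean)
  m_fz <- apply(c5$epochs[, 3, ], 2, mean)
  i350 <- which.min(abs(c5$t_ms - 350))
  expect_gt(m_cz[i350], 3)
  expect_lt(abs(m_fz[i350]), 2)
  i100 <- which.min(abs(c5$t_ms - 100))
  expect_lt(m_fz[i100], -1)  # early negativity on all channels
  # artifact flags are a seeded Bernoulli draw at the configured rate
  f <- simulate_eeg_epochs(100, 1, "Cz", n_samples = 100, fs = 250,
                           artifact_fraction = 0.1, seed = 9)
  expect_true(sum(f$artifact) >= 3 && sum(f$artifact) <= 20)
  f2 <- simulate_eeg_epochs(100, 1, "Cz", n_samples = 100, fs = 250,
                            artifact_fraction = 0.1, seed = 9)
  expect_identical(f$artifact, f2$artifact)
})

test_that("EMG trials inject recoverable MEPs over band-limited background", {
  emg <- simulate_emg_trial(c(3.5, 11), mep_mv = 1.0, bg_rms_mv = 0, seed = 1)
  expect_equal(length(unique(emg$pulse_index)), 2)
  seg <- emg[emg$pulse_index == 1, ]
  # oracle: max - min of the raw injected waveform
  raw_p2p <- max(seg$amplitude_mv) - min(seg$amplitude_mv)
  expect_equal(raw_p2p, 1.0, tolerance = 1e-9)
  r <- extract_mep(seg$t_ms, seg$amplitude_mv)
  expect_equal(r$peak_to_peak_mv, 1.0, tolerance = 0.05)
  # zero-amplitude MEP: extraction sits at the noise floor
  emg0 <- simulate_emg_trial(3.5, mep_mv = 0, bg_rms_mv = 0.005, seed = 2)
  r0 <- extract_mep(emg0$t_ms, emg0$amplitude_mv)
  expect_lt(r0$peak_to_peak_mv, 0.05)
  expect_equal(r0$bg_rms_mv, 0.005, tolerance = 0.1)
  # a 20-trial condition yields 40 EMG segments
  cfg <- cohort_config("exp1", n_participants = 1, seed = 3)
  s <- generate_schedule(cfg, 1)
  up_trials <- s$trials$trial_id[s$trials$condition == "up"]
  n_seg <- sum(s$events$trial_id %in% up_trials)
  expect_equal(n_seg, 40)
})

test_that("cohort truth couples pupil and exponent via the latent factor", {
  cfg <- cohort_config("exp2", n_participants = 300, seed = 10)
  tr <- draw_cohort_truth(cfg)
  cnd <- tr$conditions
  up <- cnd[cnd$condition == "up", ]; dn <- cnd[cnd$condition == "down", ]
  pupil_idx <- up$pupil_delta_mm - dn$pupil_delta_mm
  steep_idx <- dn$exponent - up$exponent
  expect_lt(abs(mean(pupil_idx) - 0.5), 0.06)
  expect_lt(abs(mean(steep_idx) - 0.3), 0.05)
  r_on <- cor(pupil_idx, steep_idx)
  expect_gt(r_on, 0.3); expect_lt(r_on, 0.65)
  cfg0 <- cohort_config("exp2", n_participants = 300,
                        latent_arousal_sd = 0, seed = 10)
  tr0 <- draw_cohort_truth(cfg0)
  c0 <- tr0$conditions
  r_off <- cor(c0$pupil_delta_mm[c0$condition == "up"] -
                 c0$pupil_delta_mm[c0$condition == "down"],
               c0$exponent[c0$condition == "down"] -
                 c0$exponent[c0$condition == "up"])
  expect_lt(abs(r_off), 0.15)
  expect_identical(draw_cohort_truth(cfg), tr)
})

test_that("cohorts export to the plain-text interchange layout", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config("exp1", n_participants = 1, seed = 2,
                       channels = c("Cz", "Pz", "Fz"))
  write_cohort_csvs(cfg, dir, modalities = c("schedule", "rr", "emg"))
  sched <- read.csv(file.path(dir, "schedule.csv"))
  expect_equal(length(unique(sched$trial_id)), 60)
  rr <- read.csv(file.path(dir, "rr.csv"))
  expect_true(all(c("participant", "trial_id", "r_peak_s") %in% names(rr)))
  emg <- read.csv(file.path(dir, "emg.csv"))
  expect_equal(length(unique(paste(emg$trial_id, emg$pulse_index))), 120)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$conditions), 3)
  hdr <- jsonlite::read_json(file.path(dir, "eeg_header.json"))
  expect_equal(hdr$fs_hz, 250)
  expect_equal(unlist(hdr$channels), c("Cz", "Pz", "Fz"))
})
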