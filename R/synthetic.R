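#' @title Synthetic cohort generator
#' @description Seeded generators that emulate the trial structure of the
#'   three biofeedback experiments (TMS, EEG-only, auditory oddball) and the
#'   condition effects of every recorded modality: two-eye pupil traces,
#'   1/f-shaped EEG epochs with optional evoked components, R-peak series
#'   with a controlled RMSSD, and EMG traces with injected motor evoked
#'   potentials. Per-participant ground truth is drawn once (with a latent
#'   arousal factor coupling the pupil and spectral-exponent effects) and
#'   stored, so downstream modules can be checked by parameter recovery.
#' @name synthetic
NULL

# --- seeded RNG plumbing ------------------------------------------------

#' Derive a reproducible sub-seed
#'
#' Mixes a base seed with stream indices into a 31-bit seed so that every
#' generated object is a deterministic function of (config, seed) without
#' the generators sharing one global stream.
#' @param seed base integer seed
#' @param ... integer stream indices (participant, trial, modality, ...)
#' @return integer in \[0, 2^31 - 2\]
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# --- cohort configuration ----------------------------------------------

experiment_conditions <- function(experiment) {
  switch(experiment,
    exp1 = c("up", "down", "rest"),
    exp2 = c("up", "down"),
    exp3 = c("up", "down", "control"),
    stop("unknown experiment tag: ", experiment)
  )
}

#' Cohort configuration
#'
#' Defines the study conditions a synthetic cohort is generated under:
#' experiment layout, population-level condition effects, between-participant
#' spread, the latent arousal coupling, and noise levels. Population effects
#' default to a strong-modulation regime (pupil index 0.5 mm, exponent index
#' 0.3, heart rate 3 bpm, RMSSD 5 ms, MEP 30% of rest, target P300 2 uV),
#' with between-participant index SDs chosen so headline paired effects have
#' a standardized size around 1.5.
#'
#' @param experiment `"exp1"`, `"exp2"`, or `"exp3"`
#' @param n_participants cohort size (defaults to the per-experiment sample
#'   sizes 15 / 23 / 19)
#' @param pupil_delta_mm named per-condition pupil change (mm)
#' @param exponent named per-condition aperiodic exponent
#' @param hr_bpm named per-condition mean heart rate
#' @param rmssd_ms named per-condition RMSSD
#' @param mep_mv named per-condition MEP amplitude (exp1 only used)
#' @param p300_uv named per-condition target P300 amplitude (exp3)
#' @param n100_uv condition-invariant N100 amplitude (negative)
#' @param p300_standard_uv condition-invariant late positivity to standards
#' @param latent_arousal_sd loading (0-1) of the shared latent arousal factor
#'   on the pupil and exponent modulation indices; the induced cross-measure
#'   correlation equals its square (default ~0.5)
#' @param index_sd named between-participant SDs of the modulation indices
#'   (`pupil`, `exponent`, `hr`, `rmssd`, `mep`, `p300`)
#' @param base_sd named between-participant SDs of the baseline levels
#' @param pupil_baseline_mm mean resting pupil diameter (must be in
#'   \[1.5, 9\] mm)
#' @param pupil_noise_sd per-sample pupil noise SD (mm)
#' @param eeg_noise_scale EEG sample SD (uV)
#' @param rr_jitter_sd_ms extra Gaussian R-R jitter (ms) on top of the
#'   alternating construction
#' @param bg_emg_rms_mv background EMG RMS (mV)
#' @param blink_rate_hz,spike_rate_hz pupil artifact rates
#' @param artifact_fraction fraction of EEG epochs flagged artifactual
#' @param behavior_error_rate rate of invalid behavioral responses (misses /
#'   false alarms) in the oddball task
#' @param osc_amplitude_uv amplitude of an optional 10 Hz oscillation
#' @param channels montage channel names used for simulated EEG
#' @param seed integer master seed
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(experiment = c("exp1", "exp2", "exp3"),
                          n_participants = NULL,
                          pupil_delta_mm = NULL,
                          exponent = NULL,
                          hr_bpm = NULL,
                          rmssd_ms = NULL,
                          mep_mv = NULL,
                          p300_uv = NULL,
                          n100_uv = -3,
                          p300_standard_uv = 1,
                          latent_arousal_sd = sqrt(0.5),
                          index_sd = c(pupil = 0.33, exponent = 0.2, hr = 2,
                                       rmssd = 3.3, mep = 0.2, p300 = 0.95),
                          base_sd = c(pupil = 0.4, exponent = 0.15, hr = 5,
                                      rmssd = 8, mep = 0.25, p300 = 1),
                          pupil_baseline_mm = 3.5,
                          pupil_noise_sd = 0.03,
                          eeg_noise_scale = 10,
                          rr_jitter_sd_ms = 3,
                          bg_emg_rms_mv = 0.005,
                          blink_rate_hz = 0.1,
                          spike_rate_hz = 0.05,
                          artifact_fraction = 0.1,
                          behavior_error_rate = 0.03,
                          osc_amplitude_uv = 0,
                          channels = NULL,
                          seed = 1L) {
  experiment <- match.arg(experiment)
  conds <- experiment_conditions(experiment)
  ctl <- setdiff(conds, c("up", "down"))
  fill <- function(x, up, down, other) {
    if (is.null(x)) {
      x <- stats::setNames(c(up, down, rep(other, length(ctl))), c("up", "down", ctl))
    }
    if (!all(conds %in% names(x))) {
      stop("per-condition values must be named for all of: ",
           paste(conds, collapse = ", "))
    }
    x[conds]
  }
  if (is.null(n_participants)) {
    n_participants <- c(exp1 = 15L, exp2 = 23L, exp3 = 19L)[[experiment]]
  }
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (pupil_baseline_mm < 1.5 || pupil_baseline_mm > 9) {
    stop("pupil_baseline_mm must lie in [1.5, 9] mm")
  }
  if (latent_arousal_sd < 0 || latent_arousal_sd > 1) {
    stop("latent_arousal_sd must lie in [0, 1]")
  }
  sds <- c(index_sd, base_sd, pupil_noise_sd, eeg_noise_scale,
           rr_jitter_sd_ms, bg_emg_rms_mv, blink_rate_hz, spike_rate_hz)
  if (any(sds < 0)) stop("noise and spread parameters must be >= 0")
  cfg <- list(
    experiment = experiment,
    conditions = conds,
    n_participants = as.integer(n_participants),
    pupil_delta_mm = fill(pupil_delta_mm, 0.25, -0.25, 0),
    exponent = fill(exponent, 1.85, 2.15, 2.0),
    hr_bpm = fill(hr_bpm, 66.5, 63.5, 65),
    rmssd_ms = fill(rmssd_ms, 42.5, 47.5, 45),
    mep_mv = fill(mep_mv, 1.15, 0.85, 1.0),
    p300_uv = fill(p300_uv, 4, 6, 4),
    n100_uv = n100_uv,
    p300_standard_uv = p300_standard_uv,
    latent_arousal_sd = latent_arousal_sd,
    index_sd = index_sd, base_sd = base_sd,
    pupil_baseline_mm = pupil_baseline_mm,
    pupil_noise_sd = pupil_noise_sd,
    eeg_noise_scale = eeg_noise_scale,
    rr_jitter_sd_ms = rr_jitter_sd_ms,
    bg_emg_rms_mv = bg_emg_rms_mv,
    blink_rate_hz = blink_rate_hz,
    spike_rate_hz = spike_rate_hz,
    artifact_fraction = artifact_fraction,
    behavior_error_rate = behavior_error_rate,
    osc_amplitude_uv = osc_amplitude_uv,
    channels = if (is.null(channels)) standard_montage()$channel else channels,
    seed = as.integer(seed)
  )
  if (any(cfg$exponent < 0)) stop("aperiodic exponents must be >= 0")
  if (any(cfg$hr_bpm <= 0)) stop("heart rates must be positive")
  class(cfg) <- "cohort_config"
  cfg
}

#' Draw the per-participant ground truth of a cohort
#'
#' Draws the latent arousal factor and all per-participant, per-condition
#' true values (pupil delta, exponent, HR, RMSSD, MEP, P300). The pupil and
#' exponent modulation indices share the latent factor: participants with a
#' stronger pupil index also steepen their spectrum more under
#' downregulation, giving a positive correlation (about
#' `latent_arousal_sd^2`) between the pupil index and the steepening index
#' (exponent down - up).
#'
#' @param config a [cohort_config()]
#' @return list of class `cohort_truth` with `participants` (latent factor,
#'   baseline pupil, N100) and `conditions` (long data.frame of true values)
#' @export
draw_cohort_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  conds <- config$conditions
  ctl <- setdiff(conds, c("up", "down"))
  lam <- config$latent_arousal_sd
  mix <- function(a, e) lam * a + sqrt(max(0, 1 - lam^2)) * e
  with_seed(derive_seed(config$seed, 0, 1), {
    a <- stats::rnorm(n)
    dev_pupil <- config$index_sd[["pupil"]] * mix(a, stats::rnorm(n))
    dev_steep <- config$index_sd[["exponent"]] * mix(a, stats::rnorm(n))
    dev_hr <- config$index_sd[["hr"]] * stats::rnorm(n)
    dev_rmssd <- config$index_sd[["rmssd"]] * stats::rnorm(n)
    dev_mep <- config$index_sd[["mep"]] * stats::rnorm(n)
    base_pupil <- pmin(7.5, pmax(1.8, config$pupil_baseline_mm +
                                   config$base_sd[["pupil"]] * stats::rnorm(n)))
    base_chi <- pmax(0.3, mean(config$exponent[c("up", "down")]) +
                      config$base_sd[["exponent"]] * stats::rnorm(n))
    base_hr <- pmax(40, mean(config$hr_bpm[c("up", "down")]) +
                     config$base_sd[["hr"]] * stats::rnorm(n))
    base_rmssd <- pmax(10, mean(config$rmssd_ms[c("up", "down")]) +
                        config$base_sd[["rmssd"]] * stats::rnorm(n))
    rest_name <- if ("rest" %in% conds) "rest" else "up"
    base_mep <- pmax(0.2, config$mep_mv[[rest_name]] +
                      config$base_sd[["mep"]] * stats::rnorm(n))
    base_p300 <- config$base_sd[["p300"]] * stats::rnorm(n)
    p300_dev <- matrix(config$index_sd[["p300"]] * stats::rnorm(n * length(conds)),
                       n, length(conds), dimnames = list(NULL, conds))

    chi_ref <- mean(config$exponent[c("up", "down")])
    hr_ref <- mean(config$hr_bpm[c("up", "down")])
    rmssd_ref <- mean(config$rmssd_ms[c("up", "down")])
    rest_mep <- config$mep_mv[[rest_name]]

    rows <- lapply(conds, function(cond) {
      sgn_ud <- switch(cond, up = 0.5, down = -0.5, 0)
      pupil <- config$pupil_delta_mm[[cond]] + sgn_ud * dev_pupil
      chi <- base_chi + (config$exponent[[cond]] - chi_ref) - sgn_ud * dev_steep
      hr <- base_hr + (config$hr_bpm[[cond]] - hr_ref) + sgn_ud * dev_hr
      rm <- base_rmssd + (config$rmssd_ms[[cond]] - rmssd_ref) - sgn_ud * dev_rmssd
      mep <- base_mep * pmax(0.05, config$mep_mv[[cond]] / rest_mep +
                               sgn_ud * dev_mep)
      p300 <- config$p300_uv[[cond]] + base_p300 + p300_dev[, cond]
      data.frame(participant = seq_len(n), condition = cond,
                 pupil_delta_mm = pupil, exponent = pmax(0.05, chi),
                 hr_bpm = hr, rmssd_ms = pmax(1, rm), mep_mv = mep,
                 p300_uv = p300, stringsAsFactors = FALSE)
    })
    structure(
      list(
        participants = data.frame(
          participant = seq_len(n), latent = a,
          pupil_baseline_mm = base_pupil,
          n100_uv = config$n100_uv,
          p300_standard_uv = config$p300_standard_uv
        ),
        conditions = do.call(rbind, rows)
      ),
      class = "cohort_truth"
    )
  })
}

# --- schedules ----------------------------------------------------------

phase_durations <- function(experiment) {
  switch(experiment,
    exp1 = c(instruction = 1, baseline = 4, modulation = 15, feedback = 2, brk = 2),
    exp2 = c(instruction = 2, baseline = 3, modulation = 15, feedback = 2, brk = 2),
    exp3 = c(instruction = 2, baseline = 4, modulation = 18, feedback = 2, brk = 2)
  )
}

latin_square <- function(items, shift = 0) {
  k <- length(items)
  items[((seq_len(k) - 1 + shift) %% k) + 1]
}

#' Generate the per-participant session schedule
#'
#' Builds the full trial list for one participant: condition-blocked trials
#' in a seeded, Latin-square counterbalanced block order, phase timings, and
#' within-trial events (TMS pulses for exp1, oddball tones for exp3).
#'
#' @param config a [cohort_config()]
#' @param participant participant index (1-based)
#' @return list of class `session_schedule` with `trials` (data.frame:
#'   `trial_id`, `condition`, `block`, phase durations) and `events`
#'   (data.frame: `trial_id`, `label`, `onset_s` relative to modulation
#'   start)
#' @export
generate_schedule <- function(config, participant) {
  stopifnot(inherits(config, "cohort_config"))
  if (participant < 1 || participant > config$n_participants) {
    stop("participant index out of range")
  }
  conds <- config$conditions
  ph <- phase_durations(config$experiment)
  seed <- derive_seed(config$seed, participant, 2)
  with_seed(seed, {
    base_order <- sample(conds)
    row <- latin_square(base_order, shift = participant - 1)
    blocks <- switch(config$experiment,
      exp1 = c(row, rev(row)),
      exp2 = rep(row, 3),
      exp3 = c(row, latin_square(row, 1), latin_square(row, 2))
    )
    trials_per_block <- switch(config$experiment, exp1 = 10L, exp2 = 10L, exp3 = 13L)
    n_trials <- length(blocks) * trials_per_block
    trials <- data.frame(
      trial_id = seq_len(n_trials),
      condition = rep(blocks, each = trials_per_block),
      block = rep(seq_along(blocks), each = trials_per_block),
      instruction_s = ph[["instruction"]], baseline_s = ph[["baseline"]],
      modulation_s = ph[["modulation"]], feedback_s = ph[["feedback"]],
      break_s = ph[["brk"]], stringsAsFactors = FALSE
    )
    events <- NULL
    if (config$experiment == "exp1") {
      p1 <- stats::runif(n_trials, 3, 4)
      events <- data.frame(
        trial_id = rep(trials$trial_id, each = 2),
        label = "tms_pulse",
        onset_s = as.vector(rbind(p1, 11)),
        stringsAsFactors = FALSE
      )
    } else if (config$experiment == "exp3") {
      # tone sequences are generated once per within-condition trial position
      # and reused across conditions (number and order of tones congruent)
      n_per_cond <- sum(blocks == conds[1]) * trials_per_block
      tones <- generate_oddball_sequence(n_per_cond)
      pos_in_cond <- stats::ave(seq_len(n_trials), trials$condition,
                                FUN = seq_along)
      ev <- lapply(seq_len(n_trials), function(i) {
        tt <- tones[tones$trial == pos_in_cond[i], ]
        data.frame(trial_id = i, label = tt$label, onset_s = tt$onset_s,
                   stringsAsFactors = FALSE)
      })
      events <- do.call(rbind, ev)
    }
    structure(
      list(trials = trials,
           events = if (is.null(events)) {
             data.frame(trial_id = integer(0), label = character(0),
                        onset_s = numeric(0))
           } else events),
      class = "session_schedule",
      experiment = config$experiment, participant = participant,
      phase_durations = ph
    )
  })
}

#' Generate oddball tone sequences
#'
#' Each trial carries 8 tones: the first is always a standard, tones are
#' separated by intervals drawn uniformly from \[1.8, 2.2\] s, each trial has
#' one or two targets, and at least two standards intervene between
#' consecutive targets (also across trial boundaries), which enforces a
#' minimum 5.4 s onset separation between targets. For 117 trials the
#' two-target/one-target split is 69/48, yielding 186 targets and 750
#' standards; other trial counts use the proportional split.
#'
#' @param n_trials number of trials (>= 1)
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used
#' @return data.frame with `trial`, `tone_index` (1-8), `label`
#'   (`"tone_standard"`/`"tone_target"`), `onset_s` relative to modulation
#'   start
#' @export
generate_oddball_sequence <- function(n_trials, seed = NULL) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  gen <- function() {
    n2 <- round(n_trials * 69 / 117)
    two_target <- rep(FALSE, n_trials)
    two_target[sample.int(n_trials, n2)] <- TRUE
    out <- vector("list", n_trials)
    tail_standards <- Inf  # standards after the last target of previous trial
    for (i in seq_len(n_trials)) {
      lb <- max(2, 3 - tail_standards)  # >=2 standards since previous target
      if (two_target[i]) {
        # positions (p1, p2) with p2 - p1 >= 3 (two standards in between)
        cand <- expand.grid(p1 = lb:5, p2 = 5:8)
        cand <- cand[cand$p2 - cand$p1 >= 3, ]
        pick <- cand[sample.int(nrow(cand), 1), ]
        pos <- c(pick$p1, pick$p2)
      } else {
        pos <- sample(lb:8, 1)
      }
      label <- rep("tone_standard", 8)
      label[pos] <- "tone_target"
      gaps <- stats::runif(8, 1.8, 2.2)
      onset <- cumsum(gaps)
      out[[i]] <- data.frame(trial = i, tone_index = 1:8, label = label,
                             onset_s = onset, stringsAsFactors = FALSE)
      tail_standards <- 8 - max(pos)
    }
    do.call(rbind, out)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# --- pupil --------------------------------------------------------------

#' Simulate a raw two-eye pupil trace for one trial
#'
#' 60 Hz two-eye trace spanning the baseline and modulation phases. The
#' baseline segment fluctuates around the participant baseline diameter; the
#' modulation segment ramps smoothly (half-cosine over `ramp_s`) toward
#' baseline + delta. Binocular blink gaps (invalid runs) and single-sample
#' spike artifacts are injected at the configured rates; the ground-truth
#' artifact indices are attached for oracle tests.
#'
#' @param baseline_mm participant baseline diameter (must be in \[1.5, 9\])
#' @param delta_mm condition pupil change (mm)
#' @param baseline_s,modulation_s phase durations (s)
#' @param noise_sd per-sample noise SD (mm); slow drift scales with it
#' @param blink_rate_hz,spike_rate_hz artifact rates
#' @param ramp_s ramp duration to the modulation plateau
#' @param fs sampling rate (Hz)
#' @param seed optional seed
#' @return data.frame (`t_ms`, `left_mm`, `right_mm`, `gaze_x_deg`,
#'   `gaze_y_deg`, `valid_left`, `valid_right`) with attributes
#'   `modulation_start_ms`, `spike_idx` (truth), `blink_idx` (truth)
#' @export
simulate_pupil_trial <- function(baseline_mm, delta_mm,
                                 baseline_s = 4, modulation_s = 15,
                                 noise_sd = 0.03,
                                 blink_rate_hz = 0.1, spike_rate_hz = 0.05,
                                 ramp_s = 1, fs = 60, seed = NULL) {
  if (baseline_mm < 1.5 || baseline_mm > 9) {
    stop("baseline diameter must lie in [1.5, 9] mm")
  }
  gen <- function() {
    n <- round((baseline_s + modulation_s) * fs)
    t_s <- (seq_len(n) - 1) / fs
    t_ms <- t_s * 1000
    mod_start <- baseline_s
    tm <- pmax(0, t_s - mod_start)
    ramp <- ifelse(tm >= ramp_s, 1, 0.5 * (1 - cos(pi * tm / ramp_s)))
    target <- baseline_mm + delta_mm * ramp
    drift <- if (noise_sd > 0) {
      as.numeric(stats::filter(stats::rnorm(n, 0, noise_sd * 0.15),
                               0.99, method = "recursive"))
    } else rep(0, n)
    common <- target + drift
    left <- common + stats::rnorm(n, 0, noise_sd)
    right <- common + stats::rnorm(n, 0, noise_sd)
    valid <- rep(TRUE, n)
    blink_idx <- integer(0)
    n_blinks <- stats::rpois(1, blink_rate_hz * (baseline_s + modulation_s))
    if (n_blinks > 0) {
      starts <- sample.int(n, n_blinks)
      for (s in starts) {
        len <- round(stats::runif(1, 0.15, 0.35) * fs)
        blink_idx <- union(blink_idx, s:min(n, s + len - 1))
      }
      valid[blink_idx] <- FALSE
      left[blink_idx] <- NA; right[blink_idx] <- NA
    }
    spike_idx <- integer(0)
    n_spikes <- stats::rpois(1, spike_rate_hz * (baseline_s + modulation_s))
    if (n_spikes > 0) {
      spike_idx <- setdiff(sample.int(n, n_spikes), blink_idx)
      amp <- stats::runif(length(spike_idx), 1, 3) *
        sample(c(-1, 1), length(spike_idx), replace = TRUE)
      left[spike_idx] <- left[spike_idx] + amp
      right[spike_idx] <- right[spike_idx] + amp
    }
    out <- data.frame(
      t_ms = t_ms, left_mm = left, right_mm = right,
      gaze_x_deg = stats::rnorm(n, 0, 0.5), gaze_y_deg = stats::rnorm(n, 0, 0.5),
      valid_left = valid, valid_right = valid
    )
    attr(out, "modulation_start_ms") <- mod_start * 1000
    attr(out, "spike_idx") <- sort(spike_idx)
    attr(out, "blink_idx") <- sort(blink_idx)
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# --- EEG ----------------------------------------------------------------

#' Simulate 1/f-shaped EEG epochs with optional evoked components
#'
#' Each channel of each epoch is spectrally shaped Gaussian noise with power
#' proportional to f^(-chi) (frequency-domain amplitude shaping, DC bin
#' zeroed), scaled to `noise_scale` uV sample SD, plus an optional 10 Hz
#' sinusoid. Evoked components (negative deflection peaking ~100 ms after
#' event onset on all channels; positive deflection peaking ~350 ms on a
#' channel subset) can be injected per epoch. A configurable fraction of
#' epochs is flagged artifactual.
#'
#' @param n_epochs number of epochs
#' @param chi aperiodic exponent (>= 0)
#' @param channels channel names
#' @param n_samples samples per epoch
#' @param fs sampling rate (Hz)
#' @param t_start_ms epoch start relative to the event (ERP injection uses
#'   event time 0)
#' @param noise_scale sample SD in uV
#' @param erp `NULL`, or a list with `n100_uv`, `late_uv` (scalar or
#'   per-epoch vector), `late_channels` (names of the channel subset for the
#'   late positivity)
#' @param osc_amplitude_uv amplitude of an added 10 Hz oscillation
#' @param artifact_fraction Bernoulli rate of artifact flags
#' @param seed optional seed
#' @return list with `epochs` (array epoch x channel x time, uV), `t_ms`,
#'   `channels`, `artifact` (logical per epoch)
#' @export
simulate_eeg_epochs <- function(n_epochs, chi, channels, n_samples, fs = 250,
                                t_start_ms = 0, noise_scale = 10,
                                erp = NULL, osc_amplitude_uv = 0,
                                artifact_fraction = 0, seed = NULL) {
  if (chi < 0) stop("aperiodic exponent chi must be >= 0")
  gen <- function() {
    nch <- length(channels)
    L <- n_samples
    f <- c(0, seq_len(L - 1)) * fs / L
    f_fold <- pmin(f, fs - f)          # conjugate-symmetric frequency axis
    amp <- c(0, f_fold[-1]^(-chi / 2)) # DC zeroed
    sd_theory <- sqrt(sum(amp^2)) / L  # per-sample SD of Re(ifft)
    scale <- if (sd_theory > 0) noise_scale / sd_theory else 0
    t_ms <- t_start_ms + (seq_len(L) - 1) * 1000 / fs
    ncol_tot <- n_epochs * nch
    z <- matrix(stats::rnorm(L * ncol_tot), L, ncol_tot) +
      1i * matrix(stats::rnorm(L * ncol_tot), L, ncol_tot)
    z <- z * (amp * scale)
    x <- Re(stats::mvfft(z, inverse = TRUE)) / L
    ep <- aperm(array(x, dim = c(L, nch, n_epochs)), c(3, 2, 1))
    if (osc_amplitude_uv > 0) {
      phase <- stats::runif(n_epochs * nch, 0, 2 * pi)
      osc_t <- 2 * pi * 10 * (t_ms / 1000)
      for (e in seq_len(n_epochs)) {
        for (ch in seq_len(nch)) {
          ep[e, ch, ] <- ep[e, ch, ] +
            osc_amplitude_uv * sin(osc_t + phase[(e - 1) * nch + ch])
        }
      }
    }
    if (!is.null(erp)) {
      early <- erp$n100_uv * exp(-((t_ms - 100)^2) / (2 * 40^2))
      late_shape <- exp(-((t_ms - 350)^2) / (2 * 80^2))
      late_amp <- rep(erp$late_uv, length.out = n_epochs)
      late_ch <- which(channels %in% erp$late_channels)
      early_mat <- matrix(early, nch, L, byrow = TRUE)
      for (e in seq_len(n_epochs)) {
        ep[e, , ] <- ep[e, , ] + early_mat
        if (length(late_ch) > 0 && late_amp[e] != 0) {
          ep[e, late_ch, ] <- ep[e, late_ch, ] +
            matrix(late_amp[e] * late_shape, length(late_ch), L, byrow = TRUE)
        }
      }
    }
    art <- stats::runif(n_epochs) < artifact_fraction
    list(epochs = ep, t_ms = t_ms, channels = channels, artifact = art)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# --- cardiac ------------------------------------------------------------

#' Simulate an R-peak series with controlled heart rate and RMSSD
#'
#' Alternating-jitter construction: intervals are base +/- d in alternation
#' (base = 60/HR), plus optional independent Gaussian jitter. d is solved so
#' the expected sample RMSSD equals the requested value:
#' RMSSD^2 = 4 d^2 + 2 sigma^2.
#'
#' @param hr_bpm mean heart rate (> 0)
#' @param rmssd_ms target RMSSD (>= 0)
#' @param duration_s length of the covered window
#' @param t_start_s time of the first R peak
#' @param jitter_sd_ms extra Gaussian interval jitter
#' @param seed optional seed
#' @return numeric vector of R-peak times (s)
#' @export
simulate_rr_series <- function(hr_bpm, rmssd_ms, duration_s,
                               t_start_s = 0, jitter_sd_ms = 0, seed = NULL) {
  if (hr_bpm <= 0) stop("heart rate must be positive")
  if (rmssd_ms < 0) stop("RMSSD must be >= 0")
  base <- 60 / hr_bpm
  sig <- jitter_sd_ms / 1000
  d2 <- (rmssd_ms / 1000)^2 - 2 * sig^2
  if (d2 < 0) {
    stop("requested RMSSD is below the floor implied by the interval jitter")
  }
  d <- sqrt(d2) / 2
  if (base - d - 5 * sig <= 0) {
    stop("requested RMSSD is not achievable at the requested heart rate")
  }
  gen <- function() {
    n_int <- ceiling(duration_s / max(base - d, 1e-6)) + 2
    alt <- rep_len(c(1, -1), n_int)
    rr <- base + alt * d +
      if (sig > 0) stats::rnorm(n_int, 0, sig) else 0
    peaks <- t_start_s + c(0, cumsum(rr))
    peaks[peaks <= t_start_s + duration_s]
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# --- EMG ----------------------------------------------------------------

.mep_shape <- function(t_s) {
  # Gabor-like biphasic deflection: 150 Hz carrier under a Gaussian envelope
  # centered 30 ms post-pulse (sigma 4 ms); energy confined to ~15-60 ms and
  # to the passband of the 30-800 Hz filter. Normalized to unit peak-to-peak.
  env <- exp(-((t_s - 0.030)^2) / (2 * 0.004^2))
  s <- env * sin(2 * pi * 150 * (t_s - 0.030))
  rng <- range(s)
  if (diff(rng) > 0) s / diff(rng) else s
}

#' Simulate EMG segments around TMS pulses
#'
#' For each pulse, a 5 kHz segment spanning `pre_s` before to `post_s` after
#' the pulse is generated: band-limited (30-800 Hz) background noise scaled
#' to the requested RMS, plus a biphasic deflection starting ~20 ms
#' post-pulse whose noise-free peak-to-peak amplitude equals the requested
#' MEP.
#'
#' @param pulse_times_s pulse times within the trial (s)
#' @param mep_mv true MEP peak-to-peak amplitude (mV), recycled per pulse
#' @param bg_rms_mv background EMG RMS (mV)
#' @param fs sampling rate (Hz)
#' @param pre_s,post_s segment extent around each pulse (s)
#' @param seed optional seed
#' @return data.frame with `pulse_index`, `pulse_time_s`, `t_ms` (relative
#'   to the pulse), `amplitude_mv`
#' @export
simulate_emg_trial <- function(pulse_times_s, mep_mv, bg_rms_mv = 0.005,
                               fs = 5000, pre_s = 0.2, post_s = 0.15,
                               seed = NULL) {
  if (length(pulse_times_s) == 0) stop("trial has no TMS pulse events")
  mep_mv <- rep(mep_mv, length.out = length(pulse_times_s))
  gen <- function() {
    n <- round((pre_s + post_s) * fs)
    t_s <- seq_len(n) / fs - pre_s
    bp <- .butter_cached(4, c(30, 800) / (fs / 2), "pass")
    segs <- lapply(seq_along(pulse_times_s), function(k) {
      bg <- if (bg_rms_mv > 0) {
        raw <- stats::rnorm(n)
        filt <- .filtfilt_fast(bp$b, bp$a, raw)
        filt * bg_rms_mv / sqrt(mean(filt^2))
      } else rep(0, n)
      sig <- bg + mep_mv[k] * .mep_shape(t_s)
      data.frame(pulse_index = k, pulse_time_s = pulse_times_s[k],
                 t_ms = t_s * 1000, amplitude_mv = sig)
    })
    do.call(rbind, segs)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
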