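#' @title Experiment-level analysis pipelines
#' @description End-to-end analyses of the three experiment layouts on
#'   synthetic cohorts: each `run_exp*` function generates (or accepts) a
#'   cohort, pushes every modality through the corresponding preprocessing
#'   and feature-extraction modules, and applies the study's statistical
#'   layer, returning tidy per-participant tables and the group-level test
#'   results.
#' @name pipeline
NULL

.truth_value <- function(truth, p, cond, col) {
  truth$conditions[truth$conditions$participant == p &
                     truth$conditions$condition == cond, col]
}

.pupil_trace_for_trial <- function(config, truth, participant, trial_row, seed_tag) {
  cond <- trial_row$condition
  raw <- simulate_pupil_trial(
    baseline_mm = truth$participants$pupil_baseline_mm[participant],
    delta_mm = .truth_value(truth, participant, cond, "pupil_delta_mm"),
    baseline_s = trial_row$baseline_s, modulation_s = trial_row$modulation_s,
    noise_sd = config$pupil_noise_sd,
    blink_rate_hz = config$blink_rate_hz,
    spike_rate_hz = config$spike_rate_hz,
    seed = derive_seed(config$seed, participant, trial_row$trial_id, seed_tag)
  )
  tr <- preprocess_pupil(raw)
  if (tr$rejected) return(NULL)
  tr <- baseline_correct(tr)
  if (tr$rejected) return(NULL)
  tr
}

.holm_family <- function(tests) {
  p_adj <- holm_sequential_bonferroni(vapply(tests, `[[`, 1, "p"))
  for (i in seq_along(tests)) tests[[i]]$p_holm <- p_adj[i]
  tests
}

#' Run the TMS cortical-excitability analysis (experiment 1)
#'
#' Simulates a 3-condition cohort (20 trials x up/down/rest, 2 TMS pulses
#' per trial), then: pre-pulse pupil size (150 ms window) per condition with
#' a within-subject ANOVA and Holm-corrected paired post-hoc tests; MEP
#' records through the three-stage background-EMG exclusion ledger,
#' rest-normalized and compared up vs. down with a paired t-test; heart rate
#' and RMSSD per modulation phase, rest-normalized and compared up vs. down.
#'
#' @param config a [cohort_config()] for `"exp1"` (default cohort when
#'   `NULL`)
#' @param strategy optional per-participant strategy labels; when given, the
#'   normalized MEP contrast is additionally tested within each subgroup
#'   (Holm-corrected family)
#' @param seed overrides `config$seed` when not `NULL`
#' @return list with `pupil`, `mep_records`, `mep_summary`, `exclusions`,
#'   `cardiac`, and `tests`
#' @export
run_exp1 <- function(config = NULL, strategy = NULL, seed = NULL) {
  if (is.null(config)) config <- cohort_config("exp1")
  stopifnot(config$experiment == "exp1")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  truth <- draw_cohort_truth(config)
  n <- config$n_participants

  pupil_rows <- list(); mep_rows <- list(); card_rows <- list()
  for (p in seq_len(n)) {
    sched <- generate_schedule(config, p)
    for (i in seq_len(nrow(sched$trials))) {
      tr <- sched$trials[i, ]
      ev <- sched$events[sched$events$trial_id == tr$trial_id, ]
      # pupil: mean baseline-corrected diameter 150 ms before each pulse
      trace <- .pupil_trace_for_trial(config, truth, p, tr, 31L)
      if (!is.null(trace)) {
        pp <- vapply(ev$onset_s, function(on) {
          pre_pulse_pupil(trace, trace$modulation_start_ms + on * 1000)
        }, 1)
        pupil_rows[[length(pupil_rows) + 1]] <- data.frame(
          participant = p, condition = tr$condition, trial = tr$trial_id,
          pre_pulse_mm = mean(pp, na.rm = TRUE)
        )
      }
      # EMG / MEP
      emg <- simulate_emg_trial(
        pulse_times_s = ev$onset_s,
        mep_mv = .truth_value(truth, p, tr$condition, "mep_mv"),
        bg_rms_mv = config$bg_emg_rms_mv,
        seed = derive_seed(config$seed, p, tr$trial_id, 32L)
      )
      for (k in unique(emg$pulse_index)) {
        seg <- emg[emg$pulse_index == k, ]
        rec <- extract_mep(seg$t_ms, seg$amplitude_mv)
        mep_rows[[length(mep_rows) + 1]] <- data.frame(
          participant = p, condition = tr$condition, trial = tr$trial_id,
          pulse_index = k, peak_to_peak_mv = rec$peak_to_peak_mv,
          bg_rms_mv = rec$bg_rms_mv
        )
      }
      # cardiac: modulation (or rest) phase
      peaks <- simulate_rr_series(
        hr_bpm = .truth_value(truth, p, tr$condition, "hr_bpm"),
        rmssd_ms = .truth_value(truth, p, tr$condition, "rmssd_ms"),
        duration_s = tr$modulation_s,
        jitter_sd_ms = config$rr_jitter_sd_ms,
        seed = derive_seed(config$seed, p, tr$trial_id, 33L)
      )
      rr <- rr_intervals(peaks)
      card_rows[[length(card_rows) + 1]] <- data.frame(
        participant = p, condition = tr$condition, trial = tr$trial_id,
        hr_bpm = heart_rate(rr)$mean_bpm, rmssd_ms = rmssd(rr)
      )
    }
  }
  pupil <- do.call(rbind, pupil_rows)
  meps <- do.call(rbind, mep_rows)
  card <- do.call(rbind, card_rows)

  agg <- function(df, col) {
    stats::aggregate(df[[col]], list(participant = df$participant,
                                     condition = df$condition),
                     mean, na.rm = TRUE)
  }
  wide <- function(a, conds) {
    sapply(conds, function(cc) {
      v <- a$x[a$condition == cc][order(a$participant[a$condition == cc])]
      v
    })
  }

  # pupil statistics
  pa <- agg(pupil, "pre_pulse_mm")
  pw <- wide(pa, c("up", "down", "rest"))
  pupil_anova <- rm_anova(
    data.frame(participant = rep(seq_len(n), 3),
               condition = rep(c("up", "down", "rest"), each = n),
               value = c(pw[, "up"], pw[, "down"], pw[, "rest"])),
    dv = "value", subject = "participant", within = "condition"
  )
  pupil_posthoc <- .holm_family(list(
    up_vs_down = paired_location_test(pw[, "up"], pw[, "down"]),
    up_vs_rest = paired_location_test(pw[, "up"], pw[, "rest"]),
    down_vs_rest = paired_location_test(pw[, "down"], pw[, "rest"])
  ))

  # MEP statistics
  excl <- apply_exclusions(meps)
  surv <- excl$records
  ma <- agg(surv, "peak_to_peak_mv")
  keep_p <- intersect(
    unique(ma$participant),
    ma$participant[!is.na(ma$x)]
  )
  mep_wide <- sapply(c("up", "down", "rest"), function(cc) {
    v <- rep(NA_real_, n)
    sub <- ma[ma$condition == cc, ]
    v[sub$participant] <- sub$x
    v
  })
  ok <- stats::complete.cases(mep_wide) &
    !(seq_len(n) %in% excl$participants$participant[excl$participants$excluded])
  norm <- normalize_to_rest(mep_wide[ok, "up"], mep_wide[ok, "down"],
                            mep_wide[ok, "rest"])
  mep_test <- paired_location_test(norm$up_norm, norm$down_norm)
  strategy_tests <- NULL
  if (!is.null(strategy)) {
    st <- strategy[ok]
    strategy_tests <- .holm_family(lapply(split(seq_along(st), st), function(i) {
      paired_location_test(norm$up_norm[i], norm$down_norm[i])
    }))
  }

  # cardiac statistics (normalized to rest)
  ha <- agg(card, "hr_bpm"); ra <- agg(card, "rmssd_ms")
  hw <- wide(ha, c("up", "down", "rest")); rw <- wide(ra, c("up", "down", "rest"))
  ci <- cardiac_indices(hw[, "up"], hw[, "down"], rw[, "up"], rw[, "down"],
                        hr_rest = hw[, "rest"], rmssd_rest = rw[, "rest"],
                        mode = "exp1")
  hr_test <- paired_location_test(ci$hr_up_norm, ci$hr_down_norm)
  rmssd_test <- paired_location_test(ci$rmssd_up_norm, ci$rmssd_down_norm)

  list(
    truth = truth,
    pupil = pa, mep_records = meps, exclusions = excl,
    mep_summary = cbind(participant = which(ok), norm,
                        bg_norm_diff = excl$participants$bg_norm_diff[
                          match(which(ok), excl$participants$participant)]),
    cardiac = cbind(participant = seq_len(n), ci),
    tests = list(
      pupil_anova = pupil_anova, pupil_posthoc = pupil_posthoc,
      mep_up_vs_down = mep_test, strategy = strategy_tests,
      hr_up_vs_down = hr_test, rmssd_up_vs_down = rmssd_test
    )
  )
}

.accumulate_spectra <- function(store, key, power) {
  if (is.null(store[[key]])) {
    store[[key]] <- list(sum = power, n = 1L)
  } else {
    store[[key]]$sum <- store[[key]]$sum + power
    store[[key]]$n <- store[[key]]$n + 1L
  }
  store
}

#' Run the EEG spectral-slope analysis (experiment 2)
#'
#' Simulates a 2-condition cohort (30 up + 30 down trials, 15 s modulation),
#' then: pupil preprocessing and the modulation index (one-sample t and the
#' up-vs-down paired test); Welch spectra per 3-s bin (one baseline bin plus
#' five modulation bins) averaged across trials, aperiodic fits per channel
#' and whole-head exponents; the paired slope test and the bin x condition
#' ANOVA; heart rate (paired t) and RMSSD (Wilcoxon) with their indices;
#' correlations among the pupil, slope, and cardiac indices, and the
#' Meng-Rosenthal-Rubin comparison of the slope-index correlations. The
#' reported `steepening_index` is exponent down - up (paper sign
#' convention: positive when downregulation steepens the spectrum).
#'
#' @param config a [cohort_config()] for `"exp2"` (default when `NULL`)
#' @param fit_range aperiodic fit range (Hz), default 30-45
#' @param seed overrides `config$seed`
#' @return list with `pupil`, `slopes`, `indices`, `cardiac`, `tests`
#' @export
run_exp2 <- function(config = NULL, fit_range = c(30, 45), seed = NULL) {
  if (is.null(config)) config <- cohort_config("exp2")
  stopifnot(config$experiment == "exp2")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  truth <- draw_cohort_truth(config)
  n <- config$n_participants
  nch <- length(config$channels)
  fs <- 250

  slope_rows <- list(); pupil_rows <- list(); card_rows <- list()
  for (p in seq_len(n)) {
    sched <- generate_schedule(config, p)
    chi_base <- mean(truth$conditions$exponent[truth$conditions$participant == p])
    store <- list()
    for (i in seq_len(nrow(sched$trials))) {
      tr <- sched$trials[i, ]
      cond <- tr$condition
      trace <- .pupil_trace_for_trial(config, truth, p, tr, 41L)
      if (!is.null(trace)) {
        pupil_rows[[length(pupil_rows) + 1]] <- data.frame(
          participant = p, condition = cond, trial = tr$trial_id,
          mean_change_mm = mean(modulation_samples(trace, tr$modulation_s * 1000),
                                na.rm = TRUE)
        )
      }
      seed_eeg <- derive_seed(config$seed, p, tr$trial_id, 42L)
      base_ep <- simulate_eeg_epochs(1, chi_base, config$channels,
                                     n_samples = tr$baseline_s * fs, fs = fs,
                                     noise_scale = config$eeg_noise_scale,
                                     osc_amplitude_uv = config$osc_amplitude_uv,
                                     seed = seed_eeg)
      mod_ep <- simulate_eeg_epochs(1,
                                    .truth_value(truth, p, cond, "exponent"),
                                    config$channels,
                                    n_samples = tr$modulation_s * fs, fs = fs,
                                    noise_scale = config$eeg_noise_scale,
                                    osc_amplitude_uv = config$osc_amplitude_uv,
                                    seed = seed_eeg + 1L)
      arts <- with_seed(seed_eeg + 2L,
                        stats::runif(6) < config$artifact_fraction)
      # one Welch call per trial: all six 3-s bins stacked as rows
      nb <- dim(base_ep$epochs)[3]
      segs <- vector("list", 6)
      segs[[1]] <- matrix(base_ep$epochs[1, , (nb - 3 * fs + 1):nb], nch)
      for (b in 1:5) {
        idx <- ((b - 1) * 3 * fs + 1):(b * 3 * fs)
        segs[[b + 1]] <- matrix(mod_ep$epochs[1, , idx], nch)
      }
      keep_bins <- which(!arts)
      if (length(keep_bins) > 0) {
        psd <- welch_psd(do.call(rbind, segs[keep_bins]), fs)
        for (j in seq_along(keep_bins)) {
          rows <- ((j - 1) * nch + 1):(j * nch)
          store <- .accumulate_spectra(
            store, paste(cond, keep_bins[j] - 1, sep = "|"),
            psd$power[rows, , drop = FALSE])
        }
      }
      peaks <- simulate_rr_series(
        hr_bpm = .truth_value(truth, p, cond, "hr_bpm"),
        rmssd_ms = .truth_value(truth, p, cond, "rmssd_ms"),
        duration_s = tr$modulation_s,
        jitter_sd_ms = config$rr_jitter_sd_ms,
        seed = derive_seed(config$seed, p, tr$trial_id, 43L)
      )
      rr <- rr_intervals(peaks)
      card_rows[[length(card_rows) + 1]] <- data.frame(
        participant = p, condition = cond, trial = tr$trial_id,
        hr_bpm = heart_rate(rr)$mean_bpm, rmssd_ms = rmssd(rr)
      )
    }
    freqs <- 1:45
    for (key in names(store)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      avg <- store[[key]]$sum / store[[key]]$n
      exps <- vapply(seq_len(nch), function(ch) {
        fit_aperiodic(list(freqs = freqs, power = avg[ch, ]), fit_range)$exponent
      }, 1)
      slope_rows[[length(slope_rows) + 1]] <- data.frame(
        participant = p, condition = parts[1], bin = as.integer(parts[2]),
        exponent = mean(exps), n_trials = store[[key]]$n
      )
    }
  }
  slopes <- do.call(rbind, slope_rows)
  pupil <- do.call(rbind, pupil_rows)
  card <- do.call(rbind, card_rows)

  # pupil index
  pa <- stats::aggregate(mean_change_mm ~ participant + condition, pupil, mean)
  pu <- pa$mean_change_mm[pa$condition == "up"][order(pa$participant[pa$condition == "up"])]
  pd <- pa$mean_change_mm[pa$condition == "down"][order(pa$participant[pa$condition == "down"])]
  pupil_index <- pu - pd
  pupil_index_test <- paired_location_test(pupil_index)
  pupil_paired <- paired_location_test(pu, pd)

  # slope tables
  mod_slopes <- slopes[slopes$bin > 0, ]
  sm <- stats::aggregate(exponent ~ participant + condition, mod_slopes, mean)
  su <- sm$exponent[sm$condition == "up"][order(sm$participant[sm$condition == "up"])]
  sd_ <- sm$exponent[sm$condition == "down"][order(sm$participant[sm$condition == "down"])]
  slope_test <- paired_location_test(su, sd_)
  slope_index <- slope_modulation_index(su, sd_)
  steepening_index <- sd_ - su
  anova_df <- slopes
  anova_df$bin <- factor(anova_df$bin)
  slope_anova <- if (!any(is.na(anova_df$exponent)) &&
                       nrow(anova_df) == n * 2 * 6) {
    rm_anova(anova_df, dv = "exponent", subject = "participant",
             within = c("bin", "condition"))
  } else NULL

  # cardiac
  ha <- stats::aggregate(hr_bpm ~ participant + condition, card, mean)
  ra <- stats::aggregate(rmssd_ms ~ participant + condition, card, mean)
  hu <- ha$hr_bpm[ha$condition == "up"][order(ha$participant[ha$condition == "up"])]
  hd <- ha$hr_bpm[ha$condition == "down"][order(ha$participant[ha$condition == "down"])]
  ru <- ra$rmssd_ms[ra$condition == "up"][order(ra$participant[ra$condition == "up"])]
  rd <- ra$rmssd_ms[ra$condition == "down"][order(ra$participant[ra$condition == "down"])]
  hr_test <- paired_location_test(hu, hd)
  rmssd_test <- paired_location_test(ru, rd, method = "wilcoxon")
  ci <- cardiac_indices(hu, hd, ru, rd, mode = "exp2")

  # index correlations (paper sign convention for the slope)
  if (n >= 5) {
    cor_pupil <- correlation(steepening_index, pupil_index)
    cor_hr <- correlation(steepening_index, ci$hr_index)
    cor_rmssd <- correlation(steepening_index, ci$rmssd_index, method = "spearman")
    r_ph <- correlation(pupil_index, ci$hr_index)$r
    r_pr <- correlation(pupil_index, ci$rmssd_index)$r
    meng_hr <- meng_dependent_correlation_z(cor_pupil$r, cor_hr$r, r_ph, n)
    meng_rmssd <- meng_dependent_correlation_z(
      cor_pupil$r, correlation(steepening_index, ci$rmssd_index)$r, r_pr, n)
  } else {
    cor_pupil <- cor_hr <- cor_rmssd <- meng_hr <- meng_rmssd <- NULL
  }

  list(
    truth = truth,
    pupil = pa, slopes = slopes, cardiac = cbind(participant = seq_len(n), ci),
    indices = data.frame(participant = seq_len(n),
                         pupil_index = pupil_index,
                         slope_index = slope_index,
                         steepening_index = steepening_index,
                         hr_index = ci$hr_index, rmssd_index = ci$rmssd_index),
    tests = list(
      pupil_index = pupil_index_test, pupil_up_vs_down = pupil_paired,
      slope_up_vs_down = slope_test, slope_anova = slope_anova,
      hr_up_vs_down = hr_test, rmssd_up_vs_down = rmssd_test,
      cor_slope_pupil = cor_pupil, cor_slope_hr = cor_hr,
      cor_slope_rmssd = cor_rmssd,
      meng_pupil_vs_hr = meng_hr, meng_pupil_vs_rmssd = meng_rmssd
    )
  )
}

#' Run the oddball EEG analysis (experiment 3)
#'
#' Simulates the 3-condition oddball cohort (9 blocks x 13 trials, 8 tones
#' per trial), then: per-tone EEG epochs with evoked components, artifact
#' and behavioral exclusion, baseline-corrected ERPs; 500-ms-bin spectral
#' slopes with the bin x condition x sound ANOVA; cluster-based permutation
#' contrasts on target ERPs in the P300 (252-600 ms) and N100 (52-200 ms)
#' windows; the sound x condition ANOVA on centroparietal mean amplitudes;
#' and the repeated-measures correlation between pre-tone spectral slope
#' (paper sign convention, -exponent) and P300 amplitude on z-scored
#' condition averages.
#'
#' @param config a [cohort_config()] for `"exp3"` (default when `NULL`)
#' @param fit_range aperiodic fit range (Hz)
#' @param n_perm permutations for the cluster tests
#' @param do_slope,do_erp switches for the two analysis arms
#' @param contrasts character vector of `"a_vs_b"` condition contrasts for
#'   the cluster tests
#' @param seed overrides `config$seed`
#' @return list with `slopes`, `p300`, `clusters`, `tests`, `erp_t_ms`,
#'   `target_erps`
#' @export
run_exp3 <- function(config = NULL, fit_range = c(30, 45), n_perm = 1000,
                     do_slope = TRUE, do_erp = TRUE,
                     contrasts = c("down_vs_control", "down_vs_up", "up_vs_control"),
                     seed = NULL) {
  if (is.null(config)) config <- cohort_config("exp3")
  stopifnot(config$experiment == "exp3")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  truth <- draw_cohort_truth(config)
  n <- config$n_participants
  channels <- config$channels
  nch <- length(channels)
  fs <- 250
  p300_set <- intersect(p300_channel_set(), channels)
  if (length(p300_set) == 0) p300_set <- channels
  # epoch span: -500..2000 ms for the slope arm, -100..800 ms otherwise
  t0_ms <- if (do_slope) -500 else -100
  t1_ms <- if (do_slope) 2000 else 800
  L <- round((t1_ms - t0_ms) / 1000 * fs)

  conds <- config$conditions
  slope_rows <- list()
  erps <- list()  # participant-level ERPs per condition x sound
  for (p in seq_len(n)) {
    sched <- generate_schedule(config, p)
    store <- list()
    sum_erp <- list(); n_erp <- list()
    for (i in seq_len(nrow(sched$trials))) {
      tr <- sched$trials[i, ]
      ev <- sched$events[sched$events$trial_id == tr$trial_id, ]
      n_tones <- nrow(ev)
      is_target <- ev$label == "tone_target"
      chi <- .truth_value(truth, p, tr$condition, "exponent")
      p300_amp <- ifelse(is_target,
                         .truth_value(truth, p, tr$condition, "p300_uv"),
                         truth$participants$p300_standard_uv[p])
      eeg <- simulate_eeg_epochs(
        n_tones, chi, channels, n_samples = L, fs = fs, t_start_ms = t0_ms,
        noise_scale = config$eeg_noise_scale,
        erp = list(n100_uv = config$n100_uv, late_uv = p300_amp,
                   late_channels = p300_set),
        osc_amplitude_uv = config$osc_amplitude_uv,
        artifact_fraction = config$artifact_fraction,
        seed = derive_seed(config$seed, p, tr$trial_id, 51L)
      )
      behavior_ok <- with_seed(
        derive_seed(config$seed, p, tr$trial_id, 52L),
        stats::runif(n_tones) >= config$behavior_error_rate
      )
      sound <- ifelse(is_target, "target", "standard")
      if (do_slope) {
        # one Welch call per trial: the five 500-ms bins of every clean
        # epoch stacked as rows
        keep_ep <- which(!eeg$artifact)
        if (length(keep_ep) > 0) {
          bin_sel <- lapply(0:4, function(b) {
            which(eeg$t_ms >= (b - 1) * 500 & eeg$t_ms < b * 500)
          })
          stacked <- do.call(rbind, lapply(keep_ep, function(e) {
            do.call(rbind, lapply(bin_sel, function(sel) {
              matrix(eeg$epochs[e, , sel], nch)
            }))
          }))
          psd <- welch_psd(stacked, fs)
          row0 <- 0L
          for (e in keep_ep) {
            for (b in 0:4) {
              rows <- (row0 + 1):(row0 + nch)
              key <- paste(tr$condition, sound[e], b, sep = "|")
              store <- .accumulate_spectra(store, key,
                                           psd$power[rows, , drop = FALSE])
              row0 <- row0 + nch
            }
          }
        }
      }
      if (do_erp) {
        keep <- !eeg$artifact & behavior_ok
        esel <- eeg$t_ms >= -100 & eeg$t_ms < 800
        bsel <- eeg$t_ms >= -100 & eeg$t_ms < 0
        for (e in which(keep)) {
          epo <- eeg$epochs[e, , esel]
          epo <- epo - rowMeans(eeg$epochs[e, , bsel, drop = FALSE][1, , ])
          key <- paste(tr$condition, sound[e], sep = "|")
          if (is.null(sum_erp[[key]])) {
            sum_erp[[key]] <- epo; n_erp[[key]] <- 1L
          } else {
            sum_erp[[key]] <- sum_erp[[key]] + epo
            n_erp[[key]] <- n_erp[[key]] + 1L
          }
        }
      }
    }
    if (do_slope) {
      freqs <- 1:45
      for (key in names(store)) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        avg <- store[[key]]$sum / store[[key]]$n
        exps <- vapply(seq_len(nch), function(ch) {
          fit_aperiodic(list(freqs = freqs, power = avg[ch, ]), fit_range)$exponent
        }, 1)
        slope_rows[[length(slope_rows) + 1]] <- data.frame(
          participant = p, condition = parts[1], sound = parts[2],
          bin = as.integer(parts[3]), exponent = mean(exps),
          n_trials = store[[key]]$n
        )
      }
    }
    if (do_erp) {
      erps[[p]] <- lapply(names(sum_erp), function(key) sum_erp[[key]] / n_erp[[key]])
      names(erps[[p]]) <- names(sum_erp)
    }
  }

  t_erp <- seq(-100, 800 - 1000 / fs, by = 1000 / fs)
  out <- list(truth = truth, erp_t_ms = t_erp)

  if (do_slope) {
    slopes <- do.call(rbind, slope_rows)
    out$slopes <- slopes
    adf <- slopes
    adf$bin <- factor(adf$bin)
    out$tests$slope_anova <- if (!any(is.na(adf$exponent)) &&
                                   nrow(adf) == n * length(conds) * 2 * 5) {
      rm_anova(adf, dv = "exponent", subject = "participant",
               within = c("bin", "condition", "sound"))
    } else NULL
    cm <- stats::aggregate(exponent ~ participant + condition, slopes, mean)
    w <- sapply(conds, function(cc) {
      cm$exponent[cm$condition == cc][order(cm$participant[cm$condition == cc])]
    })
    out$tests$slope_posthoc <- .holm_family(list(
      up_vs_down = paired_location_test(w[, "up"], w[, "down"]),
      down_vs_control = paired_location_test(w[, "down"], w[, "control"]),
      up_vs_control = paired_location_test(w[, "up"], w[, "control"])
    ))
  }

  if (do_erp) {
    # participant x channel x time arrays of target ERPs per condition
    tgt <- lapply(conds, function(cc) {
      arr <- array(NA_real_, c(n, nch, length(t_erp)))
      for (p in seq_len(n)) {
        key <- paste(cc, "target", sep = "|")
        if (!is.null(erps[[p]][[key]])) arr[p, , ] <- erps[[p]][[key]]
      }
      arr
    })
    names(tgt) <- conds
    out$target_erps <- tgt
    adj <- channel_adjacency(standard_montage(channels))
    win_p300 <- t_erp >= 252 & t_erp < 600
    win_n100 <- t_erp >= 52 & t_erp < 200
    out$clusters <- list()
    for (ct in contrasts) {
      ab <- strsplit(ct, "_vs_")[[1]]
      out$clusters[[paste0("p300_", ct)]] <- cluster_permutation_test(
        tgt[[ab[1]]][, , win_p300, drop = FALSE],
        tgt[[ab[2]]][, , win_p300, drop = FALSE],
        adj, n_perm = n_perm,
        seed = derive_seed(config$seed, 61L, match(ct, contrasts))
      )
      out$clusters[[paste0("n100_", ct)]] <- cluster_permutation_test(
        tgt[[ab[1]]][, , win_n100, drop = FALSE],
        tgt[[ab[2]]][, , win_n100, drop = FALSE],
        adj, n_perm = n_perm,
        seed = derive_seed(config$seed, 62L, match(ct, contrasts))
      )
    }
    # mean amplitudes per condition x sound
    rows <- list()
    for (p in seq_len(n)) {
      for (cc in conds) for (ss in c("target", "standard")) {
        key <- paste(cc, ss, sep = "|")
        m <- erps[[p]][[key]]
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, condition = cc, sound = ss,
          mean_uv = if (is.null(m)) NA_real_ else
            mean_amplitude(m, t_erp, channels, c(252, 600), p300_set)
        )
      }
    }
    p300 <- do.call(rbind, rows)
    out$p300 <- p300
    out$tests$p300_anova <- if (!any(is.na(p300$mean_uv))) {
      rm_anova(p300, dv = "mean_uv", subject = "participant",
               within = c("sound", "condition"))
    } else NULL
    tg <- p300[p300$sound == "target", ]
    wt <- sapply(conds, function(cc) {
      tg$mean_uv[tg$condition == cc][order(tg$participant[tg$condition == cc])]
    })
    out$tests$p300_posthoc <- .holm_family(list(
      down_vs_control = paired_location_test(wt[, "down"], wt[, "control"]),
      down_vs_up = paired_location_test(wt[, "down"], wt[, "up"]),
      up_vs_control = paired_location_test(wt[, "up"], wt[, "control"])
    ))
  }

  if (do_slope && do_erp) {
    pre <- out$slopes[out$slopes$bin == 0 & out$slopes$sound == "target", ]
    pre_m <- stats::aggregate(exponent ~ participant + condition, pre, mean)
    tg <- out$p300[out$p300$sound == "target", ]
    mrg <- merge(pre_m, tg, by = c("participant", "condition"))
    # paper sign convention: slope = -exponent
    out$tests$rm_slope_p300 <- rm_correlation(
      -mrg$exponent, mrg$mean_uv, mrg$participant, z_score_within = TRUE)
  }
  out
}
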