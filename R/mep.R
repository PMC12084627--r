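#' @title Motor evoked potential extraction and exclusion rules
#' @description EMG conditioning (30-800 Hz band-pass with a 50 Hz notch,
#'   applied separately to the pre-pulse background window and the
#'   post-pulse MEP window so the MEP cannot smear into the background
#'   estimate), peak-to-peak MEP amplitude in the 15-60 ms post-pulse
#'   window, background-EMG RMS in the 105-5 ms pre-pulse window, the
#'   three-stage exclusion ledger, and rest-normalized condition summaries.
#' @name mep
NULL

.notch_coef <- function(f0, fs, q = 30) {
  # RBJ biquad notch
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter an EMG window
#'
#' Zero-phase 4th-order Butterworth band-pass (30-800 Hz) followed by a
#' zero-phase 50 Hz biquad notch (Q = 30).
#'
#' @param x numeric EMG trace (mV)
#' @param fs sampling rate (Hz)
#' @param band band-pass edges (Hz)
#' @param notch_hz notch center (Hz); `NULL` disables the notch
#' @return filtered trace
#' @export
filter_emg <- function(x, fs = 5000, band = c(30, 800), notch_hz = 50) {
  if (length(x) < 30) stop("window too short for filtering")
  bp <- .butter_cached(4, band / (fs / 2), "pass")
  pad <- ceiling(0.1 * fs)
  y <- .filtfilt_fast(bp$b, bp$a, x, pad = pad)
  if (!is.null(notch_hz)) {
    nc <- .notch_coef(notch_hz, fs)
    y <- .filtfilt_fast(nc$b, nc$a, y, pad = pad)
  }
  y
}

#' Extract one MEP record from an EMG segment
#'
#' The pre-pulse window `(pulse - 105 ms, pulse - 5 ms]` and the post-pulse
#' window are filtered independently; peak-to-peak amplitude is max - min
#' over `(pulse + 15 ms, pulse + 60 ms]`, background RMS is the root mean
#' square of the filtered pre-pulse window.
#'
#' @param t_ms segment time axis relative to the pulse (ms)
#' @param amplitude_mv raw EMG (mV)
#' @param fs sampling rate (Hz)
#' @return list with `peak_to_peak_mv` and `bg_rms_mv`
#' @export
extract_mep <- function(t_ms, amplitude_mv, fs = 5000) {
  if (min(t_ms) > -105 || max(t_ms) < 60) {
    stop("segment must cover -105 to +60 ms around the pulse")
  }
  pre_sel <- t_ms > -200 & t_ms <= 0
  post_sel <- t_ms > 0
  pre <- filter_emg(amplitude_mv[pre_sel], fs)
  post <- filter_emg(amplitude_mv[post_sel], fs)
  t_pre <- t_ms[pre_sel]; t_post <- t_ms[post_sel]
  bg <- pre[t_pre > -105 & t_pre <= -5]
  mep <- post[t_post > 15 & t_post <= 60]
  list(
    peak_to_peak_mv = max(mep) - min(mep),
    bg_rms_mv = sqrt(mean(bg^2))
  )
}

#' Apply the three-stage background-EMG exclusion rules
#'
#' Stage 1 removes records with background RMS above `abs_limit` (0.01 mV).
#' Stage 2 computes, per participant, mean and sample SD of the remaining
#' background values (pooled over conditions) and removes records above
#' mean + `sd_mult` SD. Stage 3 excludes a participant entirely when the
#' absolute difference of mean background RMS between the upregulation and
#' downregulation conditions exceeds `cond_diff_limit` (0.001 mV). The
#' stages are order-dependent and applied exactly in this order.
#'
#' @param records data.frame with columns `participant`, `condition`,
#'   `bg_rms_mv` and any others (carried through)
#' @param abs_limit stage-1 absolute background limit (mV)
#' @param sd_mult stage-2 SD multiplier
#' @param cond_diff_limit stage-3 condition-difference limit (mV)
#' @return list with `records` (survivors, with an `excluded_stage` column
#'   on the input rows available via `log`), `participants` (per-participant
#'   verdict data.frame: `participant`, `excluded`, `reason`,
#'   `bg_diff_mv`, `bg_norm_diff`), `log` (the input records annotated with
#'   `excluded_stage` 0/1/2/3)
#' @export
apply_exclusions <- function(records, abs_limit = 0.01, sd_mult = 2.5,
                             cond_diff_limit = 0.001) {
  stopifnot(all(c("participant", "condition", "bg_rms_mv") %in% names(records)))
  records$excluded_stage <- 0L
  # stage 1: absolute limit
  records$excluded_stage[records$bg_rms_mv > abs_limit] <- 1L
  # stage 2: per participant, pooled mean + 2.5 SD of the survivors
  for (p in unique(records$participant)) {
    idx <- which(records$participant == p & records$excluded_stage == 0L)
    if (length(idx) < 2) next
    bg <- records$bg_rms_mv[idx]
    thr <- mean(bg) + sd_mult * stats::sd(bg)
    records$excluded_stage[idx[bg > thr]] <- 2L
  }
  # stage 3: participant-level condition difference
  verdicts <- lapply(unique(records$participant), function(p) {
    idx <- which(records$participant == p & records$excluded_stage == 0L)
    sub <- records[idx, ]
    m_up <- mean(sub$bg_rms_mv[sub$condition == "up"])
    m_down <- mean(sub$bg_rms_mv[sub$condition == "down"])
    bg_diff <- m_up - m_down
    bg_norm <- bg_diff / mean(c(m_up, m_down))
    if (length(idx) == 0) {
      return(data.frame(participant = p, excluded = TRUE,
                        reason = "no_surviving_records",
                        bg_diff_mv = NA_real_, bg_norm_diff = NA_real_))
    }
    excl <- is.finite(bg_diff) && abs(bg_diff) > cond_diff_limit
    data.frame(participant = p, excluded = excl,
               reason = if (excl) "participant_bg_diff" else "none",
               bg_diff_mv = bg_diff, bg_norm_diff = bg_norm,
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, verdicts)
  excluded_p <- verdicts$participant[verdicts$excluded]
  records$excluded_stage[records$participant %in% excluded_p &
                           records$excluded_stage == 0L] <- 3L
  list(
    records = records[records$excluded_stage == 0L, , drop = FALSE],
    participants = verdicts,
    log = records
  )
}

#' Normalize condition MEP means to the resting control condition
#'
#' @param up,down,rest per-participant condition means (mV)
#' @return data.frame with `up_norm` and `down_norm` (condition / rest)
#' @export
normalize_to_rest <- function(up, down, rest) {
  if (any(is.na(rest)) || any(rest <= 0)) {
    stop("rest-condition means must be positive and present")
  }
  data.frame(up_norm = up / rest, down_norm = down / rest)
}
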