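#' @title Offline pupillometry preprocessing
#' @description Offline cleaning of two-eye pupil traces following the
#'   standard open-source pupillometry pipeline conventions: dilation-speed
#'   outlier removal with a median-absolute-deviation criterion (multiplier
#'   12), multipass trend-line deviation removal, removal of temporally
#'   isolated sample islands, eye averaging, interpolation to 1000 Hz, and
#'   zero-phase 4 Hz low-pass smoothing; plus baseline correction, trial
#'   rejection, and the pupil modulation index.
#' @name pupil-preprocess
NULL

#' Preprocessing parameters
#'
#' @param mad_multiplier threshold multiplier for the speed and deviation
#'   criteria (robust dispersion via the raw median absolute deviation)
#' @param n_trend_passes number of trend-line deviation passes
#' @param island_max_ms maximum width of an isolated valid island (ms)
#' @param island_gap_ms minimum bordering gap width (ms)
#' @param lowpass_hz zero-phase low-pass cutoff (Hz)
#' @param target_fs output sampling rate (Hz)
#' @param max_interp_gap_ms gaps longer than this stay missing after
#'   interpolation
#' @param range_mm plausible diameter range (mm)
#' @param reject_missing trials with a higher missing fraction are rejected
#' @return list of parameters
#' @export
#' @param speed_mad_floor,dev_mad_floor numerical floors on the MAD entering
#'   the speed (mm/ms) and trend-deviation (mm) thresholds; both sit well
#'   below eye-tracker resolution and only guard the degenerate case of
#'   noise-free traces, where a zero MAD would otherwise reject arbitrarily
#'   small fluctuations
pupil_params <- function(mad_multiplier = 12, n_trend_passes = 4,
                         island_max_ms = 50, island_gap_ms = 40,
                         lowpass_hz = 4, target_fs = 1000,
                         max_interp_gap_ms = 2000,
                         range_mm = c(1.5, 9), reject_missing = 0.5,
                         speed_mad_floor = 1e-4, dev_mad_floor = 1e-3) {
  list(mad_multiplier = mad_multiplier, n_trend_passes = n_trend_passes,
       island_max_ms = island_max_ms, island_gap_ms = island_gap_ms,
       lowpass_hz = lowpass_hz, target_fs = target_fs,
       max_interp_gap_ms = max_interp_gap_ms, range_mm = range_mm,
       reject_missing = reject_missing,
       speed_mad_floor = speed_mad_floor, dev_mad_floor = dev_mad_floor)
}

raw_mad <- function(x) stats::median(abs(x - stats::median(x)))

# speed per sample: max of backward/forward absolute difference per ms
.dilation_speed <- function(t_ms, v) {
  n <- length(v)
  if (n < 2) return(rep(0, n))
  d <- abs(diff(v)) / diff(t_ms)
  pmax(c(d[1], d), c(d, d[n - 1]))
}

.remove_speed_outliers <- function(t_ms, v, mult, mad_floor = 1e-4) {
  ok <- !is.na(v)
  if (sum(ok) < 3) return(v)
  sp <- .dilation_speed(t_ms[ok], v[ok])
  thr <- stats::median(sp) + mult * max(raw_mad(sp), mad_floor)
  idx <- which(ok)[sp > thr]
  v[idx] <- NA
  v
}

.zero_phase_lowpass <- function(x, fs, cutoff, order = 3) {
  wn <- cutoff / (fs / 2)
  if (wn >= 1) return(x)
  bf <- .butter_cached(order, wn, "low")
  .filtfilt_fast(bf$b, bf$a, x, pad = 3 * ceiling(fs / cutoff))
}

# linear interpolation restricted to gaps <= max_gap (in x units);
# leading/trailing NAs stay NA
.interp_limited <- function(x_out, x_in, y_in, max_gap = Inf) {
  ok <- !is.na(y_in)
  if (sum(ok) < 2) return(rep(NA_real_, length(x_out)))
  xi <- x_in[ok]; yi <- y_in[ok]
  out <- stats::approx(xi, yi, xout = x_out, rule = 1)$y
  if (is.finite(max_gap)) {
    gaps <- which(diff(xi) > max_gap)
    for (g in gaps) {
      out[x_out > xi[g] & x_out < xi[g + 1]] <- NA
    }
  }
  out
}

.remove_trend_outliers <- function(t_ms, v, fs, params) {
  for (pass in seq_len(params$n_trend_passes)) {
    ok <- !is.na(v)
    if (sum(ok) < 10) break
    filled <- .interp_limited(t_ms, t_ms, v)
    # fill edges for filtering stability
    filled <- .fill_edges(filled)
    trend <- .zero_phase_lowpass(filled, fs, params$lowpass_hz)
    resid <- abs(v - trend)
    r <- resid[ok]
    thr <- stats::median(r) +
      params$mad_multiplier * max(raw_mad(r), params$dev_mad_floor)
    bad <- which(!is.na(resid) & resid > thr)
    if (length(bad) == 0) break
    v[bad] <- NA
  }
  v
}

.fill_edges <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0) return(x)
  if (ok[1] > 1) x[seq_len(ok[1] - 1)] <- x[ok[1]]
  n <- length(x)
  if (ok[length(ok)] < n) x[(ok[length(ok)] + 1):n] <- x[ok[length(ok)]]
  x
}

.remove_islands <- function(t_ms, v, max_ms, gap_ms) {
  ok <- !is.na(v)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  n <- length(t_ms)
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    width <- t_ms[ends[k]] - t_ms[starts[k]]
    # gap widths span the invalid run bordering the island, measured from the
    # surrounding valid samples; islands at the trace edges count as bordered
    # by an unbounded gap
    gap_before <- if (k == 1) Inf else {
      prev_valid <- starts[k - 1] - 1L
      if (prev_valid < 1) Inf else t_ms[starts[k]] - t_ms[prev_valid]
    }
    gap_after <- if (k == length(r$lengths)) Inf else {
      next_valid <- ends[k + 1] + 1L
      if (next_valid > n) Inf else t_ms[next_valid] - t_ms[ends[k]]
    }
    if (width <= max_ms && gap_before > gap_ms && gap_after > gap_ms) {
      v[starts[k]:ends[k]] <- NA
    }
  }
  v
}

#' Preprocess a raw two-eye pupil trace
#'
#' Per eye: range check, dilation-speed outlier removal (median + 12 MAD of
#' the per-sample speed), multipass trend-line deviation removal (residuals
#' against a 4 Hz zero-phase trend, median + 12 MAD, 4 passes), and removal
#' of temporally isolated islands (<= 50 ms wide bordering a gap > 40 ms).
#' Eyes are then averaged on the common sample grid (single-eye value where
#' only one is valid), the missing fraction recorded, the trace linearly
#' interpolated to 1000 Hz (gaps above `max_interp_gap_ms` stay missing) and
#' smoothed with a zero-phase Butterworth low-pass at 4 Hz. Trials with more
#' than 50% missing samples are marked rejected.
#'
#' @param raw data.frame from [simulate_pupil_trial()] or with the same
#'   columns (`t_ms`, `left_mm`, `right_mm`, `valid_left`, `valid_right`)
#' @param params a [pupil_params()] list
#' @return list of class `clean_pupil`: `t_ms` (1000 Hz grid), `mm`,
#'   `missing_fraction`, `rejected`, and the carried-over
#'   `modulation_start_ms` attribute when present
#' @export
preprocess_pupil <- function(raw, params = pupil_params()) {
  if (nrow(raw) == 0) stop("empty pupil trace")
  t_ms <- raw$t_ms
  fs_in <- 1000 / stats::median(diff(t_ms))
  clean_eye <- function(v, valid) {
    v[!valid] <- NA
    v[v < params$range_mm[1] | v > params$range_mm[2]] <- NA
    v <- .remove_speed_outliers(t_ms, v, params$mad_multiplier,
                                params$speed_mad_floor)
    v <- .remove_trend_outliers(t_ms, v, fs_in, params)
    v <- .remove_islands(t_ms, v, params$island_max_ms, params$island_gap_ms)
    v
  }
  left <- clean_eye(raw$left_mm, raw$valid_left)
  right <- clean_eye(raw$right_mm, raw$valid_right)
  avg <- rowMeans(cbind(left, right), na.rm = TRUE)
  avg[is.nan(avg)] <- NA
  missing_fraction <- mean(is.na(avg))
  rejected <- missing_fraction > params$reject_missing
  t_out <- seq(t_ms[1], t_ms[length(t_ms)], by = 1000 / params$target_fs)
  if (all(is.na(avg))) {
    mm <- rep(NA_real_, length(t_out))
    rejected <- TRUE
    missing_fraction <- 1
  } else {
    mm <- .interp_limited(t_out, t_ms, avg, params$max_interp_gap_ms)
    na_mask <- is.na(mm)
    filled <- .fill_edges(.interp_limited(t_out, t_ms, avg))
    sm <- .zero_phase_lowpass(filled, params$target_fs, params$lowpass_hz)
    sm[na_mask] <- NA
    mm <- sm
  }
  structure(
    list(t_ms = t_out, mm = mm, missing_fraction = missing_fraction,
         rejected = rejected,
         modulation_start_ms = attr(raw, "modulation_start_ms")),
    class = "clean_pupil"
  )
}

#' Baseline-correct a clean pupil trace
#'
#' Subtracts the mean pupil size of the last `baseline_ms` before modulation
#' start from every sample.
#'
#' @param trace a `clean_pupil` object
#' @param modulation_start_ms modulation onset on the trace's time axis
#'   (defaults to the attribute carried by the trace)
#' @param baseline_ms baseline window length (ms)
#' @return the trace with `mm` corrected, `baseline_mean_mm` stored, and
#'   `rejected = TRUE` if the baseline window holds no valid sample
#' @export
baseline_correct <- function(trace, modulation_start_ms = NULL,
                             baseline_ms = 1000) {
  if (is.null(modulation_start_ms)) modulation_start_ms <- trace$modulation_start_ms
  if (is.null(modulation_start_ms)) stop("modulation start time required")
  sel <- trace$t_ms >= modulation_start_ms - baseline_ms &
    trace$t_ms < modulation_start_ms
  if (!any(sel)) stop("baseline window lies outside the trace")
  b <- trace$mm[sel]
  if (all(is.na(b))) {
    trace$rejected <- TRUE
    trace$baseline_mean_mm <- NA_real_
    return(trace)
  }
  bm <- mean(b, na.rm = TRUE)
  trace$mm <- trace$mm - bm
  trace$baseline_mean_mm <- bm
  trace$modulation_start_ms <- modulation_start_ms
  trace
}

#' Modulation-phase samples of a corrected trace
#'
#' @param trace baseline-corrected `clean_pupil`
#' @param window_ms modulation window length
#' @return numeric vector (one value per ms)
#' @export
modulation_samples <- function(trace, window_ms = 15000) {
  start <- trace$modulation_start_ms
  step <- stats::median(diff(trace$t_ms))
  sel <- trace$t_ms >= start & trace$t_ms < start + window_ms
  v <- trace$mm[sel]
  n_exp <- round(window_ms / step)
  # a trace sampled up to the nominal trial end can fall a few samples short
  # of the full window; report the window length with trailing missings
  if (length(v) < n_exp) v <- c(v, rep(NA_real_, n_exp - length(v)))
  v
}

#' Pupil modulation index
#'
#' Mean across upregulation trials minus mean across downregulation trials
#' of the baseline-corrected traces, per millisecond of the modulation
#' window; the scalar index is the mean of this difference time series.
#'
#' @param up_trials,down_trials lists of baseline-corrected `clean_pupil`
#'   traces (rejected trials should be filtered out by the caller)
#' @param window_ms modulation window (15 s = 15,000 points at 1000 Hz)
#' @return list with `timeseries` (mm difference per ms) and `scalar` (mm)
#' @export
pupil_modulation_index <- function(up_trials, down_trials, window_ms = 15000) {
  if (length(up_trials) == 0 || length(down_trials) == 0) {
    stop("need at least one accepted trial per condition")
  }
  avg <- function(trials) {
    m <- vapply(trials, modulation_samples, numeric(window_ms),
                window_ms = window_ms)
    rowMeans(m, na.rm = TRUE)
  }
  ts <- avg(up_trials) - avg(down_trials)
  list(timeseries = ts, scalar = mean(ts, na.rm = TRUE))
}

#' Mean baseline-corrected pupil size before a TMS pulse
#'
#' @param trace baseline-corrected `clean_pupil`
#' @param pulse_ms pulse time on the trace's time axis
#' @param window_ms averaging window before the pulse (150 ms)
#' @return mean over `(pulse - window, pulse]`, `NA` when the window holds
#'   only missing data
#' @export
pre_pulse_pupil <- function(trace, pulse_ms, window_ms = 150) {
  sel <- trace$t_ms > pulse_ms - window_ms & trace$t_ms <= pulse_ms
  if (!any(sel)) stop("pre-pulse window lies outside the trace")
  v <- trace$mm[sel]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}
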