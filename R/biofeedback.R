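#' @title Online biofeedback engine
#' @description Re-creation of the online feedback computation used during
#'   pupil self-regulation trials: per-sample validity checks (range and
#'   dilation-velocity limits, blink flags), the baseline-referenced average
#'   and extreme change shown after each trial, the success classification
#'   driving the feedback color, and the isoluminance helper used to match
#'   display colors to the gray background.
#' @name biofeedback
NULL

#' Online filter parameters
#'
#' The printed velocity limit of 0.0027 is physiologically implausible when
#' read as mm/s (reported light-reflex peak velocities are orders of
#' magnitude larger), so the default interpretation is 0.0027 mm/ms
#' (2.7 mm/s). Both readings are selectable via `velocity_units`.
#'
#' @param min_mm,max_mm plausible pupil-diameter range in mm
#' @param velocity_threshold maximum plausible absolute pupil-size change per
#'   unit time
#' @param velocity_units `"mm_per_ms"` (default) or `"mm_per_s"`
#' @return list of class `online_filter_params`
#' @export
online_filter_params <- function(min_mm = 1.5, max_mm = 9,
                                 velocity_threshold = 0.0027,
                                 velocity_units = c("mm_per_ms", "mm_per_s")) {
  velocity_units <- match.arg(velocity_units)
  if (!(min_mm < max_mm)) stop("min_mm must be smaller than max_mm")
  if (velocity_threshold <= 0) stop("velocity_threshold must be positive")
  structure(
    list(min_mm = min_mm, max_mm = max_mm,
         velocity_threshold = velocity_threshold,
         velocity_units = velocity_units),
    class = "online_filter_params"
  )
}

#' Validate one online pupil sample
#'
#' A sample is invalid when flagged as a blink by the tracker, outside the
#' plausible diameter range, or when the rate of change relative to the last
#' valid sample exceeds the velocity threshold. The first valid sample of a
#' stream has no velocity check.
#'
#' @param current pupil diameter in mm (`NA` is treated as a blink)
#' @param previous last valid diameter in mm, or `NULL` if none yet
#' @param dt_s time since the last valid sample in seconds (required when
#'   `previous` is given)
#' @param params an [online_filter_params()] object
#' @param blink logical tracker blink flag for this sample
#' @return list with `valid` (logical) and `reason`
#'   (one of `"ok"`, `"blink"`, `"range"`, `"velocity"`)
#' @export
validate_sample <- function(current, previous = NULL, dt_s = NULL,
                            params = online_filter_params(), blink = FALSE) {
  if (isTRUE(blink) || is.na(current)) {
    return(list(valid = FALSE, reason = "blink"))
  }
  if (current < params$min_mm || current > params$max_mm) {
    return(list(valid = FALSE, reason = "range"))
  }
  if (!is.null(previous) && !is.na(previous)) {
    if (is.null(dt_s) || dt_s <= 0) stop("dt_s must be positive when a previous sample exists")
    dt <- switch(params$velocity_units,
      mm_per_ms = dt_s * 1000,
      mm_per_s = dt_s
    )
    if (abs(current - previous) / dt > params$velocity_threshold) {
      return(list(valid = FALSE, reason = "velocity"))
    }
  }
  list(valid = TRUE, reason = "ok")
}

#' Apply the online validity filter to a sample stream
#'
#' Streams [validate_sample()] over a trace, always comparing against the
#' most recent valid sample (so that a rejected spike does not become the
#' reference for its successor).
#'
#' @param t_s sample times in seconds
#' @param mm pupil diameters in mm
#' @param blink logical blink flags (defaults to all `FALSE`)
#' @param params an [online_filter_params()] object
#' @return data.frame with `t_s`, `mm`, `valid`, `reason`
#' @export
apply_online_filter <- function(t_s, mm, blink = NULL, params = online_filter_params()) {
  n <- length(mm)
  stopifnot(length(t_s) == n)
  if (is.null(blink)) blink <- rep(FALSE, n)
  valid <- logical(n); reason <- character(n)
  prev <- NULL; prev_t <- NULL
  for (i in seq_len(n)) {
    res <- validate_sample(mm[i], prev,
                           if (is.null(prev_t)) NULL else t_s[i] - prev_t,
                           params, blink = blink[i])
    valid[i] <- res$valid; reason[i] <- res$reason
    if (res$valid) { prev <- mm[i]; prev_t <- t_s[i] }
  }
  data.frame(t_s = t_s, mm = mm, valid = valid, reason = reason)
}

#' Post-trial feedback from valid samples
#'
#' Baseline is the mean of the valid baseline-phase samples; the mean change
#' is the mean of the valid modulation-phase samples minus baseline, and the
#' extreme change is the maximum change for upregulation and the minimum for
#' downregulation. A trial counts as successful (green circle) only under a
#' strict inequality in the instructed direction; a mean change of exactly
#' zero is unsuccessful (pink) for both directions.
#'
#' @param baseline_mm valid baseline-phase diameters (mm)
#' @param modulation_mm valid modulation-phase diameters (mm)
#' @param direction `"up"` or `"down"`
#' @return list of class `feedback_result` with `mean_change_mm`,
#'   `extreme_change_mm`, `success`, `color` (`"green"`/`"pink"`),
#'   `n_valid_samples`
#' @export
compute_feedback <- function(baseline_mm, modulation_mm, direction = c("up", "down")) {
  direction <- match.arg(direction)
  baseline_mm <- baseline_mm[!is.na(baseline_mm)]
  modulation_mm <- modulation_mm[!is.na(modulation_mm)]
  if (length(baseline_mm) == 0 || length(modulation_mm) == 0) {
    stop("feedback unavailable: no valid samples in baseline or modulation phase")
  }
  baseline <- mean(baseline_mm)
  changes <- modulation_mm - baseline
  mean_change <- mean(changes)
  extreme <- if (direction == "up") max(changes) else min(changes)
  success <- if (direction == "up") mean_change > 0 else mean_change < 0
  structure(
    list(mean_change_mm = mean_change, extreme_change_mm = extreme,
         success = success, color = if (success) "green" else "pink",
         n_valid_samples = length(baseline_mm) + length(modulation_mm)),
    class = "feedback_result"
  )
}

#' Relative luminance of an RGB color
#'
#' Y = 0.2126 R + 0.7152 G + 0.0722 B, used to pick display colors
#' isoluminant to the gray background (RGB 150, 150, 150).
#'
#' @param r,g,b color components in \[0, 255\]
#' @return relative luminance on the same 0-255 scale
#' @export
relative_luminance <- function(r, g, b) {
  if (any(c(r, g, b) < 0) || any(c(r, g, b) > 255)) {
    stop("color components must lie in [0, 255]")
  }
  0.2126 * r + 0.7152 * g + 0.0722 * b
}
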