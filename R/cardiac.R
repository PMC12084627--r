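#' @title Cardiac indices from R-peak series
#' @description Heart rate and time-domain heart-rate variability (RMSSD)
#'   computed from R-peak times, with the phase rule that an R-R interval
#'   counts only when both bounding peaks fall inside the phase window.
#' @name cardiac
NULL

#' R-R intervals within a phase window
#'
#' @param r_peaks numeric vector of R-peak times in seconds, strictly
#'   increasing
#' @param phase_start,phase_end optional phase bounds in seconds; an interval
#'   is retained only if both of its R peaks lie inside `[phase_start,
#'   phase_end]`
#' @return numeric vector of R-R intervals in seconds (possibly empty)
#' @export
rr_intervals <- function(r_peaks, phase_start = -Inf, phase_end = Inf) {
  r_peaks <- sort(as.numeric(r_peaks))
  if (any(diff(r_peaks) <= 0)) stop("R-peak times must be strictly increasing")
  inside <- r_peaks >= phase_start & r_peaks <= phase_end
  rr <- diff(r_peaks)
  both_in <- inside[-length(inside)] & inside[-1]
  rr[both_in]
}

#' Heart rate from R-R intervals
#'
#' Per-interval instantaneous rate is 60 divided by the interval; the phase
#' value is the arithmetic mean over intervals.
#'
#' @param rr numeric vector of R-R intervals in seconds
#' @return list with `bpm` (per-interval series) and `mean_bpm` (`NA` when
#'   there is no interval)
#' @export
heart_rate <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) == 0) return(list(bpm = numeric(0), mean_bpm = NA_real_))
  if (any(rr <= 0)) stop("R-R intervals must be positive")
  bpm <- 60 / rr
  list(bpm = bpm, mean_bpm = mean(bpm))
}

#' Root mean square of successive differences (RMSSD)
#'
#' @param rr numeric vector of R-R intervals in seconds (>= 2 intervals)
#' @return RMSSD in milliseconds, `NA` when fewer than 2 intervals
#' @export
rmssd <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 2) return(NA_real_)
  if (any(rr <= 0)) stop("R-R intervals must be positive")
  1000 * sqrt(mean(diff(rr)^2))
}

#' Cardiac modulation indices
#'
#' Two conventions: `mode = "exp2"` forms direct condition differences
#' (HR index = up - down; RMSSD index = down - up, so that larger values mark
#' stronger arousal modulation in both). `mode = "exp1"` first divides each
#' modulation condition by the resting control condition and then forms the
#' same contrasts on the normalized values.
#'
#' @param hr_up,hr_down,rmssd_up,rmssd_down per-participant phase means
#' @param hr_rest,rmssd_rest rest-condition values, required for
#'   `mode = "exp1"`
#' @param mode `"exp2"` (raw differences) or `"exp1"` (rest-normalized)
#' @return data.frame with per-participant columns `hr_index` and
#'   `rmssd_index` (plus the normalized condition values in exp1 mode)
#' @export
cardiac_indices <- function(hr_up, hr_down, rmssd_up, rmssd_down,
                            hr_rest = NULL, rmssd_rest = NULL,
                            mode = c("exp2", "exp1")) {
  mode <- match.arg(mode)
  n <- length(hr_up)
  stopifnot(length(hr_down) == n, length(rmssd_up) == n, length(rmssd_down) == n)
  if (mode == "exp1") {
    if (is.null(hr_rest) || is.null(rmssd_rest)) {
      stop("rest-condition values required for exp1-style normalization")
    }
    if (any(hr_rest == 0, na.rm = TRUE) || any(rmssd_rest == 0, na.rm = TRUE)) {
      stop("rest values must be nonzero for normalization")
    }
    hr_up_n <- hr_up / hr_rest; hr_down_n <- hr_down / hr_rest
    rm_up_n <- rmssd_up / rmssd_rest; rm_down_n <- rmssd_down / rmssd_rest
    data.frame(
      hr_up_norm = hr_up_n, hr_down_norm = hr_down_n,
      rmssd_up_norm = rm_up_n, rmssd_down_norm = rm_down_n,
      hr_index = hr_up_n - hr_down_n,
      rmssd_index = rm_down_n - rm_up_n
    )
  } else {
    data.frame(
      hr_index = hr_up - hr_down,
      rmssd_index = rmssd_down - rmssd_up
    )
  }
}
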