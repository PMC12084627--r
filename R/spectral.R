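#' @title Welch spectra and aperiodic (spectral slope) parameterization
#' @description Welch power spectral densities on a 1 Hz grid from 1-45 Hz,
#'   and a spectral parameterization that decomposes each log-power spectrum
#'   into an aperiodic component (offset and exponent, the "spectral slope")
#'   plus up to `max_peaks` Gaussian oscillatory peaks, following the
#'   fixed-mode algorithm of the standard parameterization toolbox: initial
#'   line fit, robust refit excluding peak-inflated points, iterative peak
#'   extraction on the flattened spectrum, joint Gaussian refit, and a final
#'   aperiodic refit on the peak-removed spectrum.
#' @name spectral
NULL

#' Welch power spectral density
#'
#' 1-second Hamming-windowed segments with 50% overlap, averaged
#' periodograms, returned on the 1-45 Hz grid (1 Hz resolution). Segments
#' are mean-detrended. Epochs shorter than one segment are zero-padded to a
#' single 1 s segment, so short analysis bins keep the stated grid.
#'
#' @param x numeric vector, or matrix with one channel per row
#' @param fs sampling rate in Hz (must be >= 90 to cover 45 Hz)
#' @param fmin,fmax retained frequency range (Hz)
#' @param window `"hann"` (default) or `"hamming"`. Hann is used because its
#'   sidelobes fall off at 18 dB/octave, which keeps leakage from the large
#'   low-frequency power of steep 1/f spectra out of the 30-45 Hz range;
#'   Hamming's flat -43 dB sidelobes measurably flatten spectra with
#'   exponents near 3.
#' @return list of class `power_spectrum`: `freqs` (Hz), `power` (linear
#'   units per Hz; matrix channels x freqs when `x` is a matrix),
#'   `n_segments`
#' @export
welch_psd <- function(x, fs, fmin = 1, fmax = 45,
                      window = c("hann", "hamming")) {
  window <- match.arg(window)
  if (fs < 2 * fmax) stop("sampling rate too low to cover ", fmax, " Hz")
  one <- is.null(dim(x))
  if (one) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  seg <- round(fs)
  step <- floor(seg / 2)
  if (n < seg) {
    x <- cbind(x, matrix(0, nrow(x), seg - n))
    n <- seg
  }
  starts <- seq(1, n - seg + 1, by = step)
  k <- 0:(seg - 1)
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * k / (seg - 1)))
  } else {
    0.54 - 0.46 * cos(2 * pi * k / (seg - 1))
  }
  u <- sum(w^2)
  freqs_all <- (0:(seg - 1)) * fs / seg
  keep <- which(freqs_all >= fmin - 1e-9 & freqs_all <= fmax + 1e-9)
  acc <- matrix(0, nrow(x), length(keep))
  for (s in starts) {
    segm <- x[, s:(s + seg - 1), drop = FALSE]
    segm <- segm - rowMeans(segm)
    segm <- sweep(segm, 2, w, "*")
    ft <- t(stats::mvfft(t(segm)))
    p <- (Mod(ft)^2) / (fs * u) * 2  # one-sided density
    acc <- acc + p[, keep, drop = FALSE]
  }
  pow <- acc / length(starts)
  structure(
    list(freqs = freqs_all[keep],
         power = if (one) as.numeric(pow) else pow,
         n_segments = length(starts)),
    class = "power_spectrum"
  )
}

.gaussian_model <- function(f, par3) {
  # par3: matrix with columns center, height, sd
  out <- numeric(length(f))
  if (is.null(par3) || nrow(par3) == 0) return(out)
  for (k in seq_len(nrow(par3))) {
    out <- out + par3[k, 2] * exp(-((f - par3[k, 1])^2) / (2 * par3[k, 3]^2))
  }
  out
}

.line_fit <- function(lx, ly) {
  cf <- stats::.lm.fit(cbind(1, lx), ly)$coefficients
  c(offset = cf[1], slope = cf[2])
}

#' Aperiodic parameterization of a power spectrum
#'
#' Fits log10 power as a straight line in log10 frequency (fixed mode; the
#' exponent chi is the negated slope) plus up to `max_peaks` Gaussian peaks.
#'
#' @param spectrum a `power_spectrum`, or a list with `freqs` and `power`
#'   (single spectrum)
#' @param fit_range numeric length-2 Hz interval, e.g. `c(30, 45)` or
#'   `c(2, 40)`
#' @param max_peaks maximum number of peaks (default 3)
#' @param peak_width_limits Gaussian FWHM limits in Hz
#' @param peak_threshold relative peak threshold in SD of the flattened
#'   spectrum
#' @param min_peak_height absolute minimum peak height (log10 power)
#' @param robust_quantile quantile of the positive flattened residuals below
#'   which points enter the robust aperiodic refit
#' @return list of class `aperiodic_fit`: `offset`, `exponent`, `peaks`
#'   (data.frame center/height/width), `r_squared`, `mean_abs_error`,
#'   `fit_range`
#' @export
fit_aperiodic <- function(spectrum, fit_range, max_peaks = 3,
                          peak_width_limits = c(0.5, 12),
                          peak_threshold = 2, min_peak_height = 0,
                          robust_quantile = 0.025) {
  f <- spectrum$freqs
  p <- spectrum$power
  sel <- f >= fit_range[1] - 1e-9 & f <= fit_range[2] + 1e-9
  f <- f[sel]; p <- p[sel]
  if (length(f) < 5) stop("need at least 5 frequency points in the fit range")
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("power must be positive and finite across the fit range")
  }
  lx <- log10(f); ly <- log10(p)

  # (1) initial aperiodic line
  init <- .line_fit(lx, ly)
  # (2) robust refit: drop peak-inflated points
  flat <- ly - (init[1] + init[2] * lx)
  flat[flat < 0] <- 0
  thr <- stats::quantile(flat, robust_quantile, names = FALSE)
  mask <- flat <= thr
  ap <- if (sum(mask) >= 2) .line_fit(lx[mask], ly[mask]) else init

  # (3) iterative peak extraction on the flattened spectrum
  sd_limits <- peak_width_limits / 2
  flatspec <- ly - (ap[1] + ap[2] * lx)
  guesses <- NULL
  work <- flatspec
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))  # population SD, as the
  # published algorithm uses
  for (k in seq_len(max_peaks)) {
    i_max <- which.max(work)
    h <- work[i_max]
    if (h <= peak_threshold * sd_pop(work) || h <= min_peak_height) break
    cf <- f[i_max]
    # half-height width estimate
    half <- h / 2
    ri <- i_max; while (ri < length(f) && work[ri] > half) ri <- ri + 1
    li <- i_max; while (li > 1 && work[li] > half) li <- li - 1
    fwhm <- min(abs(f[ri] - cf), abs(cf - f[li])) * 2
    gsd <- fwhm / (2 * sqrt(2 * log(2)))
    gsd <- min(max(gsd, sd_limits[1]), sd_limits[2])
    guesses <- rbind(guesses, c(cf, h, gsd))
    work <- work - h * exp(-((f - cf)^2) / (2 * gsd^2))
  }

  peaks <- NULL
  if (!is.null(guesses)) {
    # (4) joint refit of all Gaussians on the flattened spectrum
    np <- nrow(guesses)
    par0 <- as.vector(t(guesses))
    lower <- as.vector(t(cbind(pmax(fit_range[1], guesses[, 1] - 2 * guesses[, 3]),
                               0, sd_limits[1])))
    upper <- as.vector(t(cbind(pmin(fit_range[2], guesses[, 1] + 2 * guesses[, 3]),
                               Inf, sd_limits[2])))
    resid_fn <- function(par) {
      flatspec - .gaussian_model(f, matrix(par, ncol = 3, byrow = TRUE))
    }
    opt <- try(minpack.lm::nls.lm(par0, lower = lower, upper = upper,
                                  fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(maxiter = 500)),
               silent = TRUE)
    peaks <- if (inherits(opt, "try-error")) {
      obj <- function(par) sum(resid_fn(par)^2)
      o2 <- try(stats::optim(par0, obj, method = "L-BFGS-B",
                             lower = lower, upper = upper), silent = TRUE)
      if (inherits(o2, "try-error")) guesses else
        matrix(o2$par, ncol = 3, byrow = TRUE)
    } else {
      matrix(opt$par, ncol = 3, byrow = TRUE)
    }
  }

  # (5) final aperiodic refit on the peak-removed spectrum
  peak_part <- .gaussian_model(f, peaks)
  ap_final <- .line_fit(lx, ly - peak_part)
  model <- ap_final[1] + ap_final[2] * lx + peak_part
  r2 <- if (stats::sd(ly) == 0 || stats::sd(model) == 0) 1 else
    stats::cor(ly, model)^2
  structure(
    list(
      offset = unname(ap_final[1]),
      exponent = unname(-ap_final[2]),
      peaks = if (is.null(peaks)) {
        data.frame(center_hz = numeric(0), height_log10 = numeric(0),
                   width_hz = numeric(0))
      } else {
        data.frame(center_hz = peaks[, 1], height_log10 = peaks[, 2],
                   width_hz = peaks[, 3])
      },
      r_squared = r2,
      mean_abs_error = mean(abs(ly - model)),
      fit_range = fit_range
    ),
    class = "aperiodic_fit"
  )
}

#' Exponent table per participant x condition x time bin
#'
#' Averages trial spectra within each cell (after excluding artifact-flagged
#' bins), fits the aperiodic model once on the cell-average spectrum per
#' channel, and reports the whole-head exponent as the mean over channels.
#'
#' @param spectra data.frame-like long table of per-trial bin spectra:
#'   needs list-columns or, as used here, a list with elements `meta`
#'   (data.frame: `participant`, `condition`, `bin`, optional `sound`,
#'   `trial`, `artifact`) and `power` (matrix, one row per meta row, one
#'   column per frequency) plus `freqs`
#' @param fit_range Hz interval for the aperiodic fit
#' @param by grouping columns of `meta` (default participant, condition,
#'   bin, and sound when present)
#' @param ... further arguments for [fit_aperiodic()]
#' @return data.frame with the grouping columns plus `exponent`, `offset`,
#'   `r_squared`, `n_trials`; cells that lose every trial to artifact
#'   exclusion are returned with `NA` values
#' @export
slope_for_bins <- function(spectra, fit_range, by = NULL, ...) {
  meta <- spectra$meta
  pow <- spectra$power
  freqs <- spectra$freqs
  if (is.null(by)) {
    by <- intersect(c("participant", "condition", "sound", "bin"), names(meta))
  }
  keep <- if ("artifact" %in% names(meta)) !meta$artifact else rep(TRUE, nrow(meta))
  key <- interaction(meta[by], drop = FALSE, lex.order = TRUE)
  cells <- unique(meta[by])
  cell_key <- interaction(cells[by], drop = FALSE, lex.order = TRUE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    idx <- which(key == cell_key[i] & keep)
    row <- cells[i, , drop = FALSE]
    if (length(idx) == 0) {
      return(cbind(row, exponent = NA_real_, offset = NA_real_,
                   r_squared = NA_real_, n_trials = 0L))
    }
    avg <- colMeans(pow[idx, , drop = FALSE])
    fit <- fit_aperiodic(list(freqs = freqs, power = avg), fit_range, ...)
    cbind(row, exponent = fit$exponent, offset = fit$offset,
          r_squared = fit$r_squared, n_trials = length(idx))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Spectral-slope modulation index
#'
#' Per-participant difference of mean exponents, upregulation minus
#' downregulation.
#'
#' @param up,down numeric vectors of exponents paired by participant (or
#'   matrices participant x bin, averaged over bins first)
#' @return numeric vector of per-participant indices
#' @export
slope_modulation_index <- function(up, down) {
  if (is.matrix(up)) up <- rowMeans(up, na.rm = TRUE)
  if (is.matrix(down)) down <- rowMeans(down, na.rm = TRUE)
  if (length(up) != length(down)) stop("inputs must be paired by participant")
  up - down
}
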