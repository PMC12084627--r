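# Shared zero-phase filtering helpers.
#
# Zero-phase application: forward pass, time reversal, second pass, reversal
# back. Odd-reflection padding at both ends suppresses the zero-initial-
# condition edge transients (a constant input passes through exactly).

.filtfilt_fast <- function(b, a, x, pad = 0) {
  n <- length(x)
  p <- min(n - 1, pad)
  if (p > 0) {
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  } else {
    xp <- x
  }
  y <- iir_filtfilt(b, a, xp)
  if (p > 0) y[(p + 1):(p + n)] else y
}

# cached Butterworth designs (signal::butter is called once per spec)
.filter_cache <- new.env(parent = emptyenv())

.butter_cached <- function(order, w, type) {
  key <- paste(type, order, paste(format(w, digits = 12), collapse = ","))
  bf <- .filter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, w, type = type)
    .filter_cache[[key]] <- bf
  }
  bf
}
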