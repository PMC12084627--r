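# Deterministic bank of random synthetic log-power spectra used for the
# cross-implementation agreement test of the aperiodic fit.
make_reference_spectra <- function(n = 50, seed = 20260930) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  f <- 1:45
  lapply(seq_len(n), function(i) {
    chi <- runif(1, 0.5, 3)
    offset <- runif(1, -1, 1)
    npk <- sample(0:2, 1)
    lp <- offset - chi * log10(f)
    if (npk > 0) {
      for (k in seq_len(npk)) {
        ctr <- runif(1, 4, 35)
        hgt <- runif(1, 0.2, 0.8)
        wid <- runif(1, 1, 3)
        lp <- lp + hgt * exp(-((f - ctr)^2) / (2 * wid^2))
      }
    }
    lp <- lp + rnorm(length(f), 0, 0.02)
    list(freqs = f, power = 10^lp, chi = chi)
  })
}
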