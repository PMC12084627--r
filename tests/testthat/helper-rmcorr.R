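# Deterministic datasets for the rm-correlation cross-implementation check.
make_rmcorr_datasets <- function(n = 20, seed = 77) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ns <- sample(4:10, 1)
    no <- sample(3:8, 1)
    subj <- rep(seq_len(ns), each = no)
    x <- rnorm(ns * no) + rep(rnorm(ns, 0, 2), each = no)
    y <- 0.5 * x + rnorm(ns * no) + rep(rnorm(ns, 0, 2), each = no)
    data.frame(subject = subj, x = x, y = y)
  })
}
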