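#' @title Repeated-measures statistical layer
#' @description Paired and one-sample location tests with effect sizes,
#'   Holm sequential Bonferroni correction, within-subject ANOVA with
#'   Greenhouse-Geisser adjustment, repeated-measures correlation, ordinary
#'   Pearson/Spearman correlation, and the Meng-Rosenthal-Rubin z test for
#'   comparing dependent correlations. These are the group-level tools used
#'   by the experiment pipelines.
#' @name stats-layer
NULL

#' Paired or one-sample location test with effect size
#'
#' Two-sided paired-samples test of `x` against `y` (or of `x` against `mu`
#' when `y` is `NULL`). For `method = "t"`, Cohen's d for paired data is the
#' mean difference divided by the standard deviation of the differences.
#' For `method = "wilcoxon"`, the exact signed-rank distribution is used for
#' n <= 25 and the normal approximation with continuity correction above.
#'
#' @param x,y numeric vectors of equal length (`y = NULL` for a one-sample
#'   test against `mu`)
#' @param method `"t"` or `"wilcoxon"`
#' @param mu null value for the (mean) difference
#' @return list with `statistic`, `df`, `p`, `effect_size` (Cohen's d, t only),
#'   `mean_difference`, `method`
#' @export
paired_location_test <- function(x, y = NULL, method = c("t", "wilcoxon"), mu = 0) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(x) != length(y)) stop("x and y must have equal length")
    d <- x - y
  } else {
    d <- x
  }
  keep <- !is.na(d)
  d <- d[keep]
  n <- length(d)
  if (method == "t") {
    if (n < 2) stop("need at least 2 paired observations")
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      # degenerate zero-variance differences: identical pairs give the null
      # exactly; a constant nonzero shift is infinitely unlikely under it
      same <- isTRUE(all.equal(mean(d), mu))
      return(list(
        statistic = if (same) 0 else sign(mean(d) - mu) * Inf,
        df = n - 1, p = if (same) 1 else 0,
        effect_size = if (same) 0 else sign(mean(d) - mu) * Inf,
        mean_difference = mean(d) - mu, method = "t"
      ))
    }
    ht <- stats::t.test(d, mu = mu)
    list(
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value,
      effect_size = (mean(d) - mu) / sd_d,
      mean_difference = mean(d) - mu, method = "t"
    )
  } else {
    if (!any(d != mu)) stop("wilcoxon test needs at least one nonzero difference")
    ht <- stats::wilcox.test(d, mu = mu, exact = n <= 25, correct = TRUE)
    list(
      statistic = unname(ht$statistic), df = NA_real_, p = ht$p.value,
      effect_size = NA_real_, mean_difference = mean(d) - mu,
      method = "wilcoxon"
    )
  }
}

#' Holm sequential Bonferroni adjustment
#'
#' Step-down multiple-comparison correction: the i-th smallest p-value is
#' multiplied by (m - i + 1) with monotonicity enforced, capped at 1, and
#' returned in the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same order as the input
#' @export
holm_sequential_bonferroni <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Within-subject (repeated-measures) ANOVA with Greenhouse-Geisser correction
#'
#' Classical fully within-subject sums-of-squares decomposition for 1-3
#' crossed within factors on a complete balanced table. Each within effect is
#' tested against its own effect-by-subject interaction. Greenhouse-Geisser
#' epsilon is computed per effect from the covariance of the orthonormal
#' contrast scores and, under the default policy, applied whenever the effect
#' has more than one numerator df and epsilon < 1 (sphericity is trivially
#' satisfied for 2-level effects).
#'
#' @param data data.frame in long format
#' @param dv name of the numeric response column
#' @param subject name of the subject identifier column
#' @param within character vector (length 1-3) of within-factor column names
#' @param gg_policy `"auto"` (apply GG whenever epsilon < 1 and df1 > 1),
#'   `"always"`, or `"never"`
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`,
#'   `ss_effect`, `ss_error`, `F`, `p`, `epsilon`, `df1_adj`, `df2_adj`,
#'   `p_adj` (GG-corrected when the policy fires, else equal to `p`), `pes`
#'   (partial eta squared). Attribute `"ss_total"` and `"ss_subject"` carry
#'   the conservation terms.
#' @export
rm_anova <- function(data, dv, subject, within, gg_policy = c("auto", "always", "never")) {
  gg_policy <- match.arg(gg_policy)
  if (length(within) < 1 || length(within) > 3) stop("1 to 3 within factors supported")
  data <- as.data.frame(data)
  for (v in c(dv, subject, within)) {
    if (!v %in% names(data)) stop("column not found: ", v)
  }
  subj <- factor(data[[subject]])
  facs <- lapply(within, function(v) factor(data[[v]]))
  lv <- vapply(facs, nlevels, 1L)
  cells <- interaction(facs, lex.order = TRUE, drop = FALSE)
  tab <- table(subj, cells)
  if (any(tab != 1)) stop("design must be complete and balanced with one observation per cell")
  n <- nlevels(subj)
  # subject x cell matrix, cells ordered with the last factor varying fastest
  ord <- order(subj, cells)
  y <- matrix(data[[dv]][ord], nrow = n, byrow = TRUE)

  contr_orth <- function(k) {
    # orthonormal contrasts spanning the mean-zero subspace
    c0 <- stats::contr.helmert(k)
    qr.Q(qr(c0))
  }
  unit <- function(k) matrix(1 / sqrt(k), k, 1)

  effects <- unlist(lapply(seq_along(within), function(m) {
    utils::combn(seq_along(within), m, simplify = FALSE)
  }), recursive = FALSE)

  rows <- lapply(effects, function(idx) {
    K <- Reduce(kronecker, lapply(seq_along(within), function(j) {
      if (j %in% idx) contr_orth(lv[j]) else unit(lv[j])
    }))
    M <- y %*% K
    d1 <- prod(lv[idx] - 1L)
    mbar <- colMeans(M)
    ss_eff <- n * sum(mbar^2)
    ss_err <- sum(sweep(M, 2, mbar)^2)
    d2 <- (n - 1L) * d1
    Fv <- (ss_eff / d1) / (ss_err / d2)
    S <- stats::cov(M)
    eps <- if (d1 > 1) sum(diag(S))^2 / (d1 * sum(S^2)) else 1
    use_gg <- switch(gg_policy,
      auto = d1 > 1 && eps < 1,
      always = d1 > 1,
      never = FALSE
    )
    d1a <- if (use_gg) eps * d1 else d1
    d2a <- if (use_gg) eps * d2 else d2
    data.frame(
      effect = paste(within[idx], collapse = ":"),
      df1 = d1, df2 = d2, ss_effect = ss_eff, ss_error = ss_err,
      F = Fv, p = stats::pf(Fv, d1, d2, lower.tail = FALSE),
      epsilon = eps, df1_adj = d1a, df2_adj = d2a,
      p_adj = stats::pf(Fv, d1a, d2a, lower.tail = FALSE),
      pes = ss_eff / (ss_eff + ss_err),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  grand <- mean(y)
  attr(out, "ss_total") <- sum((y - grand)^2)
  attr(out, "ss_subject") <- ncol(y) * sum((rowMeans(y) - grand)^2)
  out
}

#' Repeated-measures correlation
#'
#' Common within-subject association between two measures, estimated by an
#' analysis-of-covariance decomposition with subject-specific intercepts and
#' a shared slope. `r_rm` is the signed square root of
#' SS_measure / (SS_measure + SS_error); df = N_obs - n_subjects - 1.
#'
#' @param x,y numeric vectors of paired observations
#' @param subject subject identifier, same length
#' @param z_score_within if `TRUE`, z-score `x` and `y` (grand
#'   standardization) before fitting; `r_rm` is invariant to this, it only
#'   changes the slope scale
#' @return list with `r_rm`, `df`, `p`, `slope`, `n_subjects`, `n_obs`
#' @export
rm_correlation <- function(x, y, subject, z_score_within = FALSE) {
  keep <- !(is.na(x) | is.na(y) | is.na(subject))
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  subject <- factor(subject[keep])
  cnt <- table(subject)
  if (any(cnt < 2)) {
    warning("dropping ", sum(cnt < 2), " subject(s) with < 2 observations")
    ok <- subject %in% names(cnt)[cnt >= 2]
    x <- x[ok]; y <- y[ok]; subject <- droplevels(subject[ok])
  }
  if (nlevels(subject) < 2) stop("need at least 2 subjects with >= 2 observations")
  if (z_score_within) {
    x <- as.numeric(scale(x)); y <- as.numeric(scale(y))
  }
  fit <- stats::lm(y ~ subject + x)
  an <- stats::anova(fit)
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- an["Residuals", "Df"]
  slope <- unname(stats::coef(fit)["x"])
  Fv <- (ss_x / 1) / (ss_err / df)
  list(
    r_rm = sign(slope) * sqrt(ss_x / (ss_x + ss_err)),
    df = df, p = stats::pf(Fv, 1, df, lower.tail = FALSE),
    slope = slope, n_subjects = nlevels(subject), n_obs = length(x)
  )
}

#' Meng-Rosenthal-Rubin z test for two dependent correlations
#'
#' Compares the correlations of two measures j and h with a shared third
#' variable k, observed on the same n cases, via Fisher-transformed
#' coefficients.
#'
#' @param r_jk,r_jh the two correlations being compared (shared variable j)
#' @param r_kh correlation between the two non-shared variables
#' @param n number of cases (> 3)
#' @return list with `z` and two-sided normal `p`
#' @export
meng_dependent_correlation_z <- function(r_jk, r_jh, r_kh, n) {
  if (n <= 3) stop("n must exceed 3")
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1)) stop("correlations must satisfy |r| < 1")
  zf <- function(r) atanh(r)
  r2bar <- (r_jk^2 + r_jh^2) / 2
  f <- min(1, (1 - r_kh) / (2 * (1 - r2bar)))
  h <- (1 - f * r2bar) / (1 - r2bar)
  z <- (zf(r_jk) - zf(r_jh)) * sqrt((n - 3) / (2 * (1 - r_kh) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pearson or Spearman correlation with two-sided p
#'
#' @param x,y numeric vectors, equal length >= 3
#' @param method `"pearson"` or `"spearman"`
#' @return list with `r`, `p`, `method`, `n`
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !(is.na(x) | is.na(y))
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("correlation undefined for constant input")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ht$estimate), p = ht$p.value, method = method, n = length(x))
}
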