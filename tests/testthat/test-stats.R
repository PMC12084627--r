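# Statistical layer: location tests, Holm correction, within-subject ANOVA
# with Greenhouse-Geisser, repeated-measures correlation, Meng z.

holm_by_hand <- function(p) {
  # step-down rule applied literally: sort, multiply by (m - i + 1),
  # enforce monotonicity, cap at 1, restore order
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

test_that("paired t test matches closed forms and degenerate inputs", {
  r0 <- paired_location_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$effect_size, 0)

  d <- c(1, 2, 3, 4, 5)
  r <- paired_location_test(d + 10, rep(10, 5))
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r$statistic, t_manual, tolerance = 1e-12)
  expect_equal(r$statistic, 4.242640687, tolerance = 1e-8)
  expect_equal(r$df, 4)
  expect_equal(r$effect_size, mean(d) / sd(d))
  expect_equal(r$mean_difference, 3)

  expect_error(paired_location_test(1:3, 1:4), "equal length")
})

test_that("wilcoxon branch uses the exact small-sample distribution", {
  # diffs +1 and -1: signed ranks tie exactly, two-sided exact p = 1
  # |diffs| tie at +1/-1; stats falls back from the exact distribution and
  # warns, but the two-sided p is exactly 1 either way
  r <- suppressWarnings(paired_location_test(c(2, 1), c(1, 2),
                                             method = "wilcoxon"))
  expect_equal(r$p, 1)
  # exhaustive enumeration oracle for n = 4: p = #{|sum of signed ranks|
  # >= observed} / 2^n over all sign assignments
  d <- c(0.3, 1.1, -0.4, 2.0)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 4))
  w_all <- as.matrix(signs) %*% rk
  mu <- sum(rk) / 2
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  r4 <- paired_location_test(d, rep(0, 4), method = "wilcoxon")
  expect_equal(r4$p, p_exact, tolerance = 1e-12)
  expect_error(paired_location_test(c(0, 0), c(0, 0), method = "wilcoxon"))
})

test_that("Holm adjustment matches the hand-applied step-down rule", {
  expect_equal(holm_sequential_bonferroni(0.03), 0.03)
  expect_equal(holm_sequential_bonferroni(c(0.01, 0.04, 0.03)),
               c(0.03, 0.06, 0.06))
  expect_equal(holm_sequential_bonferroni(rep(0.05, 3)), rep(0.15, 3))
  set.seed(4)
  for (k in 1:5) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sequential_bonferroni(p)
    expect_equal(adj, holm_by_hand(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
  expect_error(holm_sequential_bonferroni(c(0.2, 1.4)))
})

test_that("one-factor rm ANOVA reproduces aov and the paired-t identity", {
  set.seed(11)
  d <- expand.grid(participant = 1:6, condition = letters[1:3])
  d$value <- rnorm(18)
  r <- rm_anova(d, "value", "participant", "condition")
  a <- summary(aov(value ~ condition + Error(factor(participant) / condition),
                   d))[["Error: factor(participant):condition"]][[1]]
  expect_equal(r$ss_effect, a["condition", "Sum Sq"], tolerance = 1e-9)
  expect_equal(r$ss_error, a["Residuals", "Sum Sq"], tolerance = 1e-9)
  expect_equal(r$F, a["condition", "F value"], tolerance = 1e-9)
  expect_equal(r$p, a["condition", "Pr(>F)"], tolerance = 1e-9)

  d2 <- expand.grid(participant = 1:8, condition = c("a", "b"))
  d2$value <- rnorm(16)
  r2 <- rm_anova(d2, "value", "participant", "condition")
  tt <- paired_location_test(d2$value[d2$condition == "a"],
                             d2$value[d2$condition == "b"])
  expect_equal(r2$F, tt$statistic^2, tolerance = 1e-9)
  expect_equal(r2$epsilon, 1)
  expect_equal(r2$p_adj, r2$p)
})

test_that("multi-factor rm ANOVA conserves sums of squares and matches aov", {
  set.seed(12)
  d <- expand.grid(participant = 1:5, A = c("x", "y"), B = c("1", "2", "3"))
  d$value <- rnorm(30)
  r <- rm_anova(d, "value", "participant", c("A", "B"))
  a <- summary(aov(value ~ A * B + Error(factor(participant) / (A * B)), d))
  for (eff in c("A", "B", "A:B")) {
    stratum <- a[[paste0("Error: factor(participant):", eff)]][[1]]
    row <- r[r$effect == eff, ]
    expect_equal(row$ss_effect, stratum[1, "Sum Sq"], tolerance = 1e-9)
    expect_equal(row$ss_error, stratum["Residuals", "Sum Sq"], tolerance = 1e-9)
    expect_equal(row$F, stratum[1, "F value"], tolerance = 1e-9)
  }
  total <- attr(r, "ss_total")
  expect_equal(total, attr(r, "ss_subject") + sum(r$ss_effect + r$ss_error),
               tolerance = 1e-9)
  expect_true(all(r$pes >= 0 & r$pes <= 1))
  # 3-factor design decomposes into 7 effects and still conserves SS
  d3 <- expand.grid(participant = 1:4, A = c("x", "y"), B = c("1", "2"),
                    C = c("i", "ii", "iii"))
  d3$value <- rnorm(48)
  r3 <- rm_anova(d3, "value", "participant", c("A", "B", "C"))
  expect_equal(nrow(r3), 7)
  expect_equal(attr(r3, "ss_total"),
               attr(r3, "ss_subject") + sum(r3$ss_effect + r3$ss_error),
               tolerance = 1e-9)
  expect_error(rm_anova(d3[-1, ], "value", "participant", c("A", "B", "C")),
               "balanced")
})

test_that("rm correlation matches its structure and the frozen reference", {
  # exact within-subject identity
  x <- rep(1:5, 4); s <- rep(1:4, each = 5)
  y <- x + rep(c(10, 20, 30, 40), each = 5)
  r <- suppressWarnings(rm_correlation(x, y, s))
  expect_equal(r$r_rm, 1, tolerance = 1e-9)
  expect_equal(r$df, length(x) - 4 - 1)

  # between-subject association only: r_rm near zero
  set.seed(21)
  ns <- 20; no <- 10
  s2 <- rep(1:ns, each = no)
  off <- rnorm(ns, 0, 3)
  x2 <- rep(off, each = no) + rnorm(ns * no)
  y2 <- rep(off, each = no) + rnorm(ns * no)
  r2 <- rm_correlation(x2, y2, s2)
  expect_lt(abs(r2$r_rm), 0.1)

  # frozen reference values (independent implementation of the same
  # ANCOVA-based estimator)
  ref <- read.csv(test_path("rmcorr-reference.csv"))
  ds <- make_rmcorr_datasets()
  for (i in seq_along(ds)) {
    got <- rm_correlation(ds[[i]]$x, ds[[i]]$y, ds[[i]]$subject)
    expect_equal(got$r_rm, ref$r_rm[i], tolerance = 1e-6)
    expect_equal(got$df, ref$df[i])
    expect_equal(got$p, ref$p[i], tolerance = 1e-6)
  }
  expect_warning(rm_correlation(c(1, 2, 3, 1.5, 2.5, 3.5, 9),
                                c(2.2, 1.4, 4.1, 2.9, 3.4, 5.2, 4),
                                c(1, 1, 1, 2, 2, 2, 3)), "dropping")
})

test_that("Meng dependent-correlation z matches the frozen formula oracle", {
  r <- meng_dependent_correlation_z(0.5, 0.2, 0.3, 30)
  expect_equal(r$z, 1.4510551187822304, tolerance = 1e-10)
  expect_equal(r$p, 0.14676451261588952, tolerance = 1e-10)
  r2 <- meng_dependent_correlation_z(0.7, -0.1, 0.25, 40)
  expect_equal(r2$z, 4.4493216134058615, tolerance = 1e-10)
  expect_equal(r2$p, 8.6141942545909725e-06, tolerance = 1e-12)
  # symmetry / antisymmetry
  eq <- meng_dependent_correlation_z(0.4, 0.4, 0.2, 25)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  sw <- meng_dependent_correlation_z(0.2, 0.5, 0.3, 30)
  expect_equal(sw$z, -r$z, tolerance = 1e-12)
  expect_error(meng_dependent_correlation_z(1, 0.2, 0.1, 30))
  expect_error(meng_dependent_correlation_z(0.5, 0.2, 0.1, 3))
})

test_that("correlation wraps both coefficients with rank invariance", {
  x <- c(0.3, 1.2, 2.4, 3.1, 4.9, 6.2)
  expect_equal(correlation(x, 2 * x)$r, 1, tolerance = 1e-12)
  y <- exp(x)  # monotone nonlinear
  expect_equal(correlation(x, y, method = "spearman")$r, 1)
  expect_lt(correlation(x, y)$r, 1)
  # manual product-moment formula oracle
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlation(a, b)$r, r_manual, tolerance = 1e-12)
  expect_error(correlation(a, rep(1, 20)), "constant")
})
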