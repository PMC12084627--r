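# ERP epoching, windowed amplitudes, cluster-based permutation testing.

test_that("epoch building drops flagged epochs and zeroes the baseline", {
  set.seed(51)
  t_ms <- seq(-100, 796, by = 4)
  ep <- array(rnorm(10 * 3 * length(t_ms)), c(10, 3, length(t_ms))) + 3
  labels <- data.frame(condition = "up", sound = "target",
                       artifact = c(TRUE, TRUE, rep(FALSE, 8)),
                       behavior_ok = TRUE)
  es <- build_epochs(ep, t_ms, c("Cz", "Pz", "Fz"), labels)
  expect_equal(dim(es$epochs)[1], 8)
  expect_equal(unname(es$n_dropped["artifact"]), 2)
  bsel <- t_ms >= -100 & t_ms < 0
  bm <- apply(es$epochs[, , bsel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bm)), 1e-9)
  # a behaviorally invalid epoch is excluded even if artifact-free
  labels2 <- data.frame(artifact = FALSE,
                        behavior_ok = c(FALSE, rep(TRUE, 9)))
  es2 <- build_epochs(ep, t_ms, c("Cz", "Pz", "Fz"), labels2)
  expect_equal(dim(es2$epochs)[1], 9)
  expect_equal(unname(es2$n_dropped["behavior"]), 1)
  labels3 <- data.frame(artifact = TRUE, behavior_ok = TRUE)[rep(1, 10), ]
  expect_error(build_epochs(ep, t_ms, c("Cz", "Pz", "Fz"), labels3),
               "no epoch")
})

test_that("windowed mean amplitudes follow the half-open grid convention", {
  t_ms <- seq(-100, 796, by = 4)
  flat <- matrix(5, 2, length(t_ms))
  expect_equal(mean_amplitude(flat, t_ms, c("Cz", "Pz"), c(252, 600)), 5)
  # 10 uV on [300, 400): 25 of the 87 window samples
  w <- matrix(0, 1, length(t_ms))
  w[1, t_ms >= 300 & t_ms < 400] <- 10
  expect_equal(mean_amplitude(w, t_ms, "Cz", c(252, 600)), 10 * 25 / 87,
               tolerance = 1e-12)
  two <- rbind(matrix(4, 1, length(t_ms)), matrix(6, 1, length(t_ms)))
  expect_equal(mean_amplitude(two, t_ms, c("Cz", "Pz"), c(252, 600),
                              c("Cz", "Pz")), 5)
  arr <- array(0, c(3, 2, length(t_ms))); arr[2, , ] <- 1
  expect_equal(mean_amplitude(arr, t_ms, c("Cz", "Pz"), c(0, 100)),
               c(0, 1, 0))
  expect_error(mean_amplitude(flat, t_ms, c("Cz", "Pz"), c(252, 600),
                              "Oz"), "unknown channel")
})

test_that("identical conditions produce no clusters", {
  set.seed(52)
  adj <- channel_adjacency(standard_montage()[1:10, ])
  a <- array(rnorm(8 * 10 * 50), c(8, 10, 50))
  r <- cluster_permutation_test(a, a, adj, n_perm = 50, seed = 1)
  expect_length(r$clusters, 0)
})

test_that("an injected spatiotemporal effect is recovered where it was put", {
  set.seed(53)
  mont <- standard_montage()
  adj <- channel_adjacency(mont)
  n <- 12; nch <- nrow(mont); t_ms <- seq(-100, 796, by = 4)
  nt <- length(t_ms)
  a <- array(rnorm(n * nch * nt), c(n, nch, nt))
  b <- array(rnorm(n * nch * nt), c(n, nch, nt))
  hood <- c("Cz", "C1", "C2", "CPz", "FCz")
  mask_ch <- which(mont$channel %in% hood)
  mask_t <- which(t_ms >= 250 & t_ms < 450)
  a[, mask_ch, mask_t] <- a[, mask_ch, mask_t] + 3
  r <- cluster_permutation_test(a, b, adj, n_perm = 500, seed = 2)
  expect_gt(length(r$clusters), 0)
  top <- r$clusters[[1]]
  expect_lt(top$p, 0.05)
  expect_equal(top$sign, 1)
  hits <- top$members[, "channel"] %in% mask_ch &
    top$members[, "time"] %in% mask_t
  expect_gt(mean(hits), 0.5)
  inj <- length(mask_ch) * length(mask_t)
  expect_gt(sum(hits) / inj, 0.8)  # most of the injected region recovered
})

test_that("permutation p-values are invariant to channel relabeling", {
  set.seed(54)
  mont <- standard_montage()[1:12, ]
  adj <- channel_adjacency(mont)
  n <- 9; nch <- 12; nt <- 60
  a <- array(rnorm(n * nch * nt), c(n, nch, nt))
  b <- array(rnorm(n * nch * nt), c(n, nch, nt))
  a[, 3:5, 20:40] <- a[, 3:5, 20:40] + 1.5
  perm <- sample(nch)
  r1 <- cluster_permutation_test(a, b, adj, n_perm = 400, seed = 7)
  r2 <- cluster_permutation_test(a[, perm, ], b[, perm, ],
                                 adj[perm, perm], n_perm = 400, seed = 7)
  expect_equal(length(r1$clusters), length(r2$clusters))
  if (length(r1$clusters) > 0) {
    expect_equal(vapply(r1$clusters, `[[`, 1, "mass"),
                 vapply(r2$clusters, `[[`, 1, "mass"), tolerance = 1e-9)
    expect_equal(vapply(r1$clusters, `[[`, 1, "p"),
                 vapply(r2$clusters, `[[`, 1, "p"), tolerance = 1e-12)
  }
})

test_that("exhaustive and Monte-Carlo nulls agree at small n", {
  set.seed(55)
  mont <- standard_montage()[1:8, ]
  adj <- channel_adjacency(mont)
  n <- 9  # 2^9 = 512 assignments
  a <- array(rnorm(n * 8 * 40), c(n, 8, 40))
  b <- array(rnorm(n * 8 * 40), c(n, 8, 40))
  a[, 2:4, 10:30] <- a[, 2:4, 10:30] + 1.2
  rex <- cluster_permutation_test(a, b, adj, n_perm = 1000, seed = 3)
  expect_true(rex$exhaustive)
  expect_equal(rex$n_perm, 512)
  rmc <- cluster_permutation_test(a, b, adj, n_perm = 499, seed = 4)
  expect_false(rmc$exhaustive)
  if (length(rex$clusters) > 0) {
    expect_equal(rex$clusters[[1]]$p, rmc$clusters[[1]]$p,
                 tolerance = 2 / sqrt(499))
    expect_gte(rex$clusters[[1]]$p, 1 / 512)
  }
  expect_error(cluster_permutation_test(a[1, , , drop = FALSE],
                                        b[1, , , drop = FALSE], adj),
               "at least 2")
  expect_error(cluster_permutation_test(a, b[, 1:4, ], adj), "matching")
})

test_that("the compiled null statistic matches the plain-R clustering path", {
  set.seed(56)
  n <- 8; nch <- 10; nt <- 40
  adj <- channel_adjacency(standard_montage()[1:nch, ])
  al <- pupilarousal:::.adj_to_list(adj)
  D <- matrix(rnorm(n * nch * nt), n, nch * nt)
  S <- matrix(sample(c(1, -1), 30 * n, replace = TRUE), 30, n)
  cpp <- pupilarousal:::cluster_null_stats(D, S, 1.8, nt, nch, al)
  Dt <- t(D)
  ssq <- rowSums(Dt^2)
  ours <- vapply(1:30, function(p) {
    M <- Dt %*% S[p, ]
    tv <- M * sqrt((n - 1) / n) / sqrt(pmax(ssq - M^2 / n, 1e-12))
    pupilarousal:::.max_cluster_mass(as.numeric(tv), nt, nch, 1.8, al)
  }, 1)
  expect_equal(as.numeric(cpp), ours, tolerance = 1e-10)
})

test_that("montage adjacency is symmetric with moderate neighbor counts", {
  mont <- standard_montage()
  expect_equal(nrow(mont), 64)
  expect_true(all(p300_channel_set() %in% mont$channel))
  adj <- channel_adjacency(mont)
  expect_true(isSymmetric(adj))
  expect_true(all(!diag(adj)))
  deg <- rowSums(adj)
  expect_gte(median(deg), 4)
  expect_lte(median(deg), 8)
})
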