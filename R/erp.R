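#' @title ERP epoching and spatiotemporal cluster-based permutation tests
#' @description Epoch bookkeeping (artifact and behavioral exclusion,
#'   baseline correction), participant-level condition averages, windowed
#'   mean amplitudes (P300, N100), and a paired spatiotemporal cluster-based
#'   permutation test: point-wise paired t statistics are thresholded,
#'   suprathreshold points are grouped into clusters that are contiguous in
#'   time and across neighboring channels, cluster mass is the sum of member
#'   t values, and significance comes from the max-|mass| distribution over
#'   sign-flip permutations of the participant difference maps (family-wise
#'   error controlling, two-sided).
#' @name erp
NULL

#' Build a baseline-corrected epoch set
#'
#' Drops artifact-flagged epochs and epochs with an invalid behavioral
#' response (false alarm, miss), then subtracts the per-channel mean over
#' the baseline window from every epoch.
#'
#' @param epochs array (epoch x channel x time, uV)
#' @param t_ms epoch time axis (ms)
#' @param channels channel names
#' @param labels data.frame with one row per epoch; optional columns
#'   `artifact` (logical) and `behavior_ok` (logical) drive exclusions;
#'   remaining columns (condition, sound, ...) are carried along
#' @param baseline_ms baseline window (default -100 to 0 ms)
#' @return list of class `erp_epochs` with `epochs`, `t_ms`, `channels`,
#'   `labels`, `n_dropped` (named count by reason)
#' @export
build_epochs <- function(epochs, t_ms, channels, labels,
                         baseline_ms = c(-100, 0)) {
  stopifnot(dim(epochs)[1] == nrow(labels), dim(epochs)[3] == length(t_ms))
  art <- if ("artifact" %in% names(labels)) labels$artifact else rep(FALSE, nrow(labels))
  beh <- if ("behavior_ok" %in% names(labels)) !labels$behavior_ok else rep(FALSE, nrow(labels))
  drop <- art | beh
  if (all(drop)) stop("no epoch survives artifact/behavioral exclusion")
  keep <- which(!drop)
  ep <- epochs[keep, , , drop = FALSE]
  bsel <- t_ms >= baseline_ms[1] & t_ms < baseline_ms[2]
  if (!any(bsel)) stop("baseline window lies outside the epoch")
  bmean <- apply(ep[, , bsel, drop = FALSE], c(1, 2), mean)
  ep <- ep - as.vector(bmean)  # recycles over the time dimension
  structure(
    list(epochs = ep, t_ms = t_ms, channels = channels,
         labels = labels[keep, , drop = FALSE],
         n_dropped = c(artifact = sum(art), behavior = sum(beh & !art))),
    class = "erp_epochs"
  )
}

#' Average an epoch set into one ERP
#'
#' @param eset an `erp_epochs` set
#' @param which logical or integer selector over epochs (default: all)
#' @return matrix channel x time (uV)
#' @export
average_erp <- function(eset, which = NULL) {
  ep <- eset$epochs
  if (!is.null(which)) ep <- ep[which, , , drop = FALSE]
  if (dim(ep)[1] == 0) stop("no epochs to average")
  apply(ep, c(2, 3), mean)
}

#' Windowed mean ERP amplitude
#'
#' Mean amplitude over a time window and a named channel subset of
#' participant-level ERPs. Windows are half-open `[from, to)` on the sample
#' grid.
#'
#' @param erps matrix (channel x time) or array (participant x channel x
#'   time)
#' @param t_ms time axis
#' @param channels channel names matching the channel dimension
#' @param window_ms length-2 window in ms (e.g. `c(252, 600)`)
#' @param use_channels channel subset (default: all)
#' @return scalar, or vector per participant
#' @export
mean_amplitude <- function(erps, t_ms, channels, window_ms,
                           use_channels = NULL) {
  if (is.null(use_channels)) use_channels <- channels
  missing_ch <- setdiff(use_channels, channels)
  if (length(missing_ch) > 0) {
    stop("unknown channel(s): ", paste(missing_ch, collapse = ", "))
  }
  tsel <- t_ms >= window_ms[1] & t_ms < window_ms[2]
  if (!any(tsel)) stop("window lies outside the epoch span")
  csel <- channels %in% use_channels
  if (is.matrix(erps)) {
    mean(erps[csel, tsel])
  } else {
    apply(erps[, csel, tsel, drop = FALSE], 1, mean)
  }
}

# --- clustering machinery ----------------------------------------------

# Find clusters in a t map laid out as one vector with time fastest within
# channel (column index = t + (ch-1)*nt). Returns masses and, optionally,
# member indices.
.find_clusters <- function(tvec, nt, nch, thr, adj_list, members = FALSE) {
  res <- list()
  for (sgn in c(1, -1)) {
    v <- which(sgn * tvec > thr)
    if (length(v) == 0) next
    br <- if (length(v) == 1) TRUE else
      c(TRUE, diff(v) != 1L | ((v[-1] - 1L) %% nt == 0L))
    run_id <- cumsum(br)
    n_runs <- run_id[length(run_id)]
    starts <- v[br]
    lens <- tabulate(run_id, n_runs)
    r_ch <- (starts - 1L) %/% nt + 1L
    r_t0 <- (starts - 1L) %% nt + 1L
    r_t1 <- r_t0 + lens - 1L
    r_mass <- as.numeric(rowsum(tvec[v], run_id))
    # union-find over runs
    parent <- seq_len(n_runs)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    runs_by_ch <- split(seq_len(n_runs), r_ch)
    for (c1 in as.integer(names(runs_by_ch))) {
      for (c2 in adj_list[[c1]]) {
        if (c2 <= c1) next
        j2 <- runs_by_ch[[as.character(c2)]]
        if (is.null(j2)) next
        for (i in runs_by_ch[[as.character(c1)]]) {
          ov <- j2[r_t0[j2] <= r_t1[i] & r_t0[i] <= r_t1[j2]]
          for (j in ov) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
    roots <- vapply(seq_len(n_runs), find, 1L)
    cl_mass <- as.numeric(rowsum(r_mass, roots))
    cl_ids <- sort(unique(roots))
    for (k in seq_along(cl_ids)) {
      cl <- list(mass = cl_mass[k], sign = sgn)
      if (members) {
        rr <- which(roots == cl_ids[k])
        cl$members <- unlist(lapply(rr, function(i) {
          (r_ch[i] - 1L) * nt + (r_t0[i]:r_t1[i])
        }))
      }
      res[[length(res) + 1]] <- cl
    }
  }
  res
}

.adj_to_list <- function(adjacency) {
  lapply(seq_len(nrow(adjacency)), function(i) which(adjacency[i, ]))
}

# Lean path for the permutation null: maximum absolute cluster mass of one
# t map. Runs of suprathreshold points per channel are merged across
# neighboring channels with a two-pointer interval sweep over a union-find.
.max_cluster_mass <- function(tvec, nt, nch, thr, adj_list) {
  best <- 0
  for (sgn in c(1, -1)) {
    v <- which(sgn * tvec > thr)
    nv <- length(v)
    if (nv == 0) next
    br <- if (nv == 1) TRUE else c(TRUE, diff(v) != 1L | ((v[-1] - 1L) %% nt == 0L))
    starts_i <- which(br)
    ends_i <- c(starts_i[-1] - 1L, nv)
    cs <- cumsum(tvec[v])
    r_mass <- cs[ends_i] - c(0, cs[ends_i[-length(ends_i)]])
    r_ch <- (v[starts_i] - 1L) %/% nt + 1L
    r_t0 <- (v[starts_i] - 1L) %% nt + 1L
    r_t1 <- r_t0 + (ends_i - starts_i)
    n_runs <- length(starts_i)
    if (n_runs == 1) {
      best <- max(best, abs(r_mass))
      next
    }
    # runs are sorted by channel then time; per-channel contiguous blocks
    first_run <- integer(nch); last_run <- integer(nch)
    for (i in seq_len(n_runs)) {
      ch <- r_ch[i]
      if (first_run[ch] == 0L) first_run[ch] <- i
      last_run[ch] <- i
    }
    parent <- seq_len(n_runs)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (c1 in unique(r_ch)) {
      for (c2 in adj_list[[c1]]) {
        if (c2 <= c1 || first_run[c2] == 0L) next
        i <- first_run[c1]; j <- first_run[c2]
        while (i <= last_run[c1] && j <= last_run[c2]) {
          if (r_t1[i] < r_t0[j]) { i <- i + 1L }
          else if (r_t1[j] < r_t0[i]) { j <- j + 1L }
          else {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
            if (r_t1[i] <= r_t1[j]) i <- i + 1L else j <- j + 1L
          }
        }
      }
    }
    roots <- vapply(seq_len(n_runs), find, 1L)
    best <- max(best, abs(rowsum(r_mass, roots)))
  }
  best
}

.sign_matrix <- function(n, n_perm) {
  if (2^n <= n_perm) {
    # full enumeration (includes the identity assignment)
    m <- matrix(0L, 2^n, n)
    for (j in seq_len(n)) {
      m[, j] <- rep(rep(c(1L, -1L), each = 2^(n - j)), length.out = 2^n)
    }
    list(S = m, exhaustive = TRUE)
  } else {
    S <- matrix(sample(c(1, -1), n * n_perm, replace = TRUE), n_perm, n)
    list(S = S, exhaustive = FALSE)
  }
}

#' Paired spatiotemporal cluster-based permutation test
#'
#' Tests two paired conditions of participant-level channel x time maps.
#' The null distribution is the maximum absolute cluster mass over sign-flip
#' permutations of the participant difference maps: full enumeration of the
#' 2^n assignments when that count does not exceed `n_perm`, otherwise
#' `n_perm` Monte-Carlo draws. The observed assignment is counted in its own
#' null, so p > 0 always. Positive and negative clusters are formed
#' separately and compared against the shared max-|mass| null (two-sided,
#' family-wise error controlling).
#'
#' @param a,b arrays (participant x channel x time), paired by participant
#' @param adjacency logical channel adjacency matrix (see
#'   [channel_adjacency()])
#' @param n_perm number of permutations (default 5000)
#' @param alpha significance level annotated on the result
#' @param threshold cluster-forming t threshold; default is the two-sided
#'   point-wise t critical value at p = 0.05 with n - 1 df
#' @param seed optional seed for the Monte-Carlo draws
#' @return list of class `cluster_result`: `clusters` (list with `mass`,
#'   `sign`, `p`, `members` as (channel, time) index matrix), `threshold`,
#'   `n_perm` (draws actually used), `exhaustive`, `alpha`, `max_null`
#' @export
cluster_permutation_test <- function(a, b, adjacency, n_perm = 5000,
                                     alpha = 0.05, threshold = NULL,
                                     seed = NULL) {
  da <- dim(a)
  if (!identical(da, dim(b))) stop("condition arrays must have matching dimensions")
  n <- da[1]; nch <- da[2]; nt <- da[3]
  if (n < 2) stop("need at least 2 participants")
  if (nrow(adjacency) != nch) stop("adjacency does not cover all channels")
  if (is.null(threshold)) threshold <- stats::qt(0.975, n - 1)
  adj_list <- .adj_to_list(adjacency)
  Dt <- t(matrix(aperm(a - b, c(1, 3, 2)), n, nt * nch))  # npts x n
  ssq <- rowSums(Dt^2)
  tscale <- sqrt((n - 1) / n)

  # t maps for a batch of sign assignments, one column per assignment
  t_from_signs <- function(S) {
    M <- Dt %*% t(S)  # npts x P matrix of sums; ssq recycles down columns
    M * tscale / sqrt(pmax(ssq - M^2 / n, 1e-12))
  }

  t_obs <- as.numeric(t_from_signs(matrix(1, 1, n)))
  obs <- .find_clusters(t_obs, nt, nch, threshold, adj_list, members = TRUE)

  run <- function() {
    sm <- .sign_matrix(n, n_perm)
    null_max <- cluster_null_stats(t(Dt), sm$S, threshold, nt, nch, adj_list)
    list(null_max = null_max, exhaustive = sm$exhaustive, P = nrow(sm$S))
  }
  nl <- if (is.null(seed)) run() else with_seed(seed, run())

  clusters <- lapply(obs, function(cl) {
    m <- abs(cl$mass)
    p <- if (nl$exhaustive) {
      mean(nl$null_max >= m - 1e-12)
    } else {
      (1 + sum(nl$null_max >= m - 1e-12)) / (nl$P + 1)
    }
    idx <- cl$members
    cl$members <- cbind(channel = (idx - 1L) %/% nt + 1L,
                        time = (idx - 1L) %% nt + 1L)
    cl$p <- p
    cl
  })
  ord <- order(vapply(clusters, function(cl) -abs(cl$mass), 1))
  structure(
    list(clusters = clusters[ord], threshold = threshold,
         n_perm = nl$P, exhaustive = nl$exhaustive, alpha = alpha,
         max_null = nl$null_max),
    class = "cluster_result"
  )
}
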