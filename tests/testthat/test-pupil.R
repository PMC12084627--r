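# Offline pupil preprocessing, baseline correction, modulation indices.

make_raw <- function(mm, fs = 60, mod_start_ms = 4000) {
  n <- length(mm)
  df <- data.frame(t_ms = (0:(n - 1)) / fs * 1000,
                   left_mm = mm, right_mm = mm,
                   valid_left = !is.na(mm), valid_right = !is.na(mm))
  attr(df, "modulation_start_ms") <- mod_start_ms
  df
}

test_that("clean constant traces are a fixed point of the pipeline", {
  raw <- make_raw(rep(3, 1140))
  out <- preprocess_pupil(raw)
  expect_lt(max(abs(out$mm - 3), na.rm = TRUE), 0.001)
  expect_equal(out$missing_fraction, 0)
  expect_false(out$rejected)
  expect_equal(median(diff(out$t_ms)), 1)  # 1000 Hz grid
})

test_that("single spikes are removed and interpolated away", {
  mm <- rep(3, 1140); mm[300] <- 8
  out <- preprocess_pupil(make_raw(mm))
  # oracle: the speed rule flags the spike, linear interpolation restores 3
  expect_lt(max(abs(out$mm - 3), na.rm = TRUE), 0.01)
})

test_that("trials with a missing-data majority are rejected", {
  mm <- rep(3, 1000); mm[1:600] <- NA
  out <- preprocess_pupil(make_raw(mm))
  expect_true(out$rejected)
  expect_equal(out$missing_fraction, 0.6, tolerance = 0.01)
  out2 <- preprocess_pupil(make_raw(rep(NA_real_, 100)))
  expect_true(out2$rejected)
  expect_equal(out2$missing_fraction, 1)
  empty <- data.frame(t_ms = numeric(0), left_mm = numeric(0),
                      right_mm = numeric(0), valid_left = logical(0),
                      valid_right = logical(0))
  expect_error(preprocess_pupil(empty), "empty")
})

test_that("missing fraction is computed before interpolation", {
  mm <- rep(3, 1200)
  mm[200:230] <- NA  # a 31-sample gap (~500 ms), below the interp limit
  out <- preprocess_pupil(make_raw(mm))
  expect_equal(out$missing_fraction, 31 / 1200, tolerance = 1e-9)
  # the gap itself is interpolated on the output grid
  gap_t <- c(200, 230) / 60 * 1000
  sel <- out$t_ms > gap_t[1] & out$t_ms < gap_t[2]
  expect_true(all(!is.na(out$mm[sel])))
})

test_that("preprocessing is idempotent on artifact-free in-band traces", {
  # idempotence holds for signal content inside the 4 Hz passband; the
  # smoothing stage is (by design) not idempotent on broadband sensor noise
  t_ms <- (0:1139) / 60 * 1000
  mm <- 3 + 0.3 * sin(2 * pi * 0.2 * t_ms / 1000)
  tr <- data.frame(t_ms = t_ms, left_mm = mm, right_mm = mm,
                   valid_left = TRUE, valid_right = TRUE)
  attr(tr, "modulation_start_ms") <- 4000
  once <- preprocess_pupil(tr)
  again_raw <- data.frame(t_ms = once$t_ms, left_mm = once$mm,
                          right_mm = once$mm,
                          valid_left = !is.na(once$mm),
                          valid_right = !is.na(once$mm))
  attr(again_raw, "modulation_start_ms") <- once$modulation_start_ms
  twice <- preprocess_pupil(again_raw)
  # compare away from the trace edges, where reflection padding only
  # approximates the continuation of the signal
  ok <- !is.na(once$mm) & !is.na(twice$mm) &
    once$t_ms > 1000 & once$t_ms < max(once$t_ms) - 1000
  expect_gt(mean(ok), 0.85)
  expect_lt(max(abs(once$mm[ok] - twice$mm[ok])), 1e-6)
})

test_that("baseline correction subtracts the last-second mean", {
  out <- preprocess_pupil(make_raw(c(rep(3.2, 240), rep(3.5, 900))))
  bc <- baseline_correct(out)
  expect_equal(bc$baseline_mean_mm, 3.2, tolerance = 0.01)
  mid <- modulation_samples(bc, 14000)
  expect_lt(abs(mean(mid[3000:14000], na.rm = TRUE) - 0.3), 0.02)
  # modulation equal to baseline maps to zero
  flat <- baseline_correct(preprocess_pupil(make_raw(rep(3.0, 1140))))
  expect_lt(max(abs(modulation_samples(flat)), na.rm = TRUE), 0.002)
  # a 4-s baseline whose last second averages 3.0 (earlier 3.4):
  # the subtractor is the last-second mean, not the whole-baseline mean
  mm <- c(rep(3.4, 180), rep(3.0, 60), rep(3.6, 900))
  bc2 <- baseline_correct(preprocess_pupil(make_raw(mm)))
  expect_equal(bc2$baseline_mean_mm, 3.0, tolerance = 0.05)
  expect_error(baseline_correct(preprocess_pupil(make_raw(rep(3, 100))),
                                modulation_start_ms = 1e6), "outside")
})

test_that("the pupil modulation index averages the up-down difference", {
  fake_trace <- function(val, n_ms = 16000, mod_start = 1000) {
    structure(list(t_ms = 0:(n_ms - 1), mm = rep(val, n_ms),
                   missing_fraction = 0, rejected = FALSE,
                   modulation_start_ms = mod_start),
              class = "clean_pupil")
  }
  idx <- pupil_modulation_index(list(fake_trace(0.3)), list(fake_trace(-0.2)))
  expect_equal(idx$scalar, 0.5, tolerance = 1e-12)
  expect_length(idx$timeseries, 15000)
  idx0 <- pupil_modulation_index(list(fake_trace(0.1)), list(fake_trace(0.1)))
  expect_equal(idx0$scalar, 0)
  # linear ramps: up 0 -> 0.4, down 0 -> -0.2 over 15 s; the difference ramp
  # 0 -> 0.6 averages to 0.3
  ramp_trace <- function(a) {
    v <- c(rep(0, 1000), seq(0, a, length.out = 15000))
    structure(list(t_ms = 0:(length(v) - 1), mm = v, missing_fraction = 0,
                   rejected = FALSE, modulation_start_ms = 1000),
              class = "clean_pupil")
  }
  idxr <- pupil_modulation_index(list(ramp_trace(0.4)), list(ramp_trace(-0.2)))
  expect_equal(idxr$scalar, 0.3, tolerance = 1e-3)
  expect_error(pupil_modulation_index(list(), list(fake_trace(1))), "accepted")
})

test_that("pre-pulse averages cover exactly the 150 ms window", {
  tr <- structure(list(t_ms = 0:9999, mm = rep(0.2, 10000),
                       missing_fraction = 0, rejected = FALSE,
                       modulation_start_ms = 0), class = "clean_pupil")
  expect_equal(pre_pulse_pupil(tr, 5000), 0.2, tolerance = 1e-12)
  # step from 0 to 0.4 at 3.4 s, pulse at 3.5 s: mean over (3.35, 3.5] is
  # (0.05 * 0 + 0.10 * 0.4) / 0.15
  tr2 <- tr; tr2$mm <- ifelse(tr$t_ms >= 3400, 0.4, 0)
  # discrete-grid oracle: of the 150 samples in (3350, 3500], the 101 with
  # t >= 3400 carry 0.4; the continuous-time value is (0.05*0 + 0.10*0.4)/0.15
  expect_equal(pre_pulse_pupil(tr2, 3500), 0.4 * 101 / 150, tolerance = 1e-12)
  expect_lt(abs(pre_pulse_pupil(tr2, 3500) - (0.05 * 0 + 0.10 * 0.4) / 0.15),
            0.01)
  tr3 <- tr; tr3$mm[tr$t_ms > 4850] <- NA
  expect_true(is.na(pre_pulse_pupil(tr3, 5000)))
  expect_error(pre_pulse_pupil(tr, -500), "outside")
})

test_that("the modulation index recovers the generated condition deltas", {
  mk <- function(delta, seeds) {
    lapply(seeds, function(s) {
      tr <- simulate_pupil_trial(3.5, delta, baseline_s = 3, seed = s)
      cl <- preprocess_pupil(tr)
      if (cl$rejected) return(NULL)
      cl <- baseline_correct(cl)
      if (cl$rejected) NULL else cl
    })
  }
  up <- Filter(Negate(is.null), mk(0.25, 1:30))
  down <- Filter(Negate(is.null), mk(-0.25, 101:130))
  idx <- pupil_modulation_index(up, down)
  expect_equal(idx$scalar, 0.5, tolerance = 0.05)
})
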