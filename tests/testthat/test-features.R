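test_that("common_average_reference removes the cross-electrode mean and is idempotent", {
  set.seed(1)
  v <- matrix(rnorm(12), 4, 3)
  raw <- raw_recording(v, 1000, c("midPrCG", "PoCG", "other"))
  out <- common_average_reference(raw)
  expect_equal(rowMeans(out$voltage), rep(0, 4), tolerance = 1e-12)
  # constant across electrodes -> all zero
  rawc <- raw_recording(matrix(5, 4, 3), 1000, rep("other", 3))
  expect_equal(unname(common_average_reference(rawc)$voltage),
               matrix(0, 4, 3))
  # zero-mean input unchanged
  x <- rnorm(4)
  raw2 <- raw_recording(cbind(x, -x), 1000, rep("other", 2))
  expect_equal(common_average_reference(raw2)$voltage, raw2$voltage)
  # idempotent
  expect_equal(common_average_reference(out)$voltage, out$voltage)
  expect_error(common_average_reference(
    raw_recording(matrix(1, 4, 1), 1000, "other")), "single electrode")
})

test_that("raw_recording validates its invariants", {
  expect_error(raw_recording(matrix(c(1, NA), 2, 1), 1000, "other"), "NaN")
  expect_error(raw_recording(matrix(1, 4, 1), 399, "other"), "400")
  expect_error(raw_recording(matrix(1, 4, 2), 1000, "other"), "length")
  expect_error(raw_recording(matrix(1, 4, 1), 1000, "cerebellum"), "region")
})

test_that("extract_feature_streams matches the brute-force envelope oracle on tones", {
  fs <- 1000
  t <- seq(1 / fs, 5, by = 1 / fs)
  v <- cbind(2 * sin(2 * pi * 100 * t), 1.5 * sin(2 * pi * 8 * t))
  raw <- raw_recording(v, fs, c("midPrCG", "temporal"))
  st <- extract_feature_streams(raw)
  n <- nrow(st$hga)
  expect_equal(n, round(5 * 200))
  mid <- round(n * 0.3):round(n * 0.7)
  # 100 Hz tone: HGA ~ amplitude, within 1% RMS of the oracle
  env <- ecodec:::resample_to(oracle_envelope(v[, 1], fs, 70, 150), fs)
  rel <- sqrt(mean((st$hga[mid, 1] - env[mid])^2)) / sqrt(mean(env[mid]^2))
  expect_lt(rel, 0.01)
  expect_equal(mean(st$hga[mid, 1]), 2, tolerance = 0.02)
  # 8 Hz tone: HGA ~ 0, LFS keeps the 8 Hz component (rms = 1.5/sqrt(2))
  expect_lt(mean(st$hga[mid, 2]), 0.01)
  expect_equal(sd(st$lfs[mid, 2]), 1.5 / sqrt(2), tolerance = 0.02)
  # DC-only input: both bands ~ 0 after the transient
  rawdc <- raw_recording(matrix(3, 5000, 1), fs, "other")
  stdc <- extract_feature_streams(rawdc)
  expect_lt(max(abs(stdc$hga[mid, 1])), 0.02)
  expect_lt(max(abs(stdc$lfs[mid, 1])), 0.02)
  expect_error(extract_feature_streams(
    raw_recording(matrix(rnorm(300), , 1), 1000, "other")), "1 s")
})

test_that("sliding_zscore has unit steady-state moments and handles degenerate input", {
  set.seed(2)
  x <- matrix(rnorm(1e4, mean = 5, sd = 2), ncol = 1)
  z <- sliding_zscore(x, window_s = 30, fs = 200)
  steady <- 7000:10000
  expect_lt(abs(mean(z[steady, 1])), 0.05)
  expect_gt(sd(z[steady, 1]), 0.9)
  expect_lt(sd(z[steady, 1]), 1.1)
  # constant channel -> 0 everywhere (std floor)
  expect_equal(sliding_zscore(matrix(4, 100, 1), fs = 200),
               matrix(0, 100, 1))
  # step from 0 to 10 decays back toward 0 within one window length
  step <- matrix(c(rnorm(8000, 0, 1), rnorm(6000, 10, 1)), ncol = 1)
  zs <- sliding_zscore(step, window_s = 30, fs = 200)
  expect_gt(zs[8005, 1], 3)                  # right after the step
  expect_lt(abs(mean(zs[13800:14000, 1])), 0.5)  # one window later
})

test_that("trial_zscore normalizes to the baseline window", {
  set.seed(3)
  trial <- matrix(rnorm(400, 0, 1), 200, 2)
  base <- 1:50
  out <- trial_zscore(trial, base)
  expect_equal(colMeans(out[base, ]), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(out[base, ], 2, sd), c(1, 1), tolerance = 1e-12)
  # post-segment at baseline mean + 2 sd maps to z ~ 2
  mu <- mean(trial[base, 1])
  s <- sd(trial[base, 1])
  trial2 <- trial
  trial2[150:200, 1] <- mu + 2 * s
  out2 <- trial_zscore(trial2, base)
  expect_equal(mean(out2[150:200, 1]), 2, tolerance = 1e-9)
  expect_error(trial_zscore(trial, integer(0)), "empty")
  bad <- trial
  bad[, 2] <- 7
  expect_error(trial_zscore(bad, base), "channel\\(s\\): 2")
})

test_that("artifact_scan flags exactly the sustained variance-suppression trials", {
  set.seed(4)
  fs <- 200
  n <- 60 * fs
  hga <- matrix(rnorm(n * 4), n, 4)
  trials <- data.frame(trial = 1:4,
                       start = c(10, 22, 34, 46),
                       end = c(13, 25, 37, 49))
  rep0 <- artifact_scan(hga, trials, fs = fs)
  expect_gt(min(rep0$metric, na.rm = TRUE), 0.6)
  expect_length(rep0$flagged_trials, 0)
  # sustained suppression spanning trial 2 (12 s, enough to pull the 15 s
  # rolling std below 0.6) is flagged; a brief 0.4 s dip in trial 3 is not
  hga2 <- hga
  i2 <- (17 * fs):(29 * fs)
  hga2[i2, ] <- hga2[i2, ] * 0.2
  i3 <- (35 * fs):(35.4 * fs)
  hga2[i3, ] <- hga2[i3, ] * 0.2
  rep2 <- artifact_scan(hga2, trials, cutoff = 0.6, run_s = 1, fs = fs)
  expect_equal(rep2$flagged_trials, 2)
  # all-constant recording: metric 0, everything flagged
  repc <- artifact_scan(matrix(1, n, 4), trials, fs = fs)
  expect_equal(max(repc$metric, na.rm = TRUE), 0)
  expect_equal(repc$flagged_trials, 1:4)
  expect_error(artifact_scan(hga[1:(10 * fs), ], trials, fs = fs), "15 s")
})
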