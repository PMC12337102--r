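mk_speech_trial <- function(trial, pres, go, end, onset = go + 0.2,
                            offset = onset + 1.5) {
  data.frame(trial = trial, task = "speech", condition = "isolated", word = 1,
             presentation = pres, go_cue = go, onset = onset, offset = offset,
             start = pres, end = end, block = 1L)
}

test_that("detection labels follow the per-scheme rules", {
  fs <- 200
  tr <- mk_speech_trial(1, pres = 3, go = 5, end = 9)
  lab <- build_detection_labels(tr, n_time = 12 * fs, scheme = "fixed")
  t_of <- function(i) (i - 1) / fs
  idx_prep <- which(lab$labels == 2L)
  expect_equal(t_of(min(idx_prep)), 3, tolerance = 0.01)
  idx_sp <- which(lab$labels == 3L)
  # speech spans [5.0, 7.75) under the fixed 2.75 s scheme
  expect_equal(t_of(min(idx_sp)), 5, tolerance = 0.01)
  expect_equal(t_of(max(idx_sp)), 7.75, tolerance = 0.01)
  # ambiguous tail masked out
  expect_false(any(lab$mask[round(8 * fs):round(8.9 * fs)]))
  # 85% scheme on a 4 s post-cue trial: extent 3.4 s
  lab2 <- build_detection_labels(tr, n_time = 12 * fs, scheme = "fraction")
  expect_equal(t_of(max(which(lab2$labels == 3L))), 5 + 0.85 * 4,
               tolerance = 0.01)
  # rest block: all silence, fully unmasked
  lab3 <- build_detection_labels(tr[0, ], n_time = 100)
  expect_true(all(lab3$labels == 1L))
  expect_true(all(lab3$mask))
  # overlapping trials error
  tr2 <- rbind(tr, mk_speech_trial(2, pres = 8, go = 10, end = 14))
  expect_error(build_detection_labels(tr2, n_time = 4000), "non-overlapping")
})

test_that("extract_events implements the probability/time-threshold state machine", {
  fs <- 200
  b <- rep(0, 8 * fs)
  b[(2 * fs + 1):(5 * fs + 1)] <- 1  # b = 1 exactly on [2.0, 5.0] s
  cfg <- detector_postprocess_config(smooth_width = 1, theta_p = 0.5,
                                     t_on = 100, t_off = 100)
  ev <- extract_events(b, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 2.0)
  expect_equal(ev$onset_recognized_at, 2.5)
  expect_equal(ev$offset, 5.0)
  expect_equal(ev$offset_recognized_at, 5.5)
  # a 0.3 s run produces no event
  b2 <- rep(0, 2000)
  b2[501:560] <- 1
  expect_equal(nrow(extract_events(b2, cfg)), 0)
  # t_on longer than the trace: no events, no error
  expect_equal(nrow(extract_events(rep(1, 50), cfg)), 0)
})

test_that("extract_events equals the run-length oracle exhaustively and on random traces", {
  cfg <- detector_postprocess_config(smooth_width = 1, theta_p = 0.5,
                                     t_on = 3, t_off = 2)
  agree <- function(bits, cfg, t_on, t_off) {
    got <- extract_events(bits, cfg)
    want <- oracle_extract(bits, t_on, t_off)
    isTRUE(all.equal(got$onset, want$onset)) &&
      isTRUE(all.equal(got$offset, want$offset))
  }
  # exhaustive over all binary traces up to length 12
  ok <- TRUE
  for (len in 1:12) {
    for (v in 0:(2^len - 1)) {
      bits <- as.integer(intToBits(v)[1:len])
      ok <- ok && agree(bits, cfg, 3, 2)
    }
  }
  expect_true(ok)
  # sampled longer traces (13..20) and 100 random length-2000 traces
  set.seed(42)
  ok2 <- TRUE
  for (len in 13:20) for (k in 1:100)
    ok2 <- ok2 && agree(rbinom(len, 1, 0.5), cfg, 3, 2)
  expect_true(ok2)
  cfg2 <- detector_postprocess_config(smooth_width = 1, theta_p = 0.5,
                                      t_on = 100, t_off = 100)
  ok3 <- TRUE
  for (k in 1:100) {
    bits <- rbinom(2000, 1, 0.5)
    # embed a few long runs so events actually occur
    bits[300:550] <- 1
    bits[sample(1500, 1) + 0:200] <- 1
    ok3 <- ok3 && agree(bits, cfg2, 100, 100)
  }
  expect_true(ok3)
})

test_that("raising theta_p never increases event count on unimodal bump traces", {
  set.seed(7)
  fs <- 200
  for (k in 1:20) {
    p <- rep(0.05, 30 * fs)
    n_b <- sample(1:4, 1)
    centers <- sort(sample(seq(3, 27, by = 3), n_b))
    for (cc in centers) {
      t <- seq_along(p) / fs
      p <- p + runif(1, 0.4, 0.9) * exp(-(t - cc)^2 / (2 * runif(1, 0.3, 0.8)^2))
    }
    p <- pmin(p, 0.99)
    cnt <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(th)
      nrow(extract_events(p, detector_postprocess_config(theta_p = th))),
      numeric(1))
    expect_true(all(diff(cnt) <= 0))
  }
})

test_that("trained detector streams causal, normalized probabilities", {
  fxd <- fx_detector()
  m <- fxd$model
  s <- fxd$session
  p <- stream_probabilities(m, s)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
  # causality: truncating the input leaves earlier outputs unchanged
  feats <- session_features(s)
  p2 <- stream_probabilities(m, feats[1:2000, ])
  expect_equal(p[1:2000, ], p2, tolerance = 1e-10)
  # feature-width mismatch errors
  expect_error(stream_probabilities(m, feats[, 1:5]), "width")
})

test_that("detector training is deterministic and validates class subsets", {
  fxd <- fx_detector()
  hy <- detector_hyper(hidden = 8, n_layers = 1, epochs = 2, chunk_s = 5)
  m1 <- fit_detector(fxd$session, hyper = hy, seed = 3)
  m2 <- fit_detector(fxd$session, hyper = hy, seed = 3)
  expect_identical(m1$losses, m2$losses)
  expect_identical(m1$params, m2$params)
  expect_error(fit_detector(fxd$session, hyper = hy,
                            class_subset = c("silence", "bogus")),
               "unknown class")
  # a rest session has no speech labels: requesting speech errors
  rest <- simulate_session(sim_config(
    n_electrodes = 12, schedule = list(type = "rest", duration = 30),
    seed = 2))
  expect_error(fit_detector(rest, hyper = hy,
                            class_subset = c("silence", "speech")),
               "absent")
})

test_that("trained detector separates classes on held-out data", {
  fxd <- fx_detector()
  s_te <- simulate_session(sim_config(
    n_electrodes = 12,
    schedule = list(type = "isolated_target",
                    task = c("speech", "reading", "listening"), n_trials = 18),
    snr = 2, seed = 56))
  p <- stream_probabilities(fxd$model, s_te)
  acc <- mean(max.col(p)[s_te$train_mask] == s_te$labels[s_te$train_mask])
  expect_gt(acc, 0.6)  # threshold from pilot runs at this scale
  # rest-only block: silence probability dominates
  rest <- simulate_session(sim_config(
    n_electrodes = 12, schedule = list(type = "rest", duration = 30),
    seed = 57))
  pr <- stream_probabilities(fxd$model, rest)
  expect_equal(which.max(colMeans(pr)), c(silence = 1L))
})

test_that("recognition latency is additive in the time threshold", {
  fs <- 200
  true_ev <- data.frame(onset = 10, offset = 12)
  b <- rep(0, 15 * fs)
  b[seq.int(round(10.2 * fs) + 1, round(12.2 * fs))] <- 1  # detector lags truth by 0.2 s
  ev <- extract_events(b, detector_postprocess_config(smooth_width = 1))
  lat <- recognition_latency(ev, true_ev)
  expect_equal(lat$median_onset, 0.2 + 0.5, tolerance = 0.01)
  # perfect alignment: onset latency is exactly t_on / fs
  b2 <- rep(0, 15 * fs)
  b2[seq.int(10 * fs + 1, 12 * fs)] <- 1
  ev2 <- extract_events(b2, detector_postprocess_config(smooth_width = 1))
  lat2 <- recognition_latency(ev2, true_ev)
  expect_equal(lat2$median_onset, 0.5, tolerance = 0.01)
  expect_equal(recognition_latency(ev[0, ], true_ev)$median_onset, NA_real_)
})
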