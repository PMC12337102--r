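test_that("event_window cuts and downsamples the d*-aligned window", {
  s <- fx_small()
  spec <- event_window_spec(-1, 3, 6)
  w <- event_window(s, 10, spec)
  expect_equal(dim(w), c(round(4 * 200 / 6), ncol(s$hga), 2))
  rt <- attr(w, "rel_time")
  expect_equal(rt[1], -1)
  expect_equal(diff(rt)[1], 6 / 200)  # effective rate 33.3 Hz
  # source samples drawn from [9, 13) s
  expect_equal(w[1, , 1], s$hga[9 * 200 + 1, ])
  expect_equal(w[2, , 1], s$hga[9 * 200 + 7, ])
  expect_error(event_window_spec(3, -1), "exceed")
  expect_error(event_window(s, 0.2, spec), "bounds")
})

test_that("verifier ensemble probabilities are proper and thresholding is strict", {
  fxv <- fx_verifier()
  ens <- fxv$ensemble
  pm <- verifier_probs(ens, fxv$windows[fxv$test])
  expect_equal(unname(rowSums(pm)), rep(1, nrow(pm)), tolerance = 1e-6)
  w <- fxv$windows[[fxv$test[1]]]
  v <- verify(ens, w)
  p_sp <- unname(v$probs["speech"])
  # strict inequality at the threshold
  expect_false(verify(ens, w, theta_v = p_sp)$accepted)
  expect_true(verify(ens, w, theta_v = p_sp - 1e-9)$accepted)
  # ensemble of identical members equals the single member
  one <- ens
  one$members <- ens$members[1]
  dup <- ens
  dup$members <- ens$members[c(1, 1, 1)]
  expect_equal(verify(one, w)$probs, verify(dup, w)$probs, tolerance = 1e-12)
  # shape mismatch errors
  short <- w[1:50, , , drop = FALSE]
  expect_error(verify(ens, short), "shape")
})

test_that("verifier separates tasks on held-out data and respects contracts", {
  fxv <- fx_verifier()
  pred <- fxv$ensemble$classes[max.col(verifier_probs(fxv$ensemble,
                                                      fxv$windows[fxv$test]))]
  expect_gt(mean(pred == fxv$labels[fxv$test]), 0.8)
  # shuffled labels train to ~chance (1/3)
  set.seed(5)
  sh_lab <- sample(fxv$labels[fxv$train])
  hy <- fxv$hyper
  hy$epochs <- 10
  ens_sh <- fit_verifier(fxv$windows[fxv$train], sh_lab, hyper = hy, K = 2,
                         seed = 8)
  pred_sh <- ens_sh$classes[max.col(verifier_probs(ens_sh,
                                                   fxv$windows[fxv$test]))]
  expect_lt(mean(pred_sh == fxv$labels[fxv$test]), 0.6)
  # include_motor widens the class set
  lb <- fxv$labels[fxv$train]
  lb[seq(1, length(lb), by = 7)] <- "nonspeech_motor"
  ens_m <- fit_verifier(fxv$windows[fxv$train], lb, hyper = hy, K = 1,
                        include_motor = TRUE, seed = 2)
  expect_length(ens_m$classes, 4)
  expect_error(fit_verifier(fxv$windows[1:4], rep("speech", 4)),
               "2 classes")
  expect_warning(fit_verifier(fxv$windows[1:8],
                              c(rep("speech", 6), rep("reading", 2)),
                              hyper = hy, K = 3, seed = 1),
                 "fewer examples")
})

test_that("threshold_sweep matches a brute-force enumeration and is monotone", {
  fxv <- fx_verifier()
  ens <- fxv$ensemble
  wins <- fxv$windows[fxv$test]
  is_sp <- fxv$labels[fxv$test] == "speech"
  sw <- threshold_sweep(ens, wins, is_sp)
  expect_equal(sw$fn_rate[sw$theta == 0], 0)      # everything accepted
  expect_equal(sw$fp_rate[sw$theta == 1], 0)      # nothing accepted
  expect_true(all(diff(sw$fp_rate) <= 1e-12))
  expect_true(all(diff(sw$fn_rate) >= -1e-12))
  # brute-force oracle over the same grid
  p <- verifier_probs(ens, wins)[, "speech"]
  n <- length(p)
  for (i in seq(1, nrow(sw), by = 10)) {
    th <- sw$theta[i]
    expect_equal(sw$fp_rate[i], sum(p > th & !is_sp) / n)
    expect_equal(sw$fn_rate[i], sum(p <= th & is_sp) / n)
  }
  expect_error(threshold_sweep(ens, list(), logical(0)), "no events")
})

test_that("verification accuracy grows with post-onset context when classes separate late", {
  # constructed fixture: no pre-cue planning ramp, so nothing distinguishes
  # the classes before the detected onset
  s <- simulate_session(sim_config(
    n_electrodes = 12,
    schedule = list(type = "isolated_target",
                    task = c("speech", "reading", "listening"),
                    n_trials = 120),
    snr = 2,
    pre_cue_ramp = c(shared = 0, articulatory = 0, auditory = 0, visual = 0,
                     silent = 0),
    seed = 78))
  tr <- s$trials
  spec <- event_window_spec(-1, 3, 6)
  keep <- which(tr$onset + spec$start > 0 &
                  tr$onset + spec$end < nrow(s$hga) / 200)
  windows <- lapply(tr$onset[keep], function(d) event_window(s, d, spec))
  hy <- seqnet_hyper(conv_channels = 8, kern = 7, stride = 3, hidden = 16,
                     epochs = 20, lr = 2e-3, batch_size = 16,
                     weight_decay = 0.3)
  cc <- context_curve(windows, tr$task[keep], context_lengths = c(0, 3),
                      spec = spec, hyper = hy, K = 2, seed = 4)
  expect_equal(nrow(cc), 2)
  expect_lte(cc$accuracy[cc$context == 0], cc$accuracy[cc$context == 3])
  expect_gt(cc$accuracy[cc$context == 3], 0.8)
  expect_error(ecodec:::truncate_windows(windows, spec, 10), "exceeds")
})
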