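test_that("ranksum_z matches the reference normal-approximation test", {
  set.seed(12)
  for (k in 1:20) {
    a <- rnorm(15, mean = runif(1, 0, 1))
    b <- rnorm(12)
    r <- ranksum_z(a, b)
    w <- stats::wilcox.test(a, b, alternative = "greater", exact = FALSE,
                            correct = FALSE)
    expect_equal(r$p, w$p.value, tolerance = 1e-9)
  }
  expect_error(ranksum_z(1, 1:5), "at least 2")
})

test_that("responsiveness recovers designed electrodes and clips negative stats", {
  s <- fx_mixed201()
  for (tk in c("speech", "reading", "listening")) {
    m <- responsiveness(s, tk)
    truth <- designed_responsive(s, tk)
    sens <- sum(m$significant & truth) / sum(truth)
    spec <- sum(!m$significant & !truth) / sum(!truth)
    expect_gte(sens, 0.9)
    expect_gte(spec, 0.9)
  }
  # an electrode with higher baseline than post-onset activity: z < 0, stat 0
  s2 <- fx_mixed201()
  fs <- 200
  tr <- s2$trials[s2$trials$task == "speech", ]
  for (i in seq_len(nrow(tr))) {
    idx <- round((tr$presentation[i] - 1) * fs):round(tr$presentation[i] * fs)
    s2$hga[idx, 32] <- s2$hga[idx, 32] + 3
  }
  m2 <- responsiveness(s2, "speech")
  expect_lt(m2$z[32], 0)
  expect_equal(m2$stat[32], 0)
  expect_false(m2$significant[32])
  expect_error(responsiveness(fx_small(), "nonspeech_motor"), "fewer than 2")
})

test_that("responsiveness type-I rate stays at or below alpha on null electrodes", {
  # exchangeable nulls: silent-only grids, stated-world noise
  fr <- c(shared = 0, articulatory = 0, auditory = 0, visual = 0, silent = 1)
  raw_p <- c()
  fam_hit <- 0
  reps <- 200
  for (k in seq_len(reps)) {
    s <- simulate_session(sim_config(
      n_electrodes = 6, class_fractions = fr,
      schedule = list(type = "isolated_target", task = "speech",
                      n_trials = 12),
      seed = 3000 + k))
    m <- responsiveness(s, "speech")
    raw_p <- c(raw_p, m$p)
    if (any(m$significant)) fam_hit <- fam_hit + 1
  }
  expect_lt(mean(raw_p < 0.05), 0.08)        # raw one-sided rate ~ alpha
  expect_lte(fam_hit / reps, 0.05 + 0.03)    # Holm familywise rate
})

test_that("shared_set intersects the three significant sets", {
  s <- fx_mixed201()
  maps <- lapply(c(speech = "speech", reading = "reading",
                   listening = "listening"),
                 function(tk) responsiveness(s, tk))
  es <- shared_set(maps)
  truth <- which(s$profiles$profiles$class == "shared")
  expect_setequal(es$shared, truth)
  # empty significant set for one task empties the intersection
  maps2 <- maps
  maps2$reading$significant <- FALSE
  expect_length(shared_set(maps2)$shared, 0)
  expect_error(shared_set(maps[1:2]), "must cover")
})

test_that("contributions are nonnegative, masked channels score zero, and ranking is stable", {
  gw <- fx_speech300_windows()
  hy <- fx_cls_hyper()
  hy$epochs <- 15
  prof <- fx_speech300()$profiles$profiles
  mask <- prof$class != "silent"
  ens <- fit_classifier(gw$windows[1:120], gw$words[1:120], hyper = hy, K = 1,
                        electrode_mask = mask, seed = 3)
  cm <- contributions(ens, gw$windows[1:60], gw$words[1:60])
  expect_true(all(cm$total >= 0))
  expect_equal(cm$total == 0, !mask)  # masked electrodes contribute exactly 0
  expect_equal(cm$total, cm$hga + cm$lfs)
  # duplicating an electrode's signal into a dead (masked) channel must not
  # change the ranking of the others: the model never reads that channel
  wins2 <- lapply(gw$windows[1:60], function(w) {
    w[, which(!mask)[1], ] <- w[, which(mask)[1], ]
    w
  })
  cm2 <- contributions(ens, wins2, gw$words[1:60])
  keep <- which(mask)
  expect_equal(order(cm$total[keep]), order(cm2$total[keep]))
  # informative electrodes carry more contribution than silent ones on average
  ens_all <- fit_classifier(gw$windows[1:150], gw$words[1:150], hyper = hy,
                            K = 1, seed = 4)
  cm_all <- contributions(ens_all, gw$windows[1:60], gw$words[1:60])
  informative <- prof$tuning_phase != "none" & prof$gain_speech > 0
  expect_gt(mean(cm_all$total[informative]), mean(cm_all$total[!informative]))
})

test_that("detector contributions require labels only implicitly and favor responsive electrodes", {
  fxd <- fx_detector()
  cm <- contributions(fxd$model, fxd$session)
  prof <- fxd$session$profiles$profiles
  resp <- prof$gain_speech > 0 | prof$gain_reading > 0 | prof$gain_listening > 0
  expect_true(all(cm$total >= 0))
  expect_gt(mean(cm$hga[resp]), mean(cm$hga[!resp]))
})

test_that("multitaper band power matches a periodogram oracle within 10% in band", {
  fs <- 200
  t <- seq(1 / fs, 2, by = 1 / fs)
  x <- 1.4 * sin(2 * pi * 8 * t) + rnorm(length(t), 0, 0.05)
  bp <- multitaper_band_power(x, fs, c(5, 12))
  # periodogram oracle: band-integrated power of the tone = a^2/2
  X <- fft(x)
  f <- (0:(length(x) - 1)) * fs / length(x)
  sel <- f >= 5 & f <= 12 & f < fs / 2
  bp_or <- 2 * sum(Mod(X[sel])^2) / length(x)^2
  expect_equal(bp, bp_or, tolerance = 0.1 * bp_or)
  expect_equal(bp, 1.4^2 / 2, tolerance = 0.15)
  # tone out of band
  expect_lt(multitaper_band_power(x, fs, c(20, 30)), 0.05)
  expect_error(multitaper_band_power(x, fs, c(90, 110)), "Nyquist")
})

test_that("band_power contrasts designed theta/beta modulation across tasks", {
  s <- fx_mixed201()
  prof <- s$profiles$profiles
  sh <- which(prof$class == "shared")
  cfg <- spectral_config(block_size = 20)
  bp <- band_power(s, tasks = c("speech", "listening"), cfg = cfg,
                   electrodes = sh)
  expect_true(all(c("theta", "beta") %in% bp$band))
  # z-scores pool to mean 0 per band
  for (bd in c("theta", "beta"))
    expect_equal(mean(bp$power_z[bp$band == bd]), 0, tolerance = 1e-9)
  # beta suppressed during speech vs elevated during listening
  be <- bp[bp$band == "beta", ]
  expect_lt(mean(be$power_z[be$task == "speech"]),
            mean(be$power_z[be$task == "listening"]))
  r <- ranksum_z(be$power_z[be$task == "listening"],
                 be$power_z[be$task == "speech"])
  expect_lt(r$p, 0.05)
  expect_error(band_power(s, cfg = spectral_config(beta = c(90, 120))),
               "Nyquist")
})

test_that("longform activation flags designed auditory electrodes and calibrates on nulls", {
  lf <- simulate_session(sim_config(
    n_electrodes = 12,
    schedule = list(type = "longform", condition = "listening",
                    duration = 60),
    seed = 71))
  bl <- simulate_session(sim_config(
    n_electrodes = 12, schedule = list(type = "rest", duration = 60),
    seed = 72))
  res <- longform_activation(lf, bl, n_points = 100, seed = 5)
  prof <- lf$profiles$profiles
  aud <- prof$class == "auditory"
  expect_true(all(res$significant[aud]))
  # null: two rest blocks
  bl2 <- simulate_session(sim_config(
    n_electrodes = 12, schedule = list(type = "rest", duration = 60),
    seed = 73))
  res0 <- longform_activation(bl2, bl, n_points = 100, seed = 6)
  expect_lte(sum(res0$significant), 1)
  expect_error(longform_activation(lf, bl, n_points = 1), "at least 2")
})
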