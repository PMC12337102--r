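# Seeded simulator of sensorimotor-ECoG feature streams. The generator writes
# the study's qualitative findings into the ground truth: "shared" electrodes
# (middle precentral gyrus) respond to attempted speech > reading > listening,
# ramp up before the go-cue, and carry word information only pre-cue;
# "articulatory" electrodes respond only to attempted movements and carry word
# information post-cue; auditory (temporal) electrodes respond to listening
# with task-specific word codes; theta/beta LFS power is suppressed during
# attempted speech and elevated during perception.

SIM_CLASSES <- c("shared", "articulatory", "auditory", "visual", "silent")
SIM_TASKS <- c("speech", "reading", "listening", "nonspeech_motor")

#' Simulator configuration
#'
#' Defaults encode the stated world of the generator: per-task evoked gains at
#' shared electrodes of 3/2/1 z-units for speech/reading/listening, a pre-cue
#' ramp of 1 z-unit, AR(1) noise with coefficient 0.95 and unit standard
#' deviation at 200 Hz, log-normal word-tuning multipliers with log-sd 0.25,
#' and theta/beta modulation of -0.5 during attempted speech versus +0.3
#' during perception.
#'
#' @param n_electrodes number of electrodes (>= 4)
#' @param class_fractions named fractions over
#'   shared/articulatory/auditory/visual/silent; must sum to 1
#' @param vocab_size closed-vocabulary size (default 10)
#' @param schedule list: `type` one of `"isolated_target"`, `"online"`,
#'   `"longform"`, `"rest"`; `task` (isolated; may be a vector cycled across
#'   trials), `condition` (online/longform: `"baseline"`, `"reading"`,
#'   `"listening"`, `"imagery"`), `n_trials`, `duration` (longform/rest, s)
#' @param snr multiplier applied to all evoked gains
#' @param word_tuning_sd log-sd of per-word gain multipliers
#' @param word_code_sharing `"independent"` (default; per-task word codes) or
#'   `"shared"` (same code across tasks)
#' @param seed integer seed; sessions are bit-reproducible given the config
#' @param ... overrides for the remaining stated-world parameters (gains,
#'   timing, noise, band modulation; see the vignette)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_electrodes = 32,
                       class_fractions = c(shared = 0.15, articulatory = 0.20,
                                           auditory = 0.15, visual = 0.10,
                                           silent = 0.40),
                       vocab_size = 10,
                       schedule = list(type = "isolated_target",
                                       task = "speech", n_trials = 50),
                       snr = 1, word_tuning_sd = 0.25,
                       word_code_sharing = c("independent", "shared"),
                       seed = 1, ...) {
  cfg <- list(
    n_electrodes = n_electrodes,
    class_fractions = class_fractions,
    vocab_size = vocab_size,
    schedule = schedule,
    snr = snr,
    word_tuning_sd = word_tuning_sd,
    word_code_sharing = match.arg(word_code_sharing),
    seed = seed,
    gains = list(shared = c(speech = 3, reading = 2, listening = 1,
                            nonspeech_motor = 0.5),
                 articulatory = c(speech = 3, reading = 0, listening = 0,
                                  nonspeech_motor = 2),
                 auditory = c(speech = 1.5, reading = 0, listening = 3,
                              nonspeech_motor = 0),
                 visual = c(speech = 0, reading = 2, listening = 0,
                            nonspeech_motor = 0),
                 silent = c(speech = 0, reading = 0, listening = 0,
                            nonspeech_motor = 0)),
    pre_cue_ramp = c(shared = 1, articulatory = 0, auditory = 0, visual = 0,
                     silent = 0),
    tuning_phase = c(shared = "pre_cue", articulatory = "post_cue",
                     auditory = "post_cue", visual = "none", silent = "none"),
    theta_mod = list(shared = c(speech = -0.5, reading = 0.3, listening = 0.3,
                                nonspeech_motor = -0.3),
                     articulatory = c(speech = -0.5, reading = 0, listening = 0,
                                      nonspeech_motor = -0.5),
                     auditory = c(speech = 0, reading = 0, listening = 0.3,
                                  nonspeech_motor = 0),
                     visual = c(speech = 0, reading = 0.3, listening = 0,
                                nonspeech_motor = 0),
                     silent = c(speech = 0, reading = 0, listening = 0,
                                nonspeech_motor = 0)),
    latency = 0.2,
    ar1 = 0.95, noise_sd = 1,
    lfs_ar1 = 0.8, lfs_noise_sd = 0.7, osc_amp = 0.6,
    presentation_to_go = 2, attempt_latency = 0.2, attempt_duration = 1.5,
    trial_duration = 3, stimulus_duration = 2, iti = 2, iti_jitter = 0.5,
    online_delay_range = c(2, 8), online_clear = 4,
    false_font_gain = 0.25,
    label_scheme = "fixed", label_fixed_extent = 2.75, label_fraction = 0.85
  )
  cfg$beta_mod <- cfg$theta_mod
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (any(unlist(cfg[c("presentation_to_go", "attempt_duration",
                       "trial_duration", "stimulus_duration", "iti")]) <= 0))
    stop("all durations must be positive")
  structure(cfg, class = "sim_config")
}

class_region <- c(shared = "midPrCG", articulatory = "PrCG",
                  auditory = "temporal", visual = "frontal", silent = "other")

#' Build the simulated electrode grid
#'
#' Class counts follow `class_fractions` with largest-remainder rounding;
#' regions follow the class (shared electrodes sit on the middle precentral
#' gyrus, articulatory electrodes alternate between pre- and postcentral
#' gyrus, auditory on temporal, visual on frontal cortex). Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()]
#' @return list with `profiles` (one row per electrode) and `word_tuning`
#'   (per task, an electrode x word multiplier matrix)
#' @export
make_grid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_electrodes
  if (n < 4) stop("need at least 4 electrodes")
  fr <- config$class_fractions[SIM_CLASSES]
  fr[is.na(fr)] <- 0
  names(fr) <- SIM_CLASSES
  if (abs(sum(fr) - 1) > 1e-8) stop("class_fractions must sum to 1")
  base <- floor(fr * n)
  rem <- fr * n - base
  extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
  counts <- base
  counts[extra] <- counts[extra] + 1
  cls <- rep(SIM_CLASSES, counts)
  region <- class_region[cls]
  artic <- which(cls == "articulatory")
  region[artic[seq_along(artic) %% 2 == 0]] <- "PoCG"
  with_seed(config$seed, {
    gm <- do.call(rbind, config$gains[cls])
    profiles <- data.frame(electrode = seq_len(n), region = unname(region),
                           class = cls,
                           gain_speech = gm[, "speech"],
                           gain_reading = gm[, "reading"],
                           gain_listening = gm[, "listening"],
                           gain_nonspeech_motor = gm[, "nonspeech_motor"],
                           latency = config$latency,
                           pre_cue_ramp = unname(config$pre_cue_ramp[cls]),
                           tuning_phase = unname(config$tuning_phase[cls]),
                           row.names = NULL)
    V <- config$vocab_size
    draw <- function() {
      m <- matrix(1, n, V)
      tuned <- profiles$tuning_phase != "none"
      m[tuned, ] <- rlnorm(sum(tuned) * V, 0, config$word_tuning_sd)
      m
    }
    wt <- if (config$word_code_sharing == "shared") {
      m <- draw()
      list(speech = m, reading = m, listening = m, nonspeech_motor = draw())
    } else {
      list(speech = draw(), reading = draw(), listening = draw(),
           nonspeech_motor = draw())
    }
    list(profiles = profiles, word_tuning = wt)
  })
}

# gamma-density evoked kernel, peak-normalized, ~1 s wide
evoked_kernel <- function(fs = 200, shape = 2, scale = 0.25, len_s = 2.5) {
  tt <- seq(0, len_s, by = 1 / fs)
  k <- dgamma(tt, shape = shape, scale = scale)
  k / max(k)
}

add_segment <- function(sig, i0, seg) {
  n <- length(sig)
  if (i0 > n) return(sig)
  j <- seq.int(i0, min(n, i0 + length(seg) - 1))
  sig[j] <- sig[j] + seg[seq_along(j)]
  sig
}

ar1_noise <- function(n, rho, sd) {
  as.numeric(stats::filter(rnorm(n, 0, sd * sqrt(1 - rho^2)), rho,
                           method = "recursive"))
}

# build the trial table for a schedule; times in seconds
build_schedule <- function(config) {
  sc <- config$schedule
  type <- sc$type %||% "isolated_target"
  mk <- function(...) data.frame(..., stringsAsFactors = FALSE)
  empty <- mk(trial = integer(0), task = character(0), condition = character(0),
              word = integer(0), presentation = numeric(0), go_cue = numeric(0),
              onset = numeric(0), offset = numeric(0), start = numeric(0),
              end = numeric(0), block = integer(0))
  bg <- empty
  if (type == "rest") {
    return(list(trials = empty, bg = bg,
                duration = sc$duration %||% 60, type = type))
  }
  if (type == "longform") {
    cond <- sc$condition %||% "listening"
    dur <- sc$duration %||% 120
    if (cond %in% c("reading", "listening")) {
      cur <- 2
      rows <- list()
      while (cur + config$stimulus_duration < dur - 1) {
        rows[[length(rows) + 1]] <-
          mk(trial = NA_integer_, task = cond, condition = cond,
             word = sample.int(config$vocab_size, 1), presentation = cur,
             go_cue = cur, onset = cur, offset = cur + config$stimulus_duration,
             start = cur, end = cur + config$stimulus_duration, block = 1L)
        cur <- cur + config$stimulus_duration + runif(1, 0.5, 1.5)
      }
      bg <- do.call(rbind, rows)
    }
    return(list(trials = empty, bg = bg, duration = dur, type = type))
  }
  if (type == "isolated_target") {
    nt <- sc$n_trials %||% 50
    tasks <- rep_len(sc$task %||% "speech", nt)
    words <- as.vector(vapply(seq_len(ceiling(nt / config$vocab_size)),
                              function(i) sample.int(config$vocab_size),
                              integer(config$vocab_size)))[seq_len(nt)]
    cur <- 2
    rows <- vector("list", nt)
    for (i in seq_len(nt)) {
      tk <- tasks[i]
      if (tk %in% c("speech", "nonspeech_motor")) {
        pres <- cur
        go <- pres + config$presentation_to_go
        on <- go + config$attempt_latency
        off <- on + config$attempt_duration
        end <- go + config$trial_duration
      } else {
        pres <- cur
        go <- pres
        on <- pres
        off <- on + config$stimulus_duration
        end <- off
      }
      rows[[i]] <- mk(trial = i, task = tk, condition = "isolated",
                      word = words[i], presentation = pres, go_cue = go,
                      onset = on, offset = off, start = pres, end = end,
                      block = 1L)
      # jitter keeps trial onsets off any exact lattice shared with the
      # oscillation periods and the downsampling grid
      cur <- end + config$iti + runif(1, 0, config$iti_jitter)
    }
    return(list(trials = do.call(rbind, rows), bg = bg,
                duration = cur + 1, type = type))
  }
  if (type == "online") {
    cond <- sc$condition %||% "baseline"
    nt <- sc$n_trials %||% 10
    words <- as.vector(vapply(seq_len(ceiling(nt / config$vocab_size)),
                              function(i) sample.int(config$vocab_size),
                              integer(config$vocab_size)))[seq_len(nt)]
    cur <- 2
    rows <- vector("list", nt)
    for (i in seq_len(nt)) {
      pres <- cur
      delay <- runif(1, config$online_delay_range[1], config$online_delay_range[2])
      on <- pres + delay
      off <- on + config$attempt_duration
      end <- off + config$online_clear
      rows[[i]] <- mk(trial = i, task = "speech", condition = cond,
                      word = words[i], presentation = pres, go_cue = pres,
                      onset = on, offset = off, start = pres, end = end,
                      block = 1L)
      cur <- end
    }
    trials <- do.call(rbind, rows)
    dur <- cur + 1
    if (cond %in% c("reading", "listening")) {
      bcur <- 1
      brows <- list()
      while (bcur + config$stimulus_duration < dur - 1) {
        brows[[length(brows) + 1]] <-
          mk(trial = NA_integer_, task = cond, condition = cond,
             word = sample.int(config$vocab_size, 1), presentation = bcur,
             go_cue = bcur, onset = bcur,
             offset = bcur + config$stimulus_duration, start = bcur,
             end = bcur + config$stimulus_duration, block = 1L)
        bcur <- bcur + config$stimulus_duration + runif(1, 0.5, 1.5)
      }
      bg <- do.call(rbind, brows)
    }
    return(list(trials = trials, bg = bg, duration = dur, type = type))
  }
  stop("unknown schedule type: ", type)
}

#' Simulate a neural session
#'
#' Generates both feature streams, trial records, ground-truth speech events,
#' and the detector label track for the configured schedule. High-gamma
#' activity is AR(1) noise plus gamma-shaped evoked bumps scaled by per-task
#' gains and word multipliers (plus a pre-cue ramp at shared electrodes on
#' speech trials); the low-frequency signal is broadband noise plus 8 Hz
#' (theta) and 25 Hz (beta) oscillations whose amplitudes are modulated by
#' task. Bit-reproducible given the config.
#'
#' @param config a [sim_config()]
#' @return a [neural_session()]
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$vocab_size < 2 && any(config$tuning_phase != "none"))
    stop("word tuning requires a vocabulary of at least 2 words")
  grid <- make_grid(config)
  fs <- 200
  with_seed(config$seed + 1L, {
    sch <- build_schedule(config)
    trials <- sch$trials
    bg <- sch$bg
    n_time <- round(sch$duration * fs)
    E <- config$n_electrodes
    kern <- evoked_kernel(fs)
    hga <- matrix(0, n_time, E)
    lfs <- matrix(0, n_time, E)
    all_resp <- rbind(trials, bg)
    prof <- grid$profiles
    t2i <- function(t) pmax(1L, pmin(n_time, round(t * fs) + 1L))
    for (e in seq_len(E)) {
      hga[, e] <- ar1_noise(n_time, config$ar1, config$noise_sd)
      cl <- prof$class[e]
      # evoked high-gamma responses
      if (nrow(all_resp)) for (i in seq_len(nrow(all_resp))) {
        tk <- all_resp$task[i]
        gtask <- if (tk == "false_font") "reading" else tk
        g <- config$gains[[cl]][gtask]
        if (tk == "false_font") g <- g * config$false_font_gain
        g <- g * config$snr
        if (g > 0) {
          wm <- 1
          if (prof$tuning_phase[e] == "post_cue" && gtask %in% names(grid$word_tuning))
            wm <- grid$word_tuning[[gtask]][e, all_resp$word[i]]
          hga[, e] <- add_segment(hga[, e],
                                  t2i(all_resp$onset[i] + prof$latency[e]),
                                  g * wm * kern)
        }
        # pre-cue planning ramp (speech attempts, shared electrodes)
        if (tk == "speech" && prof$pre_cue_ramp[e] > 0) {
          ramp_end <- if (all_resp$go_cue[i] - all_resp$presentation[i] > 0.3)
            all_resp$go_cue[i] else all_resp$onset[i]
          ramp_start <- if (all_resp$go_cue[i] - all_resp$presentation[i] > 0.3)
            all_resp$presentation[i] else all_resp$onset[i] - 1
          wm <- if (prof$tuning_phase[e] == "pre_cue")
            grid$word_tuning$speech[e, all_resp$word[i]] else 1
          amp <- prof$pre_cue_ramp[e] * config$snr * wm
          nup <- max(2L, round((ramp_end - ramp_start) * fs))
          ramp <- c(seq(0, amp, length.out = nup),
                    seq(amp, 0, length.out = round(0.5 * fs)))
          hga[, e] <- add_segment(hga[, e], t2i(ramp_start), ramp)
        }
      }
      # low-frequency signal: broadband noise + modulated oscillations
      tt <- (seq_len(n_time) - 1) / fs
      env_th <- rep(1, n_time)
      env_be <- rep(1, n_time)
      if (nrow(all_resp)) for (i in seq_len(nrow(all_resp))) {
        tk <- all_resp$task[i]
        gtask <- if (tk == "false_font") "reading" else tk
        span <- t2i(c(all_resp$onset[i], all_resp$onset[i] + 2))
        j <- span[1]:span[2]
        env_th[j] <- env_th[j] + config$theta_mod[[cl]][gtask]
        env_be[j] <- env_be[j] + config$beta_mod[[cl]][gtask]
      }
      lfs[, e] <- ar1_noise(n_time, config$lfs_ar1, config$lfs_noise_sd) +
        pmax(env_th, 0) * config$osc_amp * sin(2 * pi * 8 * tt + runif(1, 0, 2 * pi)) +
        pmax(env_be, 0) * config$osc_amp * sin(2 * pi * 25 * tt + runif(1, 0, 2 * pi))
    }
    lab <- sim_label_track(trials, bg, n_time, fs, config)
    ev <- trials[trials$task == "speech", c("trial", "word", "onset", "offset")]
    rownames(ev) <- NULL
    neural_session(hga, lfs, prof$region, trials, lab$labels, lab$mask,
                   events = ev,
                   profiles = c(grid, list()), config = config)
  })
}

# label track for simulated schedules; background perception spans are
# painted first, then main trials override
sim_label_track <- function(trials, bg, n_time, fs, config) {
  labels <- rep(1L, n_time)  # silence
  mask <- rep(TRUE, n_time)
  code <- c(silence = 1L, preparation = 2L, speech = 3L, reading = 4L,
            listening = 5L)
  paint <- function(t0, t1, value) {
    i0 <- max(1L, round(t0 * fs) + 1L)
    i1 <- min(n_time, round(t1 * fs))
    if (i1 >= i0) labels[i0:i1] <<- value
    invisible(NULL)
  }
  span_rows <- function(df) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    for (i in seq_len(nrow(df))) {
      tk <- df$task[i]
      if (tk %in% c("reading", "false_font")) paint(df$onset[i], df$offset[i], code["reading"])
      if (tk == "listening") paint(df$onset[i], df$offset[i], code["listening"])
    }
  }
  span_rows(bg)
  if (nrow(trials)) for (i in seq_len(nrow(trials))) {
    tk <- trials$task[i]
    if (tk == "speech") {
      if (trials$go_cue[i] - trials$presentation[i] > 0.3) {
        paint(trials$presentation[i], trials$go_cue[i], code["preparation"])
        ext <- if (config$label_scheme == "fixed") config$label_fixed_extent
               else config$label_fraction * (trials$end[i] - trials$go_cue[i])
        ext <- min(ext, trials$end[i] - trials$go_cue[i])
        paint(trials$go_cue[i], trials$go_cue[i] + ext, code["speech"])
        if (trials$go_cue[i] + ext < trials$end[i]) {
          i0 <- round((trials$go_cue[i] + ext) * fs) + 1L
          i1 <- min(n_time, round(trials$end[i] * fs))
          if (i1 >= i0) mask[i0:i1] <- FALSE
        }
      } else {
        paint(trials$onset[i], trials$offset[i] + 0.25, code["speech"])
      }
    } else if (tk %in% c("reading", "false_font", "listening")) {
      span_rows(trials[i, , drop = FALSE])
    }
  }
  list(labels = labels, mask = mask)
}

#' Ground-truth responsive electrode set for a task
#'
#' Electrodes whose designed evoked gain for `task` is positive.
#'
#' @param session a simulated [neural_session()]
#' @param task one of speech/reading/listening/nonspeech_motor
#' @export
designed_responsive <- function(session, task) {
  prof <- session$profiles$profiles
  if (is.null(prof)) stop("session has no simulator ground truth")
  prof[[paste0("gain_", task)]] > 0
}
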