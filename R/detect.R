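# Streaming speech detection: 5-class frame labeling, LSTM training, and the
# probability/time-threshold state machine that turns continuous speech
# probabilities into discrete detected events.

#' Build the 5-class detection label track for a set of trials
#'
#' Speech trials with a countdown are labeled preparation between presentation
#' and go-cue and speech from the go-cue to a per-scheme extent (a fixed
#' 2.75 s, or 85% of the post-cue trial duration); the ambiguous tail up to
#' trial end is masked out of the training loss. Self-paced speech trials
#' (go-cue coincides with presentation) are labeled speech over the annotated
#' attempt. Perception trials are labeled reading/listening over the stimulus
#' span. Everything else is silence.
#'
#' @param trials trial table (see [neural_session()]); must be sorted and
#'   non-overlapping
#' @param n_time number of 200 Hz samples in the session
#' @param scheme `"fixed"` or `"fraction"`
#' @param fixed_extent speech extent after go-cue, seconds (scheme `"fixed"`)
#' @param fraction fraction of the post-cue trial duration (scheme `"fraction"`)
#' @param fs sampling rate
#' @return list with integer `labels` (codes into [DETECTOR_CLASSES]) and a
#'   logical `mask` (FALSE = excluded from training)
#' @export
build_detection_labels <- function(trials, n_time, scheme = c("fixed", "fraction"),
                                   fixed_extent = 2.75, fraction = 0.85,
                                   fs = 200) {
  scheme <- match.arg(scheme)
  if (nrow(trials) > 1) {
    o <- order(trials$start)
    tr <- trials[o, ]
    if (any(diff(tr$start) < 0) || any(tr$start[-1] < tr$end[-nrow(tr)] - 1e-9))
      stop("trials must be sorted and non-overlapping")
  }
  cfg <- list(label_scheme = scheme, label_fixed_extent = fixed_extent,
              label_fraction = fraction)
  sim_label_track(trials, NULL, n_time, fs, cfg)
}

#' Detector hyperparameters
#' @param hidden LSTM hidden units per layer
#' @param n_layers number of LSTM layers
#' @param epochs,lr,batch_size optimizer settings (Adam)
#' @param chunk_s truncated-backpropagation chunk length in seconds
#' @export
detector_hyper <- function(hidden = 64, n_layers = 3, epochs = 30, lr = 1e-3,
                           batch_size = 8, chunk_s = 10, weight_decay = 0) {
  list(hidden = hidden, n_layers = n_layers, epochs = epochs, lr = lr,
       batch_size = batch_size, chunk_s = chunk_s,
       weight_decay = weight_decay)
}

session_chunks <- function(sessions, chunk_s, fs = 200) {
  if (inherits(sessions, "neural_session")) sessions <- list(sessions)
  cl <- round(chunk_s * fs)
  xs <- list(); ys <- list(); ms <- list()
  for (s in sessions) {
    feats <- session_features(s)
    nch <- floor(nrow(feats) / cl)
    for (k in seq_len(nch)) {
      i <- ((k - 1) * cl + 1):(k * cl)
      xs[[length(xs) + 1]] <- t(feats[i, ])
      ys[[length(ys) + 1]] <- s$labels[i]
      ms[[length(ms) + 1]] <- s$train_mask[i]
    }
  }
  FF <- nrow(xs[[1]])
  B <- length(xs)
  X <- array(0, c(FF, B, cl))
  for (b in seq_len(B)) X[, b, ] <- xs[[b]]
  list(X = X, Y = matrix(as.integer(unlist(ys)), cl, B),
       mask = matrix(as.integer(unlist(ms)), cl, B))
}

#' Train the streaming speech-detection model
#'
#' A stack of unidirectional LSTM layers with a 5-way softmax head, trained
#' with Adam on cross-entropy over unmasked samples using truncated
#' backpropagation over fixed-length chunks. The output head always has width
#' 5, so post-processing is unchanged across ablations; `class_subset`
#' implements ablations (e.g. a "speech-only" detector) by masking
#' excluded-class samples out of the training loss -- the ablated model never
#' sees reading/listening data, and those output units are never targets, so
#' their probabilities are trained toward zero.
#'
#' @param sessions a [neural_session()] or list of them
#' @param hyper see [detector_hyper()]
#' @param class_subset character subset of [DETECTOR_CLASSES] to train on
#'   (default all); classes outside the subset are relabeled silence
#' @param seed RNG seed (initialization and batch order)
#' @return a `detector_model`
#' @export
fit_detector <- function(sessions, hyper = detector_hyper(), class_subset = NULL,
                         seed = 1) {
  ch <- session_chunks(sessions, hyper$chunk_s)
  if (!is.null(class_subset)) {
    keep <- match(class_subset, DETECTOR_CLASSES)
    if (anyNA(keep)) stop("unknown class in class_subset")
    if (!all(keep %in% unique(as.vector(ch$Y[ch$mask == 1L]))))
      stop("a requested class is absent from the labels")
    drop <- setdiff(seq_along(DETECTOR_CLASSES), keep)
    ch$mask[ch$Y %in% drop] <- 0L  # excluded-class data is not used at all
  } else {
    pres <- unique(as.vector(ch$Y[ch$mask == 1L]))
    if (!all(c(1L, 3L) %in% pres))
      stop("training data must contain silence and speech samples")
  }
  params <- init_lstm_net(dim(ch$X)[1], hyper$hidden, hyper$n_layers,
                          length(DETECTOR_CLASSES), seed = seed)
  fit <- train_lstm_net(params, ch$X, ch$Y, ch$mask, epochs = hyper$epochs,
                        lr = hyper$lr, batch_size = hyper$batch_size,
                        seed = seed + 1000L,
                        weight_decay = hyper$weight_decay %||% 0)
  structure(list(params = fit$params, losses = fit$losses,
                 classes = DETECTOR_CLASSES, n_features = dim(ch$X)[1],
                 hyper = hyper, class_subset = class_subset),
            class = "detector_model")
}

#' Stream class probabilities through the detector
#'
#' Strictly causal: the probability at time t depends only on features at or
#' before t. Rows sum to 1.
#'
#' @param model a `detector_model`
#' @param session a [neural_session()] (or a time x features matrix)
#' @return time x 5 probability matrix at 200 Hz
#' @export
stream_probabilities <- function(model, session) {
  feats <- if (inherits(session, "neural_session")) session_features(session)
           else as.matrix(session)
  if (ncol(feats) != model$n_features)
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(feats), model$n_features))
  X <- array(t(feats), c(ncol(feats), 1, nrow(feats)))
  p <- lstm_probs(model$params, X)  # C x 1 x T
  out <- t(p[, 1, ])
  colnames(out) <- model$classes
  out
}

#' Post-processing configuration for event extraction
#'
#' @param smooth_width causal moving-average width in samples (default 40,
#'   i.e. 200 ms at 200 Hz)
#' @param theta_p probability threshold in (0,1)
#' @param t_on,t_off time thresholds in samples (default 100 = 0.5 s)
#' @export
detector_postprocess_config <- function(smooth_width = 40, theta_p = 0.5,
                                        t_on = 100, t_off = 100) {
  stopifnot(t_on >= 1, t_off >= 1, theta_p > 0, theta_p < 1)
  list(smooth_width = smooth_width, theta_p = theta_p,
       t_on = as.integer(t_on), t_off = as.integer(t_off))
}

#' Extract discrete speech events from a probability trace
#'
#' The speech-class probability is smoothed with a causal moving average and
#' thresholded at `theta_p` into a binary signal b(t). An event onset is the
#' first sample of a run of b = 1 lasting at least `t_on` samples (recognized
#' `t_on` samples later); the event ends at the last b = 1 sample before b = 0
#' persists for `t_off` samples (recognized once those `t_off` samples have
#' elapsed). Gaps shorter than `t_off` merge; 1-runs shorter than `t_on`
#' outside an event produce nothing.
#'
#' @param trace time x 5 probability matrix (or a bare speech-probability /
#'   binary vector)
#' @param cfg a [detector_postprocess_config()]
#' @param fs sampling rate
#' @return data.frame of `detected_event`s: `onset`, `offset`,
#'   `onset_recognized_at`, `offset_recognized_at` (seconds)
#' @export
extract_events <- function(trace, cfg = detector_postprocess_config(), fs = 200) {
  p <- if (is.matrix(trace)) trace[, "speech"] else as.numeric(trace)
  sm <- causal_ma(p, cfg$smooth_width)
  b <- sm > cfg$theta_p
  n <- length(b)
  out <- data.frame(onset = numeric(0), offset = numeric(0),
                    onset_recognized_at = numeric(0),
                    offset_recognized_at = numeric(0))
  if (n == 0 || !any(b)) return(out)
  r <- rle(as.integer(b))
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  ends <- cumsum(r$lengths)
  in_event <- FALSE
  ev_on <- NA_integer_
  ev_off <- NA_integer_
  emit <- function(on, off) {
    out[nrow(out) + 1L, ] <<- c((on - 1) / fs, (off - 1) / fs,
                                (on - 1) / fs + cfg$t_on / fs,
                                (off - 1) / fs + cfg$t_off / fs)
  }
  for (k in seq_along(r$values)) {
    if (r$values[k] == 1L) {
      if (!in_event) {
        if (r$lengths[k] >= cfg$t_on) {
          in_event <- TRUE
          ev_on <- starts[k]
          ev_off <- ends[k]
        }
      } else {
        ev_off <- ends[k]
      }
    } else if (in_event && r$lengths[k] >= cfg$t_off) {
      emit(ev_on, ev_off)
      in_event <- FALSE
    }
  }
  if (in_event) emit(ev_on, ev_off)
  out
}

#' Run detection end to end on a session
#'
#' @param model a `detector_model`
#' @param session a [neural_session()]
#' @param cfg post-processing configuration
#' @export
detect_events <- function(model, session, cfg = detector_postprocess_config()) {
  extract_events(stream_probabilities(model, session), cfg)
}

#' Onset/offset recognition latencies against ground truth
#'
#' Matches detected events to true attempts (onset-to-onset, see
#' [match_events()]) and summarizes recognition latency = recognized time
#' minus true boundary.
#'
#' @param events data.frame from [extract_events()]
#' @param true_events data.frame with `onset`, `offset` (seconds)
#' @param tol matching tolerance in seconds
#' @return list with per-event latencies and their medians (empty if nothing
#'   matched)
#' @export
recognition_latency <- function(events, true_events, tol = 0.5) {
  if (!nrow(events) || !nrow(true_events))
    return(list(onset = numeric(0), offset = numeric(0),
                median_onset = NA_real_, median_offset = NA_real_))
  m <- match_events(true_events, events, tol = tol)
  keep <- which(m$status == "TP")
  if (!length(keep))
    return(list(onset = numeric(0), offset = numeric(0),
                median_onset = NA_real_, median_offset = NA_real_))
  att <- m$assigned[keep]
  on_lat <- events$onset_recognized_at[keep] - true_events$onset[att]
  off_lat <- events$offset_recognized_at[keep] - true_events$offset[att]
  list(onset = on_lat, offset = off_lat,
       median_onset = median(on_lat), median_offset = median(off_lat))
}
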