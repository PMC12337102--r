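# Verification gate: classify the fixed window around a detected onset d* as
# attempted speech, reading, or listening (optionally non-speech movement) and
# accept only confident speech.

#' Event-window specification
#'
#' Defaults give a 4 s window around the detected onset, consumed at 33.3 Hz
#' (downsampled by a factor of 6 from 200 Hz).
#'
#' @param start_offset,end_offset window bounds relative to d*, seconds
#' @param downsample_factor integer decimation factor from 200 Hz
#' @export
event_window_spec <- function(start_offset = -1, end_offset = 3,
                              downsample_factor = 6) {
  if (end_offset <= start_offset) stop("window end must exceed its start")
  list(start = start_offset, end = end_offset,
       factor = as.integer(downsample_factor))
}

#' Extract the feature window around a detected onset
#'
#' @param session a [neural_session()]
#' @param d_star detected onset, seconds
#' @param spec an [event_window_spec()]
#' @return array (time x electrode x 2 bands), downsampled; time length is
#'   `round((end-start)*200/factor)`
#' @export
event_window <- function(session, d_star, spec = event_window_spec()) {
  fs <- session$sample_rate_hz
  n_src <- round((spec$end - spec$start) * fs)
  i0 <- round((d_star + spec$start) * fs) + 1L
  n_out <- round(n_src / spec$factor)
  idx <- i0 + (seq_len(n_out) - 1L) * spec$factor
  if (idx[1] < 1 || idx[length(idx)] > session_length(session))
    stop(sprintf("event window for d*=%.2f s out of session bounds", d_star))
  out <- array(0, c(n_out, ncol(session$hga), 2),
               dimnames = list(NULL, NULL, c("HGA", "LFS")))
  out[, , 1] <- session$hga[idx, ]
  out[, , 2] <- session$lfs[idx, ]
  attr(out, "rel_time") <- spec$start + (seq_len(n_out) - 1L) * spec$factor / fs
  out
}

# stack a list of (time x E x 2) windows into a (2E x B x T) cube, optionally
# keeping only masked electrodes
window_stack <- function(windows, electrode_mask = NULL) {
  w1 <- windows[[1]]
  E <- dim(w1)[2]
  keep <- if (is.null(electrode_mask)) rep(TRUE, E) else electrode_mask
  if (!any(keep)) stop("electrode mask removes every electrode")
  TT <- dim(w1)[1]
  FF <- 2 * sum(keep)
  X <- array(0, c(FF, length(windows), TT))
  for (b in seq_along(windows)) {
    w <- windows[[b]]
    X[, b, ] <- t(cbind(w[, keep, 1], w[, keep, 2]))
  }
  X
}

#' Hyperparameters for the conv + GRU sequence classifiers
#' @param conv_channels,kern,stride temporal convolution shape
#' @param hidden,n_layers GRU shape
#' @param epochs,lr,batch_size Adam settings
#' @param patience early-stopping patience (epochs without validation
#'   improvement) when a validation set is supplied
#' @param weight_decay decoupled L2 decay on weight matrices
#' @export
seqnet_hyper <- function(conv_channels = 32, kern = 5, stride = 1, hidden = 64,
                        n_layers = 2, epochs = 30, lr = 1e-3, batch_size = 16,
                        patience = 5, weight_decay = 2e-3) {
  list(conv_channels = conv_channels, kern = kern, stride = stride,
       hidden = hidden, n_layers = n_layers, epochs = epochs, lr = lr,
       batch_size = batch_size, patience = patience,
       weight_decay = weight_decay)
}

fit_seq_ensemble <- function(X, y, n_class, hyper, K, seed) {
  members <- vector("list", K)
  for (m in seq_len(K)) {
    ms <- seed + m - 1L
    params <- init_seqnet(dim(X)[1], hyper$conv_channels, hyper$kern,
                          hyper$stride, hyper$hidden, hyper$n_layers,
                          n_class, seed = ms)
    members[[m]] <- train_seqnet(params, X, y, epochs = hyper$epochs,
                                 lr = hyper$lr, batch_size = hyper$batch_size,
                                 seed = ms + 5000L,
                                 weight_decay = hyper$weight_decay %||% 0)$params
  }
  members
}

ensemble_probs <- function(members, X) {
  p <- 0
  for (m in members) p <- p + seqnet_probs(m, X)
  p / length(members)  # C x B
}

#' Train the speech-verification ensemble
#'
#' K randomly initialized conv+GRU models classify a detected event window as
#' attempted speech, reading, or listening (plus non-speech movement when
#' `include_motor`). Ensemble probability is the arithmetic mean of member
#' probabilities.
#'
#' @param windows list of event windows ([event_window()]); speech windows
#'   aligned to detected onsets, perceptual windows to stimulus onsets
#' @param task_labels character/factor over
#'   speech/reading/listening\[/nonspeech_motor\]
#' @param hyper see [seqnet_hyper()]
#' @param K ensemble size (default 10)
#' @param include_motor add the non-speech movement class
#' @param theta_v acceptance threshold stored with the ensemble
#' @param seed RNG seed
#' @return a `verifier_ensemble`
#' @export
fit_verifier <- function(windows, task_labels, hyper = seqnet_hyper(), K = 10,
                         include_motor = FALSE, theta_v = 0.65, seed = 1) {
  classes <- c("speech", "reading", "listening",
               if (include_motor) "nonspeech_motor")
  task_labels <- as.character(task_labels)
  if (!all(task_labels %in% classes))
    stop("task_labels outside the verifier class set")
  if (length(unique(task_labels)) < 2) stop("need at least 2 classes present")
  cnt <- table(factor(task_labels, classes))
  if (any(cnt > 0 & cnt < K))
    warning("some classes have fewer examples than ensemble members")
  X <- window_stack(windows)
  y <- match(task_labels, classes)
  members <- fit_seq_ensemble(X, y, length(classes), hyper, K, seed)
  structure(list(members = members, classes = classes, theta_v = theta_v,
                 n_features = dim(X)[1], n_time = dim(X)[3], hyper = hyper),
            class = "verifier_ensemble")
}

verifier_check_shape <- function(ensemble, X) {
  if (dim(X)[1] != ensemble$n_features || dim(X)[3] != ensemble$n_time)
    stop("window shape does not match the ensemble's training shape")
}

#' Verify a detected event
#'
#' @param ensemble a [fit_verifier()] result
#' @param window a single event window
#' @param theta_v acceptance threshold on the mean speech probability
#'   (strict inequality; default 0.65)
#' @return list with named `probs` and logical `accepted`
#' @export
verify <- function(ensemble, window, theta_v = ensemble$theta_v) {
  X <- window_stack(list(window))
  verifier_check_shape(ensemble, X)
  p <- ensemble_probs(ensemble$members, X)[, 1]
  names(p) <- ensemble$classes
  list(probs = p, accepted = unname(p["speech"] > theta_v))
}

#' Mean speech probability for a batch of windows
#' @param ensemble a verifier ensemble
#' @param windows list of event windows
#' @return matrix (events x classes) of ensemble-mean probabilities
#' @export
verifier_probs <- function(ensemble, windows) {
  X <- window_stack(windows)
  verifier_check_shape(ensemble, X)
  p <- t(ensemble_probs(ensemble$members, X))
  colnames(p) <- ensemble$classes
  p
}

#' Sweep the verification threshold
#'
#' Varies the speech-probability threshold over \[0, 1\] and reports the
#' false-positive rate (non-speech events accepted) and false-negative rate
#' (speech events rejected), both as proportions of all evaluated events.
#'
#' @param ensemble a verifier ensemble
#' @param windows list of event windows
#' @param is_speech logical: which events are true speech attempts
#' @param thetas threshold grid
#' @return data.frame with `theta`, `fp_rate`, `fn_rate`
#' @export
threshold_sweep <- function(ensemble, windows, is_speech,
                            thetas = seq(0, 1, by = 0.01)) {
  if (!length(windows)) stop("no events to sweep")
  p <- verifier_probs(ensemble, windows)[, "speech"]
  n <- length(p)
  data.frame(theta = thetas,
             fp_rate = vapply(thetas, function(th) sum(!is_speech & p > th) / n,
                              numeric(1)),
             fn_rate = vapply(thetas, function(th) sum(is_speech & p <= th) / n,
                              numeric(1)))
}

# truncate windows at d* + L (keep only samples with relative time < L)
truncate_windows <- function(windows, spec, L) {
  if (L > spec$end) stop("context length exceeds the window end")
  lapply(windows, function(w) {
    rt <- attr(w, "rel_time")
    keep <- which(rt < L)
    out <- w[keep, , , drop = FALSE]
    attr(out, "rel_time") <- rt[keep]
    out
  })
}

#' Verification accuracy versus post-onset context length
#'
#' For each context length L, retrains a verifier on windows truncated at
#' d* + L, picks the threshold minimizing FP + FN on a validation split, and
#' reports accept/reject accuracy on the test split.
#'
#' @param windows list of full event windows
#' @param task_labels verifier class labels per window
#' @param context_lengths seconds of post-onset context to keep
#' @param spec the [event_window_spec()] the windows were cut with
#' @param hyper,K,seed training settings
#' @return data.frame with `context`, `theta`, `accuracy`
#' @export
context_curve <- function(windows, task_labels, context_lengths,
                          spec = event_window_spec(), hyper = seqnet_hyper(),
                          K = 3, seed = 1) {
  task_labels <- as.character(task_labels)
  is_speech <- task_labels == "speech"
  n <- length(windows)
  grp <- with_seed(seed, sample(rep_len(c(1, 1, 1, 2, 3), n)))
  out <- data.frame(context = numeric(0), theta = numeric(0),
                    accuracy = numeric(0))
  for (L in context_lengths) {
    tw <- truncate_windows(windows, spec, L)
    ens <- fit_verifier(tw[grp == 1], task_labels[grp == 1], hyper = hyper,
                        K = K, seed = seed)
    pv <- verifier_probs(ens, tw[grp == 2])[, "speech"]
    cand <- sort(unique(c(0, pv, 1)))
    costs <- vapply(cand, function(th)
      sum(!is_speech[grp == 2] & pv > th) + sum(is_speech[grp == 2] & pv <= th),
      numeric(1))
    th <- cand[which.min(costs)]
    pt <- verifier_probs(ens, tw[grp == 3])[, "speech"]
    acc <- mean((pt > th) == is_speech[grp == 3])
    out[nrow(out) + 1L, ] <- c(L, th, acc)
  }
  out
}
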