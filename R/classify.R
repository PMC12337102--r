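# Closed-vocabulary word classification of verified event windows, plus the
# time-window retraining and electrode-set ablations used to probe motor
# planning.

#' Train the word-classification ensemble
#'
#' K randomly initialized conv+GRU models map an event window to a
#' distribution over the closed vocabulary; ensemble probability is the mean
#' of member probabilities.
#'
#' @param windows list of event windows ([event_window()])
#' @param word_labels factor/character word label per window
#' @param hyper see [seqnet_hyper()]
#' @param K ensemble size (10 online; 5 per cross-validation fold)
#' @param electrode_mask optional logical keep-mask over electrodes; channels
#'   outside the mask are dropped before the first layer
#' @param seed RNG seed
#' @return a `word_classifier_ensemble`
#' @export
fit_classifier <- function(windows, word_labels, hyper = seqnet_hyper(), K = 10,
                           electrode_mask = NULL, seed = 1) {
  word_labels <- as.factor(word_labels)
  if (any(table(word_labels) < 2))
    stop("every vocabulary word needs at least 2 examples")
  X <- window_stack(windows, electrode_mask)
  y <- as.integer(word_labels)
  members <- fit_seq_ensemble(X, y, nlevels(word_labels), hyper, K, seed)
  structure(list(members = members, vocabulary = levels(word_labels),
                 electrode_mask = electrode_mask, n_features = dim(X)[1],
                 n_time = dim(X)[3], hyper = hyper),
            class = "word_classifier_ensemble")
}

#' Classify an event window into the vocabulary
#'
#' @param ensemble a [fit_classifier()] result
#' @param window a single event window (full electrode set; the ensemble's
#'   mask is applied internally)
#' @return list with `probs` (named, sums to 1) and `word` (argmax;
#'   lowest-index tie-break)
#' @export
classify <- function(ensemble, window) {
  X <- window_stack(list(window), ensemble$electrode_mask)
  if (dim(X)[1] != ensemble$n_features || dim(X)[3] != ensemble$n_time)
    stop("window shape does not match the ensemble's training shape")
  p <- ensemble_probs(ensemble$members, X)[, 1]
  names(p) <- ensemble$vocabulary
  list(probs = p, word = ensemble$vocabulary[which.max(p)])
}

#' Batch word predictions
#' @param ensemble a word classifier ensemble
#' @param windows list of event windows
#' @return character vector of predicted words
#' @export
classify_batch <- function(ensemble, windows) {
  X <- window_stack(windows, ensemble$electrode_mask)
  p <- ensemble_probs(ensemble$members, X)
  ensemble$vocabulary[apply(p, 2, which.max)]
}

# cut classification windows aligned to the go-cue of each speech trial
go_cue_windows <- function(session, window = c(-1, 3), factor = 6,
                           task = "speech") {
  tr <- session$trials[session$trials$task == task, ]
  spec <- event_window_spec(window[1], window[2], factor)
  list(windows = lapply(tr$go_cue, function(g) event_window(session, g, spec)),
       words = factor(tr$word), trials = tr$trial)
}

#' Time-window retraining with electrode-set ablations
#'
#' Retrains the word classifier on windows of neural activity relative to the
#' go-cue (by default \[-2,0\], \[-1,1\] and \[0,2\] s) under three electrode
#' conditions: all electrodes, shared electrodes removed, articulatory
#' electrodes removed. Reports cross-validated accuracy distributions per
#' window x condition and a per-electrode contribution map for the
#' all-electrode model.
#'
#' @param session a [neural_session()] with isolated-target speech trials
#' @param shared,articulatory integer electrode sets (must be disjoint)
#' @param windows list of 2-vectors, seconds relative to go-cue
#' @param hyper,folds,members_per_fold,seed cross-validation settings
#' @param factor downsampling factor for the windows
#' @return nested list: per window name, `accuracy` (per condition, vector of
#'   fold accuracies) and `contributions` (a [contributions()] map)
#' @export
timewindow_retrain <- function(session, shared, articulatory,
                               windows = list(c(-2, 0), c(-1, 1), c(0, 2)),
                               hyper = seqnet_hyper(), folds = 10,
                               members_per_fold = 5, seed = 1, factor = 6) {
  if (length(intersect(shared, articulatory)))
    stop("shared and articulatory electrode sets must be disjoint")
  E <- ncol(session$hga)
  masks <- list(all = rep(TRUE, E),
                no_shared = !(seq_len(E) %in% shared),
                no_articulatory = !(seq_len(E) %in% articulatory))
  out <- list()
  for (w in windows) {
    gw <- go_cue_windows(session, w, factor)
    acc <- lapply(masks, function(mk)
      crossval(gw$windows, gw$words, folds = folds,
               members_per_fold = members_per_fold, hyper = hyper,
               electrode_mask = mk, seed = seed))
    ens <- fit_classifier(gw$windows, gw$words, hyper = hyper, K = 1,
                          seed = seed)
    contrib <- contributions(ens, gw$windows, gw$words)
    out[[sprintf("[%g,%g]", w[1], w[2])]] <-
      list(window = w, accuracy = acc, contributions = contrib)
  }
  out
}

#' Cross-task word-decoding transfer
#'
#' Trains per-fold ensembles within task A and evaluates each fold's model on
#' the corresponding held-out fold of task B (and within A itself), probing
#' whether the two tasks use the same word code.
#'
#' @param windows_a,labels_a training-task windows and word labels
#' @param windows_b,labels_b transfer-task windows and word labels (same
#'   vocabulary)
#' @param folds,members_per_fold,hyper,seed cross-validation settings
#' @return list with per-fold `within` and `transfer` accuracies
#' @export
cross_task_transfer <- function(windows_a, labels_a, windows_b, labels_b,
                                folds = 5, members_per_fold = 2,
                                hyper = seqnet_hyper(), seed = 1) {
  labels_a <- as.factor(labels_a)
  labels_b <- factor(labels_b, levels = levels(labels_a))
  if (anyNA(labels_b)) stop("vocabulary mismatch between tasks")
  fold_a <- stratified_folds(labels_a, folds, seed)
  fold_b <- stratified_folds(labels_b, folds, seed + 1L)
  Xa <- window_stack(windows_a)
  Xb <- window_stack(windows_b)
  ya <- as.integer(labels_a)
  yb <- as.integer(labels_b)
  within <- numeric(folds)
  transfer <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_a != f)
    members <- fit_seq_ensemble(Xa[, tr, , drop = FALSE], ya[tr],
                                nlevels(labels_a), hyper, members_per_fold,
                                seed + 100L * f)
    pa <- ensemble_probs(members, Xa[, fold_a == f, , drop = FALSE])
    within[f] <- mean(apply(pa, 2, which.max) == ya[fold_a == f])
    pb <- ensemble_probs(members, Xb[, fold_b == f, , drop = FALSE])
    transfer[f] <- mean(apply(pb, 2, which.max) == yb[fold_b == f])
  }
  list(within = within, transfer = transfer)
}
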