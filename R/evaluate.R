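# End-to-end scoring: event matching with the counted-once duplicate rule,
# TPR/FPR, pseudo-blocks, cross-validation, and the nonparametric statistics
# used throughout (Fisher exact, Holm-Bonferroni, permutation correlations).

#' Match detected events to true speech attempts
#'
#' A detection is assigned to the nearest attempt whose onset lies within
#' `tol` seconds of the detection onset (exact tie: the earlier attempt).
#' For each attempt with one or more assigned detections, the earliest is a
#' TP and the rest are duplicate-TPs; unassigned detections are FPs.
#'
#' @param true_attempts data.frame with column `onset` (non-overlapping)
#' @param detections data.frame with column `onset`
#' @param tol matching tolerance in seconds (default 0.5)
#' @return a `match_result` list: `assigned` (attempt index or NA per
#'   detection), `status` (TP/duplicate-TP/FP per detection),
#'   `attempt_matched` (logical per attempt), `tolerance`
#' @export
match_events <- function(true_attempts, detections, tol = 0.5) {
  if (tol < 0) stop("tolerance must be non-negative")
  ta <- if (is.data.frame(true_attempts)) true_attempts$onset else as.numeric(true_attempts)
  dt <- if (is.data.frame(detections)) detections$onset else as.numeric(detections)
  nd <- length(dt)
  assigned <- rep(NA_integer_, nd)
  if (length(ta) && nd) {
    for (i in seq_len(nd)) {
      d <- abs(ta - dt[i])
      j <- which(d <= min(d) + 1e-9)[1]  # ties (within fp noise) -> earliest
      if (d[j] <= tol) assigned[i] <- j
    }
  }
  status <- rep("FP", nd)
  matched <- rep(FALSE, length(ta))
  for (j in unique(assigned[!is.na(assigned)])) {
    k <- which(assigned == j)
    first <- k[which.min(dt[k])]
    status[first] <- "TP"
    status[setdiff(k, first)] <- "duplicate-TP"
    matched[j] <- TRUE
  }
  structure(list(assigned = assigned, status = status,
                 attempt_matched = matched, tolerance = tol),
            class = "match_result")
}

#' Compute TPR/FPR from a match result
#'
#' TPR = matched attempts / attempts. FPR = FP / (FP + matched attempts):
#' duplicate detections of one attempt are counted once in the denominator,
#' so duplicates change neither rate. Empty detections give FPR 0; TPR is 0
#' by convention when there are no attempts.
#'
#' @param match a [match_events()] result
#' @return an `eval_report` list of counts and rates
#' @export
compute_rates <- function(match) {
  stopifnot(inherits(match, "match_result"))
  n_att <- length(match$attempt_matched)
  n_tp <- sum(match$attempt_matched)
  n_fp <- sum(match$status == "FP")
  n_dup <- sum(match$status == "duplicate-TP")
  denom <- n_fp + n_tp
  structure(list(attempts = n_att, detections = length(match$status),
                 TP = n_tp, FP = n_fp, duplicates = n_dup,
                 TPR = if (n_att > 0) n_tp / n_att else 0,
                 FPR = if (denom > 0) n_fp / denom else 0),
            class = "eval_report")
}

#' Split trial outcomes into consecutive pseudo-blocks
#'
#' Used only for visualizing metric variability (never for inference). Sizes
#' differ by at most one.
#'
#' @param x vector of per-trial outcomes
#' @param k number of pseudo-blocks (default 6)
#' @param metric function applied per block (default mean)
#' @return numeric vector of k per-block metrics
#' @export
pseudo_blocks <- function(x, k = 6, metric = mean) {
  if (k <= 0) stop("k must be positive")
  n <- length(x)
  if (k > n) stop("k exceeds the number of trials")
  big <- n %% k
  sizes <- c(rep(ceiling(n / k), big), rep(floor(n / k), k - big))
  idx <- split(seq_len(n), rep(seq_len(k), sizes))
  vapply(idx, function(i) metric(x[i]), numeric(1))
}

#' Two-sided Fisher exact comparison of two proportions
#'
#' @param a_success,a_total,b_success,b_total counts
#' @return two-sided exact p-value
#' @export
fisher_compare <- function(a_success, a_total, b_success, b_total) {
  cnt <- c(a_success, a_total, b_success, b_total)
  if (any(cnt < 0) || a_success > a_total || b_success > b_total)
    stop("invalid counts")
  tab <- matrix(c(a_success, a_total - a_success,
                  b_success, b_total - b_success), 2)
  fisher.test(tab)$p.value
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p vector of raw p-values in \[0,1\]
#' @return adjusted p-values (monotone, capped at 1), in the input order
#' @export
holm_bonferroni <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Correlation with a permutation p-value
#'
#' The p-value is the add-one-corrected proportion of label permutations whose
#' absolute correlation is at least the observed one.
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-constant)
#' @param method `"spearman"` or `"pearson"`
#' @param n_perm number of permutations (default 1000)
#' @param seed RNG seed
#' @return list with `r` and `p`
#' @export
correlation_permutation <- function(x, y, method = c("spearman", "pearson"),
                                    n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) stop("need equal lengths >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
  r <- cor(x, y, method = method)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      rp <- cor(x, sample(y), method = method)
      if (abs(rp) >= abs(r) - 1e-12) hits <- hits + 1L
    }
    list(r = r, p = (1 + hits) / (n_perm + 1))
  })
}

#' Stratified k-fold assignment
#' @param labels class labels
#' @param folds number of folds
#' @param seed RNG seed
#' @return integer fold id per observation
#' @export
stratified_folds <- function(labels, folds = 10, seed = 1) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      i <- sample(which(labels == cl))
      fold[i] <- rep_len(seq_len(folds), length(i))
    }
  })
  fold
}

#' Cross-validated word-classification accuracy
#'
#' In each of `folds` folds, 90% of trials train an ensemble of
#' `members_per_fold` randomly initialized models (10% of the training split
#' is held out as a validation set for early stopping) and the remaining 10%
#' are scored by the ensemble-mean probabilities.
#'
#' @param windows list of event windows (see [event_window()])
#' @param labels word labels (factor or character)
#' @param folds number of folds (>= 2), stratified by word
#' @param members_per_fold ensemble size per fold
#' @param hyper see [seqnet_hyper()]
#' @param electrode_mask optional logical keep-mask over electrodes
#' @param seed RNG seed
#' @return numeric vector of per-fold accuracies
#' @export
crossval <- function(windows, labels, folds = 10, members_per_fold = 5,
                     hyper = seqnet_hyper(), electrode_mask = NULL, seed = 1) {
  if (folds < 2) stop("need at least 2 folds")
  labels <- as.factor(labels)
  fold <- stratified_folds(labels, folds, seed)
  X <- window_stack(windows, electrode_mask)
  y <- as.integer(labels)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    val <- with_seed(seed + 31L * f, sample(tr, max(1, round(0.1 * length(tr)))))
    tr2 <- setdiff(tr, val)
    probs <- 0
    for (m in seq_len(members_per_fold)) {
      ms <- seed + 1000L * f + m
      params <- init_seqnet(dim(X)[1], hyper$conv_channels, hyper$kern,
                            hyper$stride, hyper$hidden, hyper$n_layers,
                            nlevels(labels), seed = ms)
      fit <- train_seqnet(params, X[, tr2, , drop = FALSE], y[tr2],
                          epochs = hyper$epochs, lr = hyper$lr,
                          batch_size = hyper$batch_size, seed = ms + 1L,
                          X_val = X[, val, , drop = FALSE], y_val = y[val],
                          patience = hyper$patience,
                          weight_decay = hyper$weight_decay %||% 0)
      probs <- probs + seqnet_probs(fit$params, X[, te, , drop = FALSE])
    }
    pred <- apply(probs, 2, which.max)
    acc[f] <- mean(pred == y[te])
  }
  acc
}
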