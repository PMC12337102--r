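# Offline neural analyses: per-task electrode responsiveness (rank-sum with
# Holm correction), shared-set identification, gradient-based electrode
# contributions, multitaper band-power contrasts, and longform activation
# tests.

#' Wilcoxon rank-sum Z statistic (normal approximation, tie-corrected)
#'
#' One-sided test of `post` being stochastically greater than `pre`.
#'
#' @param post,pre numeric samples
#' @return list with `z` and one-sided `p`
#' @export
ranksum_z <- function(post, pre) {
  n1 <- length(post)
  n2 <- length(pre)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  all <- c(post, pre)
  rk <- rank(all)
  W <- sum(rk[seq_len(n1)])
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(all)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
  z <- (W - mu) / sig
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

task_post_window <- function(task) {
  if (task == "listening") c(0.5, 1) else c(0, 1)
}

#' Per-electrode responsiveness map for a task
#'
#' Each trial is z-scored to its silent pre-stimulus baseline; the per-trial
#' mean HGA in the pre-stimulus window is compared to the mean HGA after
#' response onset (\[0,1\] s after go-cue for attempted speech and reading,
#' \[0.5,1\] s after stimulus onset for listening) with a one-sided rank-sum
#' test per electrode, Holm-corrected across electrodes.
#'
#' @param session a [neural_session()]
#' @param task `"speech"`, `"reading"` or `"listening"`
#' @param alpha significance level after correction (default 0.05)
#' @param pre_window pre-stimulus comparison window relative to presentation,
#'   seconds
#' @param baseline_window silent inter-trial window used for the per-trial
#'   z-score; kept disjoint from `pre_window` so that the pre-stimulus sample
#'   stays exchangeable with the post-onset sample under the null
#' @param post_window override of the task analysis window (relative to
#'   go-cue/onset)
#' @return a `responsiveness_map` data.frame: per electrode `z`, `stat`
#'   (z clipped at 0 for display), `p`, `p_adj`, `significant`
#' @export
responsiveness <- function(session, task, alpha = 0.05,
                           pre_window = c(-1, 0),
                           baseline_window = c(-2, -1), post_window = NULL) {
  tr <- session$trials[session$trials$task == task, ]
  if (nrow(tr) < 2) stop("fewer than 2 trials for task ", task)
  if (is.null(post_window)) post_window <- task_post_window(task)
  fs <- session$sample_rate_hz
  E <- ncol(session$hga)
  pre_means <- matrix(NA_real_, nrow(tr), E)
  post_means <- matrix(NA_real_, nrow(tr), E)
  for (i in seq_len(nrow(tr))) {
    z0 <- round((tr$presentation[i] + baseline_window[1]) * fs) + 1L
    z1 <- round((tr$presentation[i] + baseline_window[2]) * fs)
    b0 <- round((tr$presentation[i] + pre_window[1]) * fs) + 1L
    b1 <- round((tr$presentation[i] + pre_window[2]) * fs)
    anchor <- if (task == "speech") tr$go_cue[i] else tr$onset[i]
    p0 <- round((anchor + post_window[1]) * fs) + 1L
    p1 <- round((anchor + post_window[2]) * fs)
    i0 <- min(z0, b0, p0)
    i1 <- max(z1, b1, p1)
    if (i0 < 1 || i1 > session_length(session)) next
    seg <- trial_zscore(session$hga[i0:i1, , drop = FALSE], (z0:z1) - i0 + 1L)
    pre_means[i, ] <- colMeans(seg[(b0:b1) - i0 + 1L, , drop = FALSE])
    post_means[i, ] <- colMeans(seg[(p0:p1) - i0 + 1L, , drop = FALSE])
  }
  ok <- stats::complete.cases(pre_means)
  z <- numeric(E)
  p <- numeric(E)
  for (e in seq_len(E)) {
    r <- ranksum_z(post_means[ok, e], pre_means[ok, e])
    z[e] <- r$z
    p[e] <- r$p
  }
  p_adj <- holm_bonferroni(p)
  structure(data.frame(electrode = seq_len(E), region = session$electrode_map,
                       z = z, stat = pmax(z, 0), p = p, p_adj = p_adj,
                       significant = p_adj < alpha & z > 0),
            class = c("responsiveness_map", "data.frame"),
            task = task, alpha = alpha,
            windows = list(pre = pre_window, post = post_window))
}

#' Shared-electrode set from per-task responsiveness maps
#'
#' Shared electrodes are those significantly activated by all of attempted
#' speech, reading, and listening. The articulatory set is external (prior
#' encoding estimates or simulator ground truth).
#'
#' @param maps named list of [responsiveness()] maps with entries `speech`,
#'   `reading`, `listening`
#' @param articulatory optional integer electrode set
#' @return an `electrode_sets` list: `shared`, `articulatory`, `by_task`
#' @export
shared_set <- function(maps, articulatory = NULL) {
  need <- c("speech", "reading", "listening")
  if (!all(need %in% names(maps))) stop("maps must cover speech, reading, listening")
  sig <- lapply(maps[need], function(m) m$electrode[m$significant])
  structure(list(shared = Reduce(intersect, sig),
                 articulatory = articulatory, by_task = sig),
            class = "electrode_sets")
}

#' Gradient-based electrode contributions
#'
#' Takes the derivative of the model's loss (at the true labels) with respect
#' to the input features over time, the L2 norm over the time dimension per
#' electrode and band, and averages across time courses (trials for the
#' verifier/classifier, whole blocks for the detector). HGA and LFS
#' sub-scores are reported separately and summed.
#'
#' @param model a `word_classifier_ensemble`, `verifier_ensemble`, or
#'   `detector_model`
#' @param data list of event windows (ensembles) or a [neural_session()] /
#'   list of sessions (detector)
#' @param labels true labels per window (ensembles)
#' @param ... unused
#' @return a `contribution_map` data.frame: per electrode `hga`, `lfs`,
#'   `total`
#' @export
contributions <- function(model, data, labels = NULL, ...) {
  UseMethod("contributions")
}

seq_ensemble_contrib <- function(members, X, y, E_keep) {
  acc_h <- 0
  acc_l <- 0
  for (m in members) {
    dX <- seqnet_input_grad(m, X, y)  # (2E, B, T)
    l2 <- sqrt(apply(dX^2, c(1, 2), sum))  # 2E x B
    acc_h <- acc_h + rowMeans(l2[seq_len(E_keep), , drop = FALSE])
    acc_l <- acc_l + rowMeans(l2[E_keep + seq_len(E_keep), , drop = FALSE])
  }
  list(hga = acc_h / length(members), lfs = acc_l / length(members))
}

contrib_frame <- function(hga, lfs, keep, E) {
  h <- numeric(E)
  l <- numeric(E)
  h[keep] <- hga
  l[keep] <- lfs
  structure(data.frame(electrode = seq_len(E), hga = h, lfs = l,
                       total = h + l),
            class = c("contribution_map", "data.frame"))
}

#' @export
contributions.word_classifier_ensemble <- function(model, data, labels = NULL, ...) {
  if (is.null(labels)) stop("true labels are required for the loss gradient")
  y <- as.integer(factor(as.character(labels), levels = model$vocabulary))
  w1 <- data[[1]]
  E <- dim(w1)[2]
  keep <- which(model$electrode_mask %||% rep(TRUE, E))
  X <- window_stack(data, model$electrode_mask)
  cc <- seq_ensemble_contrib(model$members, X, y, length(keep))
  contrib_frame(cc$hga, cc$lfs, keep, E)
}

#' @export
contributions.verifier_ensemble <- function(model, data, labels = NULL, ...) {
  if (is.null(labels)) stop("true labels are required for the loss gradient")
  y <- match(as.character(labels), model$classes)
  E <- dim(data[[1]])[2]
  X <- window_stack(data)
  cc <- seq_ensemble_contrib(model$members, X, y, E)
  contrib_frame(cc$hga, cc$lfs, seq_len(E), E)
}

#' @export
contributions.detector_model <- function(model, data, labels = NULL, ...) {
  if (inherits(data, "neural_session")) data <- list(data)
  E <- ncol(data[[1]]$hga)
  acc_h <- 0
  acc_l <- 0
  for (s in data) {
    feats <- session_features(s)
    X <- array(t(feats), c(ncol(feats), 1, nrow(feats)))
    Y <- matrix(as.integer(s$labels), ncol = 1)
    M <- matrix(as.integer(s$train_mask), ncol = 1)
    dX <- lstm_input_grad(model$params, X, Y, M)  # (2E, 1, T)
    l2 <- sqrt(apply(dX^2, 1, sum))
    acc_h <- acc_h + l2[seq_len(E)]
    acc_l <- acc_l + l2[E + seq_len(E)]
  }
  contrib_frame(acc_h / length(data), acc_l / length(data), seq_len(E), E)
}

# ---- multitaper spectral estimation ----------------------------------------

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal formulation; tapers are
#' unit-norm columns ordered by decreasing eigenvalue.
#'
#' @param n taper length in samples
#' @param nw time-bandwidth product (default 3)
#' @param k number of tapers (default 5)
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  W <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- diag(diag_main)
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper mean band power of a signal segment
#'
#' Band power is the two-sided-corrected sum of the tapered spectral
#' estimates over the in-band FFT bins; for a sinusoid of amplitude a inside
#' the band it approaches a^2/2.
#'
#' @param x numeric signal segment
#' @param fs sampling rate
#' @param band 2-vector of band edges in Hz (within (0, fs/2))
#' @param nw,k multitaper parameters
#' @export
multitaper_band_power <- function(x, fs, band, nw = 3, k = 5) {
  n <- length(x)
  if (band[2] >= fs / 2 || band[1] <= 0) stop("band outside (0, Nyquist)")
  tap <- dpss_tapers(n, nw, k)
  freqs <- (0:(n - 1)) * fs / n
  sel <- which(freqs >= band[1] & freqs <= band[2] & freqs < fs / 2)
  pw <- 0
  for (j in seq_len(k)) {
    Y <- fft(x * tap[, j])
    pw <- pw + 2 * sum(Mod(Y[sel])^2) / n
  }
  pw / k
}

#' Spectral analysis configuration
#' @param theta,beta band edges in Hz
#' @param window analysis window relative to go-cue/onset, seconds
#' @param block_size trials per pseudo-block (default 60)
#' @param nw,k multitaper parameters
#' @export
spectral_config <- function(theta = c(5, 12), beta = c(20, 30),
                            window = c(0, 2), block_size = 60, nw = 3, k = 5) {
  list(theta = theta, beta = beta, window = window, block_size = block_size,
       nw = nw, k = k)
}

#' Pseudo-blocked z-scored band power per task
#'
#' For every trial, the multitaper mean LFS power in the theta and beta bands
#' over the analysis window (from go-cue for attempted speech, stimulus onset
#' otherwise), averaged over `electrodes`. Trial powers are averaged over
#' consecutive non-overlapping pseudo-blocks and the pooled distribution
#' across tasks is z-scored per band.
#'
#' @param session a [neural_session()]
#' @param tasks tasks to contrast
#' @param cfg a [spectral_config()]
#' @param electrodes electrode subset (default all)
#' @return data.frame with `task`, `band`, `block`, `power_z`
#' @export
band_power <- function(session, tasks = c("speech", "reading", "listening"),
                       cfg = spectral_config(), electrodes = NULL) {
  fs <- session$sample_rate_hz
  if (cfg$theta[2] >= fs / 2 || cfg$beta[2] >= fs / 2)
    stop("band outside Nyquist range")
  if (is.null(electrodes)) electrodes <- seq_len(ncol(session$lfs))
  rows <- list()
  for (tk in tasks) {
    tr <- session$trials[session$trials$task == tk, ]
    if (!nrow(tr)) next
    pt <- matrix(NA_real_, nrow(tr), 2)
    for (i in seq_len(nrow(tr))) {
      anchor <- if (tk == "speech") tr$go_cue[i] else tr$onset[i]
      i0 <- round((anchor + cfg$window[1]) * fs) + 1L
      i1 <- round((anchor + cfg$window[2]) * fs)
      if (i0 < 1 || i1 > session_length(session)) next
      th <- vapply(electrodes, function(e)
        multitaper_band_power(session$lfs[i0:i1, e], fs, cfg$theta, cfg$nw, cfg$k),
        numeric(1))
      be <- vapply(electrodes, function(e)
        multitaper_band_power(session$lfs[i0:i1, e], fs, cfg$beta, cfg$nw, cfg$k),
        numeric(1))
      pt[i, ] <- c(mean(th), mean(be))
    }
    pt <- pt[stats::complete.cases(pt), , drop = FALSE]
    nb <- floor(nrow(pt) / cfg$block_size)
    if (nb < 1) stop("need at least one full pseudo-block of trials for task ", tk)
    for (b in seq_len(nb)) {
      j <- ((b - 1) * cfg$block_size + 1):(b * cfg$block_size)
      rows[[length(rows) + 1]] <- data.frame(task = tk, block = b,
                                             theta = mean(pt[j, 1]),
                                             beta = mean(pt[j, 2]))
    }
  }
  d <- do.call(rbind, rows)
  out <- rbind(data.frame(task = d$task, band = "theta", block = d$block,
                          power = d$theta),
               data.frame(task = d$task, band = "beta", block = d$block,
                          power = d$beta))
  out$power_z <- NA_real_
  for (bd in unique(out$band)) {
    i <- out$band == bd
    out$power_z[i] <- (out$power[i] - mean(out$power[i])) / sd(out$power[i])
  }
  out
}

#' Longform versus baseline activation test
#'
#' Samples `n_points` random time points (with replacement) in each session,
#' averages HGA over the surrounding `window_s` window per electrode, and
#' compares longform to baseline with one-sided rank-sum tests, Holm-corrected
#' across electrodes.
#'
#' @param longform_session,baseline_session [neural_session()]s
#' @param n_points samples per session (default 100; must be >= 2)
#' @param window_s averaging window, seconds
#' @param alpha significance level
#' @param seed RNG seed for the sampling
#' @return data.frame per electrode: `z`, `p`, `p_adj`, `significant`
#' @export
longform_activation <- function(longform_session, baseline_session,
                                n_points = 100, window_s = 4, alpha = 0.05,
                                seed = 1) {
  if (n_points < 2) stop("need at least 2 sampled time points")
  fs <- longform_session$sample_rate_hz
  half <- round(window_s / 2 * fs)
  sample_means <- function(s, seed_k) {
    n <- session_length(s)
    if (n < 2 * half + 1) stop("session shorter than the averaging window")
    ctr <- with_seed(seed_k, sample((half + 1):(n - half), n_points,
                                    replace = TRUE))
    t(vapply(ctr, function(c0)
      colMeans(s$hga[(c0 - half):(c0 + half), , drop = FALSE]),
      numeric(ncol(s$hga))))
  }
  lf <- sample_means(longform_session, seed)
  bl <- sample_means(baseline_session, seed + 1L)
  E <- ncol(lf)
  z <- numeric(E)
  p <- numeric(E)
  for (e in seq_len(E)) {
    r <- ranksum_z(lf[, e], bl[, e])
    z[e] <- r$z
    p[e] <- r$p
  }
  p_adj <- holm_bonferroni(p)
  data.frame(electrode = seq_len(E), z = z, p = p, p_adj = p_adj,
             significant = p_adj < alpha & z > 0)
}
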