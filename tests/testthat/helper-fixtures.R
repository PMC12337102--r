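# Shared fixtures (memoized so expensive simulations/models are built once per
# test run) and independent oracles used across test files.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small mixed-task session for shape/window/detector plumbing tests
fx_small <- function() fx("small", function()
  simulate_session(sim_config(
    n_electrodes = 12,
    schedule = list(type = "isolated_target",
                    task = c("speech", "reading", "listening"), n_trials = 24),
    seed = 101)))

# 201-trial mixed session at the stated-world SNR: responsiveness / shared-set
# / band-power recovery
fx_mixed201 <- function() fx("mixed201", function()
  simulate_session(sim_config(
    n_electrodes = 32,
    schedule = list(type = "isolated_target",
                    task = c("speech", "reading", "listening"),
                    n_trials = 201),
    seed = 11)))

# high-SNR isolated speech set for classifier-based checks ("high-SNR"
# fixture: snr = 2, everything else stated-world)
fx_speech300 <- function() fx("speech300", function()
  simulate_session(sim_config(
    n_electrodes = 16,
    schedule = list(type = "isolated_target", task = "speech",
                    n_trials = 300),
    snr = 2, seed = 21)))

fx_speech300_windows <- function() fx("speech300_windows", function() {
  s <- fx_speech300()
  tr <- s$trials[s$trials$task == "speech", ]
  spec <- event_window_spec(-1, 3, 6)
  list(windows = lapply(tr$go_cue, function(g) event_window(s, g, spec)),
       words = factor(tr$word))
})

# small trained detector (mixed tasks, high SNR) shared across detect tests
fx_detector <- function() fx("detector", function() {
  s <- simulate_session(sim_config(
    n_electrodes = 12,
    schedule = list(type = "isolated_target",
                    task = c("speech", "reading", "listening"), n_trials = 36),
    snr = 2, seed = 55))
  hy <- detector_hyper(hidden = 32, n_layers = 3, epochs = 28, lr = 2e-3,
                       chunk_s = 10, batch_size = 16)
  list(session = s, model = fit_detector(s, hyper = hy, seed = 5),
       hyper = hy)
})

# verifier training windows + a small trained ensemble (high SNR)
fx_verifier <- function() fx("verifier", function() {
  s <- simulate_session(sim_config(
    n_electrodes = 12,
    schedule = list(type = "isolated_target",
                    task = c("speech", "reading", "listening"), n_trials = 120),
    snr = 2, seed = 77))
  tr <- s$trials
  spec <- event_window_spec(-1, 3, 6)
  keep <- which(tr$onset + spec$start > 0 &
                  tr$onset + spec$end < nrow(s$hga) / 200)
  windows <- lapply(tr$onset[keep], function(d) event_window(s, d, spec))
  labels <- tr$task[keep]
  hy <- seqnet_hyper(conv_channels = 8, kern = 7, stride = 3, hidden = 16,
                     epochs = 20, lr = 2e-3, batch_size = 16,
                     weight_decay = 0.3)
  set.seed(9)
  te <- sample(length(windows), 24)
  trn <- setdiff(seq_along(windows), te)
  ens <- fit_verifier(windows[trn], labels[trn], hyper = hy, K = 3, seed = 3)
  list(session = s, windows = windows, labels = labels, spec = spec,
       hyper = hy, train = trn, test = te, ensemble = ens)
})

# default hyper for classifier-style tests (desk scale)
fx_cls_hyper <- function()
  seqnet_hyper(conv_channels = 8, kern = 7, stride = 3, hidden = 16,
               epochs = 30, lr = 2e-3, batch_size = 16, weight_decay = 0.3)

# ---- independent oracles ----------------------------------------------------

# per-sample state-machine oracle for event extraction on a BINARY trace
oracle_extract <- function(b, t_on, t_off, fs = 200) {
  n <- length(b)
  events <- list()
  state <- "off"
  ones <- 0L
  zeros <- 0L
  run_start <- NA_integer_
  ev_on <- NA_integer_
  last_one <- NA_integer_
  for (i in seq_len(n)) {
    if (b[i]) {
      if (ones == 0L) run_start <- i
      ones <- ones + 1L
      zeros <- 0L
      if (state == "off" && ones >= t_on) {
        state <- "on"
        ev_on <- run_start
      }
      if (state == "on") last_one <- i
    } else {
      zeros <- zeros + 1L
      ones <- 0L
      if (state == "on" && zeros >= t_off) {
        events[[length(events) + 1]] <- c(ev_on, last_one)
        state <- "off"
      }
    }
  }
  if (state == "on") events[[length(events) + 1]] <- c(ev_on, last_one)
  if (!length(events))
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  m <- do.call(rbind, events)
  data.frame(onset = (m[, 1] - 1) / fs, offset = (m[, 2] - 1) / fs)
}

# exhaustive two-sided Fisher p over tables with fixed margins
oracle_fisher <- function(a, at, b, bt) {
  m <- a + b            # total successes
  n <- at + bt - m      # total failures
  k <- at               # draws
  kk <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(kk, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force FFT band filter + analytic envelope at the native rate,
# written independently of the package's filtering code
oracle_envelope <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- fft(x)
  f <- (0:(n - 1)) * fs / n
  f2 <- pmin(f, fs - f)
  X[!(f2 >= lo & f2 <= hi)] <- 0
  pos <- f > 0 & f < fs / 2
  neg <- f > fs / 2
  Xa <- X
  Xa[pos] <- 2 * Xa[pos]
  Xa[neg] <- 0
  Mod(fft(Xa, inverse = TRUE) / n)
}
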