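# Feature extraction: common-average referencing, band extraction of the
# high-gamma amplitude (HGA, 70-150 Hz envelope) and low-frequency signal
# (LFS, 1-100 Hz) at 200 Hz, streaming/trial normalization, and artifact
# screening.

ECOG_REGIONS <- c("midPrCG", "PrCG", "PoCG", "temporal", "frontal", "other")

#' Construct a raw multichannel recording
#'
#' @param voltage time x electrode numeric matrix (arbitrary units)
#' @param sample_rate_hz sampling rate, must be at least 400 Hz
#' @param electrode_map per-electrode anatomical region label
#' @export
raw_recording <- function(voltage, sample_rate_hz, electrode_map) {
  voltage <- as.matrix(voltage)
  if (anyNA(voltage)) stop("voltage contains NaN/NA")
  if (sample_rate_hz < 400) stop("sample_rate_hz must be >= 400 (Nyquist for the 150 Hz band edge)")
  if (length(electrode_map) != ncol(voltage))
    stop("electrode_map length must equal the electrode count")
  if (!all(electrode_map %in% ECOG_REGIONS))
    stop("unknown region label in electrode_map")
  structure(list(voltage = voltage, sample_rate_hz = sample_rate_hz,
                 electrode_map = as.character(electrode_map)),
            class = "raw_recording")
}

#' Construct a 200 Hz neural feature stream
#'
#' @param values time x electrode matrix of normalized features (z-units)
#' @param band `"HGA"` or `"LFS"`
#' @param sample_rate_hz fixed at 200
#' @export
feature_stream <- function(values, band = c("HGA", "LFS"), sample_rate_hz = 200) {
  band <- match.arg(band)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("feature stream must be finite")
  structure(values, band = band, sample_rate_hz = sample_rate_hz,
            class = c("feature_stream", "matrix", "array"))
}

#' Common-average reference
#'
#' Subtracts, at every time point, the mean across electrodes. Idempotent.
#'
#' @param raw a [raw_recording()]
#' @return the referenced recording
#' @export
common_average_reference <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  if (ncol(raw$voltage) < 2)
    stop("common-average reference is undefined for a single electrode")
  raw$voltage <- raw$voltage - rowMeans(raw$voltage)
  raw
}

# ---- FIR design and application --------------------------------------------

# linear-phase windowed-sinc band-pass taps; lo = 0 gives a low-pass
fir_bandpass <- function(fs, lo, hi, ntaps) {
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  n <- -m:m
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  f1 <- lo / fs
  f2 <- hi / fs
  h <- 2 * f2 * sinc(2 * f2 * n)
  if (lo > 0) h <- h - 2 * f1 * sinc(2 * f1 * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)  # Hamming
  h * w
}

# FFT convolution; zero-phase mode compensates the (L-1)/2 group delay exactly
apply_fir <- function(x, h, causal = FALSE) {
  n <- length(x)
  L <- length(h)
  nf <- stats::nextn(n + L - 1, 2)
  y <- Re(fft(fft(c(x, rep(0, nf - n))) * fft(c(h, rep(0, nf - L))),
              inverse = TRUE)) / nf
  if (causal) y[seq_len(n)] else y[(L - 1) / 2 + seq_len(n)]
}

# amplitude of the analytic signal (discrete Hilbert transform)
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  mult <- numeric(n)
  mult[1] <- 1
  if (n %% 2 == 0) {
    mult[n / 2 + 1] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * mult, inverse = TRUE) / n)
}

resample_to <- function(x, fs, out_fs = 200) {
  n_out <- round(length(x) / fs * out_fs)
  t_in <- (seq_along(x) - 1) / fs
  t_out <- (seq_len(n_out) - 1) / out_fs
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Extract HGA and LFS feature streams from a raw recording
#'
#' Band-passes each electrode to 70-150 Hz and takes the analytic-signal
#' amplitude (HGA), band-limits to `lfs_low`-100 Hz (LFS), and resamples both
#' to 200 Hz. Filters are linear-phase windowed-sinc FIR applied either with
#' exact group-delay compensation (`causal = FALSE`, offline/zero-phase) or
#' causally (streaming).
#'
#' @param raw a [raw_recording()] of at least 1 s
#' @param lfs_low lower band edge of the LFS in Hz (default 1)
#' @param causal apply filters causally instead of zero-phase
#' @return list with elements `hga` and `lfs`, both [feature_stream()]s
#' @export
extract_feature_streams <- function(raw, lfs_low = 1, causal = FALSE) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sample_rate_hz
  if (fs < 400) stop("sample rate below 400 Hz")
  n <- nrow(raw$voltage)
  if (n / fs < 1) stop("recording must be at least 1 s long")
  h_hg <- fir_bandpass(fs, 70, 150, 2 * floor(0.1 * fs) + 1)
  h_lf <- fir_bandpass(fs, lfs_low, 100,
                       min(2 * floor(1.65 * fs / max(lfs_low, 0.5)) + 1,
                           2 * floor(3.5 * fs) + 1))
  n_out <- round(n / fs * 200)
  E <- ncol(raw$voltage)
  hga <- matrix(0, n_out, E)
  lfs <- matrix(0, n_out, E)
  for (e in seq_len(E)) {
    v <- raw$voltage[, e]
    hg <- hilbert_envelope(apply_fir(v, h_hg, causal))
    lf <- apply_fir(v, h_lf, causal)
    hga[, e] <- resample_to(hg, fs)
    lfs[, e] <- resample_to(lf, fs)
  }
  list(hga = feature_stream(hga, "HGA"), lfs = feature_stream(lfs, "LFS"))
}

#' Causal sliding-window z-score
#'
#' Normalizes each channel by the mean and standard deviation of the trailing
#' `window_s` seconds (growing window during warm-up). The standard deviation
#' is floored at `std_floor`, so constant channels map to 0.
#'
#' @param values time x electrode matrix
#' @param window_s window length in seconds (default 30)
#' @param fs sampling rate in Hz
#' @param std_floor lower bound on the running standard deviation
#' @export
sliding_zscore <- function(values, window_s = 30, fs = 200, std_floor = 1e-6) {
  x <- as.matrix(values)
  n <- nrow(x)
  w <- round(window_s * fs)
  idx <- seq_len(n)
  cnt <- pmin(idx, w)
  out <- x
  for (e in seq_len(ncol(x))) {
    cs <- cumsum(x[, e])
    cs2 <- cumsum(x[, e]^2)
    lag <- pmax(idx - w, 0)
    s1 <- cs - c(0, cs)[lag + 1]
    s2 <- cs2 - c(0, cs2)[lag + 1]
    mu <- s1 / cnt
    va <- pmax(s2 / cnt - mu^2, 0)
    out[, e] <- (x[, e] - mu) / pmax(sqrt(va), std_floor)
  }
  out
}

#' Z-score a trial against its pre-stimulus baseline
#'
#' @param trial time x electrode matrix of one trial's features
#' @param baseline_idx integer indices (rows of `trial`) of the silent
#'   pre-stimulus baseline
#' @return the trial with each channel normalized so that the baseline samples
#'   have mean 0 and standard deviation 1
#' @export
trial_zscore <- function(trial, baseline_idx) {
  trial <- as.matrix(trial)
  if (length(baseline_idx) == 0) stop("baseline window is empty")
  if (min(baseline_idx) < 1 || max(baseline_idx) > nrow(trial))
    stop("baseline window outside trial")
  base <- trial[baseline_idx, , drop = FALSE]
  mu <- colMeans(base)
  s <- apply(base, 2, sd)
  bad <- which(!(s > 0))
  if (length(bad))
    stop(sprintf("zero baseline variance in channel(s): %s",
                 paste(bad, collapse = ", ")))
  sweep(sweep(trial, 2, mu), 2, s, "/")
}

#' Screen trials for variance-suppression artifacts
#'
#' At every time point, takes the standard deviation of each electrode's HGA
#' over the window \[-5, +10\] s, then the 30th percentile of these values
#' across electrodes. Time points where the window does not fit inside the
#' recording are excluded. A trial is flagged when the metric stays below
#' `cutoff` for at least `run_s` seconds inside the trial.
#'
#' @param hga time x electrode HGA matrix at `fs` Hz
#' @param trials data.frame with columns `trial`, `start`, `end` (seconds)
#' @param cutoff flagging cutoff on the aggregate metric (default 0.6)
#' @param run_s minimum sustained sub-cutoff duration in seconds
#' @param fs sampling rate
#' @return an `artifact_report` list: `metric` (NA where undefined),
#'   `flagged_trials`, `cutoff`
#' @export
artifact_scan <- function(hga, trials, cutoff = 0.6, run_s = 1, fs = 200) {
  x <- as.matrix(hga)
  n <- nrow(x)
  if (n / fs < 15) stop("recording must be at least 15 s for the [-5, 10] s window")
  pre <- round(5 * fs)
  post <- round(10 * fs)
  wlen <- pre + post + 1
  valid <- (pre + 1):(n - post)
  stds <- matrix(NA_real_, length(valid), ncol(x))
  for (e in seq_len(ncol(x))) {
    cs <- cumsum(x[, e])
    cs2 <- cumsum(x[, e]^2)
    lo <- valid - pre
    hi <- valid + post
    s1 <- cs[hi] - c(0, cs)[lo]
    s2 <- cs2[hi] - c(0, cs2)[lo]
    mu <- s1 / wlen
    stds[, e] <- sqrt(pmax(s2 / wlen - mu^2, 0))
  }
  metric <- rep(NA_real_, n)
  metric[valid] <- apply(stds, 1, quantile, probs = 0.3, na.rm = TRUE)
  low <- !is.na(metric) & metric < cutoff
  flagged <- integer(0)
  for (i in seq_len(nrow(trials))) {
    i0 <- max(1, round(trials$start[i] * fs) + 1)
    i1 <- min(n, round(trials$end[i] * fs))
    if (i1 <= i0) next
    r <- rle(low[i0:i1])
    if (any(r$values & r$lengths >= round(run_s * fs)))
      flagged <- c(flagged, trials$trial[i])
  }
  structure(list(metric = metric, flagged_trials = flagged, cutoff = cutoff),
            class = "artifact_report")
}
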