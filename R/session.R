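# The session container: both feature streams, the electrode map, trial and
# event tables, and the detector label track. One RDS file per session with a
# fixed logical schema; reader/writer round-trip bit-exactly.

#' Assemble a neural session
#'
#' @param hga,lfs time x electrode feature matrices at 200 Hz
#' @param electrode_map per-electrode region labels
#' @param trials data.frame of trial records (columns `trial`, `task`,
#'   `condition`, `word`, `presentation`, `go_cue`, `onset`, `offset`,
#'   `start`, `end`, `block`)
#' @param labels integer label track, codes into [DETECTOR_CLASSES]
#' @param train_mask logical; FALSE marks samples excluded from training loss
#' @param events data.frame of true speech attempts (`trial`, `word`,
#'   `onset`, `offset` in seconds); empty for blocks without attempts
#' @param profiles optional simulator ground-truth electrode profiles
#' @param config optional simulator configuration
#' @export
neural_session <- function(hga, lfs, electrode_map, trials, labels, train_mask,
                           events, profiles = NULL, config = NULL) {
  hga <- as.matrix(hga)
  lfs <- as.matrix(lfs)
  stopifnot(all(dim(hga) == dim(lfs)),
            length(electrode_map) == ncol(hga),
            length(labels) == nrow(hga),
            length(train_mask) == nrow(hga))
  structure(list(hga = hga, lfs = lfs, electrode_map = as.character(electrode_map),
                 trials = trials, labels = as.integer(labels),
                 train_mask = as.logical(train_mask), events = events,
                 profiles = profiles, config = config, sample_rate_hz = 200),
            class = "neural_session")
}

#' @export
print.neural_session <- function(x, ...) {
  cat(sprintf("<neural_session> %.1f s, %d electrodes, %d trials, %d true events\n",
              nrow(x$hga) / x$sample_rate_hz, ncol(x$hga), nrow(x$trials),
              nrow(x$events)))
  invisible(x)
}

#' Number of time samples in a session
#' @param session a [neural_session()]
#' @export
session_length <- function(session) nrow(session$hga)

#' Session feature matrix: HGA and LFS columns side by side (time x 2E)
#' @param session a [neural_session()]
#' @export
session_features <- function(session) cbind(session$hga, session$lfs)

#' Write / read a session container
#'
#' Serialized as a single RDS file (version 3). The logical schema mirrors an
#' HDF5 layout (`/hga`, `/lfs`, `/labels`, `/trials`, `/events`,
#' `/electrodes`) but uses R serialization because no HDF5 binding is
#' available in the supported dependency set. Round-trips bit-exactly.
#'
#' @param session a [neural_session()]
#' @param path file path
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "neural_session"))
  saveRDS(session, path, version = 3)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  s <- readRDS(path)
  stopifnot(inherits(s, "neural_session"))
  s
}
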