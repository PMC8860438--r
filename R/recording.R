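#' EEG recording container
#'
#' Bundles a channels-by-samples signal matrix with its sampling rate,
#' channel labels, and (optionally) a montage adjacency matrix.
#'
#' @param signal numeric matrix, channels in rows, samples in columns (uV).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector of unique channel labels; defaults
#'   to the matrix rownames or \code{ch1, ch2, ...}.
#' @param adjacency optional logical adjacency matrix (symmetric,
#'   irreflexive) over the channels, as built by [montage_adjacency()].
#' @return an object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(signal, sampling_rate, channel_labels = NULL,
                          adjacency = NULL) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (is.null(channel_labels)) {
    channel_labels <- rownames(signal)
    if (is.null(channel_labels))
      channel_labels <- paste0("ch", seq_len(nrow(signal)))
  }
  if (length(channel_labels) != nrow(signal))
    stop("channel_labels length must match number of signal rows")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(signal) <- channel_labels
  if (!is.null(adjacency)) {
    if (!isTRUE(all.equal(adjacency, t(adjacency))))
      stop("adjacency must be symmetric")
    if (any(diag(adjacency) != 0)) stop("adjacency must be irreflexive")
  }
  structure(list(signal = signal, sampling_rate = as.numeric(sampling_rate),
                 channel_labels = channel_labels, adjacency = adjacency),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Hypnogram container
#'
#' Per-epoch sleep-stage labels on a fixed epoch grid starting at time 0.
#'
#' @param stages character vector of stage labels, one per epoch, from
#'   \code{c("W", "N1", "N2", "N3", "REM")}.
#' @param epoch_length epoch length in seconds (30 s is the scoring standard).
#' @return an object of class \code{hypnogram}.
#' @export
hypnogram <- function(stages, epoch_length = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "REM"))
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, epoch_length = as.numeric(epoch_length)),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %g s (%.1f min)\n", length(x$stages),
              x$epoch_length, length(x$stages) * x$epoch_length / 60))
  print(table(factor(x$stages, levels = c("W", "N1", "N2", "N3", "REM"))))
  invisible(x)
}

# Stage label at a vector of times (seconds); NA past the hypnogram end.
stage_at <- function(hyp, times) {
  idx <- floor(times / hyp$epoch_length) + 1
  out <- rep(NA_character_, length(times))
  ok <- idx >= 1 & idx <= length(hyp$stages)
  out[ok] <- hyp$stages[idx[ok]]
  out
}

# Continuous runs (in samples, 1-based inclusive) of the requested stages,
# clipped to n_samples.
stage_runs <- function(hyp, stages, fs, n_samples) {
  inmask <- hyp$stages %in% stages
  r <- rle(inmask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- matrix(numeric(0), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  for (k in keep) {
    s0 <- round((starts[k] - 1) * hyp$epoch_length * fs) + 1
    s1 <- round(ends[k] * hyp$epoch_length * fs)
    s1 <- min(s1, n_samples)
    if (s1 > s0) out <- rbind(out, c(s0, s1))
  }
  out
}

# Logical per-sample mask of the requested stages.
stage_mask <- function(hyp, stages, fs, n_samples) {
  mask <- logical(n_samples)
  runs <- stage_runs(hyp, stages, fs, n_samples)
  for (i in seq_len(nrow(runs))) mask[runs[i, 1]:runs[i, 2]] <- TRUE
  mask
}

#' Z-normalize an EEG recording in the time domain
#'
#' Rescales every channel to zero mean and unit standard deviation over the
#' full recording. This mitigates gross power differences (age, amplifier)
#' before spectral analysis; downstream event detection is in any case
#' invariant to per-channel gain because all amplitude criteria are
#' percentile based.
#'
#' @param recording an [eeg_recording()].
#' @return the recording with normalized channels.
#' @export
znorm_signal <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  sds <- apply(recording$signal, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance channel(s): ",
         paste(recording$channel_labels[sds == 0], collapse = ", "))
  mus <- rowMeans(recording$signal)
  recording$signal <- (recording$signal - mus) / sds
  recording
}
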