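#' Write / read a hypnogram as CSV
#'
#' Columns: \code{epoch_index} (1-based), \code{onset_s}, \code{stage}.
#'
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @return \code{read_hypnogram_csv} returns a [hypnogram()].
#' @export
write_hypnogram_csv <- function(hyp, path) {
  df <- data.frame(epoch_index = seq_along(hyp$stages),
                   onset_s = (seq_along(hyp$stages) - 1) * hyp$epoch_length,
                   stage = hyp$stages)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  epoch_length <- if (nrow(df) > 1) df$onset_s[2] - df$onset_s[1] else 30
  hypnogram(df$stage, epoch_length)
}

#' Write / read an EEG recording as raw float binary plus JSON header
#'
#' Lossless float interchange: samples are stored channel-major as 8-byte
#' doubles in \code{<path>.bin}, with sampling rate, channel labels, and
#' dimensions in \code{<path>.json}.
#'
#' @param recording an [eeg_recording()].
#' @param path base path (without extension).
#' @return \code{read_recording} returns an [eeg_recording()].
#' @export
write_recording <- function(recording, path) {
  hdr <- list(sampling_rate = recording$sampling_rate,
              channel_labels = recording$channel_labels,
              n_channels = nrow(recording$signal),
              n_samples = ncol(recording$signal),
              byte_order = "little", dtype = "float64")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(recording$signal)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = hdr$n_channels * hdr$n_samples,
               size = 8, endian = "little")
  sig <- matrix(x, nrow = hdr$n_channels, byrow = TRUE)
  eeg_recording(sig, hdr$sampling_rate, hdr$channel_labels)
}

#' Write / read detected events as CSV
#'
#' One row per event with the detection metadata (kind, channel, timing,
#' amplitude, stage, and the co-occurrence partner/lag when gated). Epoch
#' waveforms are not serialized here.
#'
#' @param events an \code{event_set}.
#' @param path file path.
#' @return \code{read_events_csv} returns a data.frame.
#' @export
write_events_csv <- function(events, path) {
  df <- cbind(kind = events$kind, events$events)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a behavior table as CSV
#' @param table behavior data.frame (subject, group, age_group, test,
#'   block, cascades).
#' @param path file path.
#' @return \code{read_behavior_csv} returns the data.frame.
#' @export
write_behavior_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a channel adjacency relation as CSV
#'
#' Long format, one row per (channel, neighbor) pair, editable by hand.
#'
#' @param adjacency logical adjacency matrix.
#' @param path file path.
#' @return \code{read_adjacency_csv} returns the adjacency matrix.
#' @export
write_adjacency_csv <- function(adjacency, path) {
  idx <- which(adjacency, arr.ind = TRUE)
  df <- data.frame(channel = rownames(adjacency)[idx[, 1]],
                   neighbor = colnames(adjacency)[idx[, 2]])
  utils::write.csv(df[order(df$channel, df$neighbor), ], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @export
read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  chans <- sort(unique(c(df$channel, df$neighbor)))
  adj <- matrix(FALSE, length(chans), length(chans),
                dimnames = list(chans, chans))
  adj[cbind(df$channel, df$neighbor)] <- TRUE
  adj | t(adj)
}

#' Write a per-channel coupling result as CSV
#' @param result a \code{coupling_result} (or a data.frame of stacked
#'   results with a \code{subject} column).
#' @param path file path.
#' @export
write_coupling_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
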