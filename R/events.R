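new_event_set <- function(kind, events, epochs, fs, half_s = 2.5,
                          norm_epochs = NULL) {
  structure(list(kind = kind, events = events, epochs = epochs,
                 norm_epochs = norm_epochs, fs = fs, half_s = half_s),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set:%s> %d event(s) on %d channel(s) @ %g Hz\n",
              x$kind, nrow(x$events),
              length(unique(x$events$channel)), x$fs))
  invisible(x)
}

empty_events <- function() {
  data.frame(id = integer(0), channel = character(0),
             center_time = numeric(0), onset = numeric(0),
             offset = numeric(0), duration = numeric(0),
             amplitude = numeric(0), stage = character(0))
}

# Extract +/- half_s epochs around center samples; drops (and reports)
# events whose epoch would cross the recording bounds.
extract_epochs <- function(x, centers, fs, half_s) {
  hw <- round(half_s * fs)
  n <- length(x)
  ok <- centers - hw >= 1 & centers + hw <= n
  ep <- t(vapply(centers[ok], function(c0) x[(c0 - hw):(c0 + hw)],
                 numeric(2 * hw + 1)))
  list(epochs = ep, kept = ok)
}

#' Detect sleep spindles with an individualized amplitude criterion
#'
#' Per channel: band-pass filter +/-2 Hz around the channel's individual
#' spindle peak frequency (zero-phase Butterworth), take the instantaneous
#' amplitude via the Hilbert envelope, smooth with a 200-ms moving average,
#' and threshold at the 75th percentile of the smoothed envelope over all
#' samples in the requested stages. Supra-threshold runs lasting 0.5-3 s
#' become events; the event center is the largest positive peak of the
#' band-filtered signal within the run. Raw +/-2.5 s epochs are cut from
#' the unfiltered signal; events with centers outside the requested stages
#' or epochs crossing the recording bounds are dropped (counted in
#' \code{attr(result, "dropped")}).
#'
#' @param recording an [eeg_recording()].
#' @param hypnogram a [hypnogram()].
#' @param peaks data.frame from [find_peaks()] (needs \code{channel},
#'   \code{spindle_peak_freq}).
#' @param stages eligible stages (default "N3").
#' @param percentile amplitude criterion percentile (default 75).
#' @param dur_range event duration bounds in seconds.
#' @param half_s epoch half-width in seconds.
#' @return an \code{event_set} of kind \code{"spindle"}.
#' @export
detect_spindles <- function(recording, hypnogram, peaks, stages = "N3",
                            percentile = 75, dur_range = c(0.5, 3),
                            half_s = 2.5) {
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  mask <- stage_mask(hypnogram, stages, fs, n)
  if (!any(mask)) stop("no samples in requested stage(s): ",
                       paste(stages, collapse = "/"))
  all_ev <- list(); all_ep <- list(); dropped <- 0L
  for (ch in recording$channel_labels) {
    pf <- peaks$spindle_peak_freq[peaks$channel == ch]
    if (length(pf) != 1 || is.na(pf))
      stop("missing spindle peak frequency for channel ", ch)
    lo <- pf - 2; hi <- pf + 2
    if (lo <= 0) stop("spindle band edge below 0 Hz for channel ", ch)
    x <- recording$signal[ch, ]
    b <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
    xf <- signal::filtfilt(b, x)
    env <- Mod(analytic_signal(xf))
    env <- moving_average(env, max(1L, round(0.2 * fs)))
    thr <- amplitude_threshold(env[mask], percentile)
    supra <- env >= thr
    r <- rle(supra)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    idx <- which(r$values)
    for (k in idx) {
      dur <- (ends[k] - starts[k] + 1) / fs
      if (dur < dur_range[1] || dur > dur_range[2]) next
      seg <- xf[starts[k]:ends[k]]
      c0 <- starts[k] + which.max(seg) - 1
      st <- stage_at(hypnogram, (c0 - 1) / fs)
      if (is.na(st) || !(st %in% stages)) { dropped <- dropped + 1L; next }
      ex <- extract_epochs(x, c0, fs, half_s)
      if (!any(ex$kept)) { dropped <- dropped + 1L; next }
      all_ev[[length(all_ev) + 1]] <- data.frame(
        channel = ch, center_time = (c0 - 1) / fs,
        onset = (starts[k] - 1) / fs, offset = (ends[k] - 1) / fs,
        duration = dur, amplitude = max(env[starts[k]:ends[k]]), stage = st)
      all_ep[[length(all_ep) + 1]] <- ex$epochs
    }
  }
  ev <- if (length(all_ev)) do.call(rbind, all_ev) else empty_events()
  if (nrow(ev)) ev <- cbind(id = seq_len(nrow(ev)), ev)
  else ev$id <- integer(0)
  ep <- if (length(all_ep)) do.call(rbind, all_ep)
    else matrix(numeric(0), 0, 2 * round(half_s * fs) + 1)
  out <- new_event_set("spindle", ev, ep, fs, half_s)
  attr(out, "dropped") <- dropped
  out
}

#' Percentile amplitude criterion
#'
#' Threshold value for an amplitude criterion: the given percentile of the
#' reference distribution, computed with linear interpolation between order
#' statistics (quantile type 7). Detectors compare with \code{>=}, so
#' values tied with the threshold are kept - with 100 identical candidate
#' amplitudes every candidate passes.
#'
#' @param amplitudes numeric reference sample.
#' @param percentile percentile in [0, 100].
#' @return scalar threshold.
#' @export
amplitude_threshold <- function(amplitudes, percentile = 75) {
  stats::quantile(amplitudes, percentile / 100, names = FALSE, type = 7)
}

#' Detect slow oscillations by zero-crossing and amplitude criteria
#'
#' The continuous signal is high-pass filtered at 0.16 Hz and low-pass
#' filtered at 2 Hz (zero-phase Butterworth). Candidates are the segments
#' between successive positive-to-negative zero crossings lasting 0.8-2 s
#' and containing one trough followed by one positive peak. A candidate is
#' a valid SO when its trough-to-peak amplitude reaches the 75th percentile
#' of all stage-eligible candidate amplitudes on that channel (ties kept).
#' Raw +/-2.5 s epochs are cut around the filtered-signal trough.
#'
#' @inheritParams detect_spindles
#' @param hp,lp filter cutoffs in Hz.
#' @param dur_range candidate duration bounds in seconds.
#' @return an \code{event_set} of kind \code{"slow_oscillation"};
#'   \code{amplitude} is trough-to-peak, \code{trough_amplitude} the
#'   (negative) trough value, both in filtered-signal units.
#' @export
detect_slow_oscillations <- function(recording, hypnogram, stages = "N3",
                                     percentile = 75, hp = 0.16, lp = 2,
                                     dur_range = c(0.8, 2), half_s = 2.5) {
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  if (n / fs < 10) stop("recording too short for SO detection (< 10 s)")
  all_ev <- list(); all_ep <- list(); dropped <- 0L
  for (ch in recording$channel_labels) {
    x <- recording$signal[ch, ]
    xf <- butter_filtfilt(x, fs, low = hp, high = lp)
    pos <- xf > 0
    p2n <- which(pos[-n] & !pos[-1])       # sample index before the crossing
    cand <- list()
    for (k in seq_len(length(p2n) - 1)) {
      s0 <- p2n[k] + 1; s1 <- p2n[k + 1]
      dur <- (s1 - s0 + 1) / fs
      if (dur < dur_range[1] || dur > dur_range[2]) next
      seg <- xf[s0:s1]
      imin <- which.min(seg); imax <- which.max(seg)
      if (!(seg[imin] < 0 && seg[imax] > 0 && imin < imax)) next
      trough <- s0 + imin - 1
      st <- stage_at(hypnogram, (trough - 1) / fs)
      if (is.na(st) || !(st %in% stages)) next
      cand[[length(cand) + 1]] <- data.frame(
        channel = ch, center_time = (trough - 1) / fs,
        onset = (s0 - 1) / fs, offset = (s1 - 1) / fs, duration = dur,
        amplitude = seg[imax] - seg[imin], trough_amplitude = seg[imin],
        stage = st, trough = trough)
    }
    if (length(cand) < 4) {
      warning("channel ", ch, ": fewer than 4 SO candidates; ",
              "percentile ill-defined, returning no events")
      next
    }
    cd <- do.call(rbind, cand)
    thr <- amplitude_threshold(cd$amplitude, percentile)
    cd <- cd[cd$amplitude >= thr, , drop = FALSE]
    for (i in seq_len(nrow(cd))) {
      ex <- extract_epochs(x, cd$trough[i], fs, half_s)
      if (!any(ex$kept)) { dropped <- dropped + 1L; next }
      all_ev[[length(all_ev) + 1]] <- cd[i, setdiff(names(cd), "trough")]
      all_ep[[length(all_ep) + 1]] <- ex$epochs
    }
  }
  ev <- if (length(all_ev)) do.call(rbind, all_ev) else
    cbind(empty_events(), trough_amplitude = numeric(0))
  rownames(ev) <- NULL
  if (nrow(ev)) ev <- cbind(id = seq_len(nrow(ev)), ev)
  else ev$id <- integer(0)
  ep <- if (length(all_ep)) do.call(rbind, all_ep)
    else matrix(numeric(0), 0, 2 * round(half_s * fs) + 1)
  out <- new_event_set("slow_oscillation", ev, ep, fs, half_s)
  attr(out, "dropped") <- dropped
  out
}

#' Z-normalize event epochs in the time domain
#'
#' Maps every raw epoch to zero mean and unit SD (the raw epoch is kept
#' alongside), so that later phase estimation is unaffected by power
#' differences between subjects or amplifiers. Zero-variance epochs are
#' dropped with a warning.
#'
#' @param events an \code{event_set}.
#' @return the event set with a \code{norm_epochs} matrix added.
#' @export
znorm_epochs <- function(events) {
  stopifnot(inherits(events, "event_set"))
  if (!nrow(events$events)) { events$norm_epochs <- events$epochs; return(events) }
  sds <- apply(events$epochs, 1, stats::sd)
  bad <- sds == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance epoch(s) dropped")
    events$events <- events$events[!bad, , drop = FALSE]
    events$epochs <- events$epochs[!bad, , drop = FALSE]
    sds <- sds[!bad]
  }
  mus <- rowMeans(events$epochs)
  events$norm_epochs <- (events$epochs - mus) / sds
  events
}

#' Gate spindles on slow-oscillation co-occurrence
#'
#' Keeps only spindles with at least one same-channel SO trough within
#' \code{window} seconds of the spindle peak (symmetric window); the
#' partner is the nearest such SO and \code{lag} = SO trough time - spindle
#' peak time. Restricting coupling analysis to co-occurring events prevents
#' spurious phase estimates when no SO is present in the epoch.
#'
#' @param spindles spindle \code{event_set}.
#' @param sos slow-oscillation \code{event_set} from the same recording.
#' @param window co-occurrence window in seconds (default 2.5).
#' @return object of class \code{coupled_events}: the gated spindle
#'   \code{event_set} with \code{partner_id} and \code{lag} columns.
#' @export
gate_cooccurrence <- function(spindles, sos, window = 2.5) {
  stopifnot(inherits(spindles, "event_set"), inherits(sos, "event_set"))
  ev <- spindles$events
  if (!nrow(ev)) {
    out <- spindles
    out$events <- cbind(ev, partner_id = integer(0), lag = numeric(0))
    class(out) <- c("coupled_events", "event_set")
    return(out)
  }
  partner <- rep(NA_integer_, nrow(ev))
  lag <- rep(NA_real_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    so <- sos$events[sos$events$channel == ev$channel[i], , drop = FALSE]
    if (!nrow(so)) next
    d <- so$center_time - ev$center_time[i]
    j <- which.min(abs(d))
    if (abs(d[j]) <= window) { partner[i] <- so$id[j]; lag[i] <- d[j] }
  }
  keep <- !is.na(partner)
  out <- spindles
  out$events <- cbind(ev[keep, , drop = FALSE],
                      partner_id = partner[keep], lag = lag[keep])
  out$epochs <- spindles$epochs[keep, , drop = FALSE]
  if (!is.null(spindles$norm_epochs))
    out$norm_epochs <- spindles$norm_epochs[keep, , drop = FALSE]
  class(out) <- c("coupled_events", "event_set")
  out
}

#' Fraction of spindles with a co-occurring slow oscillation, by stage
#'
#' @inheritParams gate_cooccurrence
#' @param hypnogram the recording's [hypnogram()].
#' @return data.frame (channel, stage, n_spindles, n_cooccurring, rate);
#'   the rate is \code{NA} where a stage has no spindles (undefined, not 0).
#' @export
cooccurrence_rate <- function(spindles, sos, hypnogram, window = 2.5) {
  gated <- gate_cooccurrence(spindles, sos, window)
  ev <- spindles$events
  stages <- sort(unique(ev$stage))
  chans <- sort(unique(ev$channel))
  out <- expand.grid(channel = chans, stage = stages,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_spindles <- mapply(function(ch, st)
    sum(ev$channel == ch & ev$stage == st), out$channel, out$stage)
  out$n_cooccurring <- mapply(function(ch, st)
    sum(gated$events$channel == ch & gated$events$stage == st),
    out$channel, out$stage)
  out$rate <- ifelse(out$n_spindles > 0,
                     out$n_cooccurring / out$n_spindles, NA_real_)
  out
}
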