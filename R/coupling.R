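#' SO phase at the spindle peak, per coupled event
#'
#' For every normalized spindle epoch (peak at the epoch center, t = 0),
#' extracts the underlying slow-oscillation component with a zero-phase
#' 2 Hz low-pass filter (reflection padding suppresses edge transients on
#' the short epoch), takes the analytic-signal phase, and reads it out at
#' t = 0. Cosine convention: SO up-state peak = 0 rad, trough = +/-pi.
#'
#' @param coupled a \code{coupled_events} object whose epochs have been
#'   z-normalized with [znorm_epochs()].
#' @param lp low-pass cutoff in Hz isolating the SO component.
#' @return numeric vector of phases in (-pi, pi], one per event.
#' @export
so_phase_at_spindle_peak <- function(coupled, lp = 2) {
  stopifnot(inherits(coupled, "coupled_events"))
  ep <- coupled$norm_epochs
  if (is.null(ep)) stop("epochs must be z-normalized first (znorm_epochs)")
  if (!nrow(ep)) return(numeric(0))
  fs <- coupled$fs
  nsamp <- ncol(ep)
  if ((nsamp - 1) / fs < 5)
    stop("epoch too short for stable filtering (< 5 s)")
  b <- signal::butter(3, lp / (fs / 2), type = "low")
  center <- (nsamp + 1) / 2
  vapply(seq_len(nrow(ep)), function(i) {
    x <- ep[i, ]
    pad <- c(rev(x), x, rev(x))             # reflection padding
    xf <- signal::filtfilt(b, pad)[nsamp + seq_len(nsamp)]
    Arg(analytic_signal(xf))[center]
  }, numeric(1))
}

#' Coupling strength: mean resultant length of a phase sample
#'
#' Equals 1 - circular variance. 1 means perfectly consistent spindle
#' timing relative to the SO phase, 0 means no phase preference.
#'
#' @param phases numeric vector of angles in radians (at least one).
#' @return scalar in [0, 1].
#' @examples
#' coupling_strength(rep(0.5, 10))        # perfectly consistent: 1
#' coupling_strength(c(0, pi))            # antipodal: 0
#' coupling_strength(rvonmises(500, 0, 4))
#' @export
coupling_strength <- function(phases) {
  if (!length(phases)) stop("empty phase vector")
  Mod(mean(exp(1i * phases)))
}

#' Preferred phase: circular mean of a phase sample
#'
#' @param phases numeric vector of angles in radians (at least one).
#' @return angle in (-pi, pi]; \code{NA} with a warning when the resultant
#'   vector has zero length (direction undefined).
#' @export
preferred_phase <- function(phases) {
  if (!length(phases)) stop("empty phase vector")
  z <- mean(exp(1i * phases))
  if (Mod(z) < 1e-12) {
    warning("zero resultant length: preferred phase undefined")
    return(NA_real_)
  }
  wrap_phase(Arg(z))
}

#' Per-channel coupling summary for one subject-night
#'
#' Reads out SO phases at spindle peaks and assembles, per channel, the
#' phase sample, its coupling strength (mean resultant length) and
#' preferred phase. Channels with fewer than \code{min_events} events are
#' reported with \code{NA} metrics since the resultant length is strongly
#' upward-biased in tiny samples.
#'
#' @inheritParams so_phase_at_spindle_peak
#' @param min_events minimum event count for a reportable channel.
#' @param night_label optional label (e.g. "adaptation", "learning").
#' @return object of class \code{coupling_result}: data.frame with
#'   \code{channel}, \code{n_events}, \code{coupling_strength},
#'   \code{preferred_phase}, \code{night}; per-channel phase samples in
#'   \code{attr(, "phases")}.
#' @export
subject_coupling <- function(coupled, lp = 2, min_events = 10,
                             night_label = NA_character_) {
  ph <- so_phase_at_spindle_peak(coupled, lp)
  chans <- unique(coupled$events$channel)
  phases <- split(ph, factor(coupled$events$channel, levels = chans))
  res <- do.call(rbind, lapply(chans, function(ch) {
    p <- phases[[ch]]
    n <- length(p)
    data.frame(channel = ch, n_events = n,
               coupling_strength = if (n >= min_events)
                 coupling_strength(p) else NA_real_,
               preferred_phase = if (n >= min_events)
                 preferred_phase(p) else NA_real_,
               night = night_label)
  }))
  structure(res, phases = phases, class = c("coupling_result", "data.frame"))
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("<coupling_result> SO-spindle coupling per channel\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
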