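#' SO-trough-locked time-frequency representation
#'
#' Short-time power with a 500-ms Hanning taper, evaluated on a -2..2 s
#' grid in 50-ms steps and 5-30 Hz in 0.5-Hz steps (oscillatory power is
#' estimated by direct projection on the tapered complex exponential at
#' each requested frequency, so the frequency step is not tied to the FFT
#' bin spacing of the short window). Time points whose window would exceed
#' the epoch are marked missing.
#'
#' @param so_events slow-oscillation \code{event_set} (epochs centered on
#'   the trough); normalized epochs are used when present.
#' @param times time grid in seconds relative to the trough.
#' @param freqs frequency grid in Hz.
#' @param win_s taper length in seconds.
#' @return object of class \code{tfr_result}: \code{times}, \code{freqs},
#'   \code{power} (trial-averaged, times x freqs), and the per-trial power
#'   array \code{trial_power} (trials x times x freqs) needed for
#'   bootstrap baselining.
#' @export
compute_tfr <- function(so_events, times = seq(-2, 2, by = 0.05),
                        freqs = seq(5, 30, by = 0.5), win_s = 0.5) {
  stopifnot(inherits(so_events, "event_set"))
  ep <- if (!is.null(so_events$norm_epochs)) so_events$norm_epochs
        else so_events$epochs
  if (!nrow(ep)) stop("no epochs to analyze")
  fs <- so_events$fs
  half_s <- so_events$half_s
  if (2 * half_s < win_s) stop("epoch shorter than the analysis window")
  nw <- round(win_s * fs)
  if (nw %% 2 == 0) nw <- nw + 1
  hw <- (nw - 1) / 2
  nsamp <- ncol(ep)
  center0 <- (nsamp + 1) / 2                   # sample index of t = 0
  taper <- signal::hanning(nw)
  tt <- (seq_len(nw) - 1 - hw) / fs
  basis <- exp(-2i * pi * outer(tt, freqs)) * taper   # nw x nfreq
  scale <- 2 / (fs * sum(taper^2))

  ntrial <- nrow(ep)
  valid <- round(times * fs) + center0 - hw >= 1 &
           round(times * fs) + center0 + hw <= nsamp
  tp <- array(NA_real_, c(ntrial, length(times), length(freqs)))
  for (j in which(valid)) {
    c0 <- round(times[j] * fs) + center0
    seg <- ep[, (c0 - hw):(c0 + hw), drop = FALSE]
    seg <- seg - rowMeans(seg)
    tp[, j, ] <- Mod(seg %*% basis)^2 * scale
  }
  structure(list(times = times, freqs = freqs,
                 power = apply(tp, c(2, 3), mean),
                 trial_power = tp),
            class = "tfr_result")
}

#' @export
print.tfr_result <- function(x, ...) {
  cat(sprintf(
    "<tfr_result> %d trial(s), %d time bins (%.2f..%.2f s), %d freqs (%g..%g Hz)%s\n",
    dim(x$trial_power)[1], length(x$times), min(x$times), max(x$times),
    length(x$freqs), min(x$freqs), max(x$freqs),
    if (!is.null(x$zpower)) ", baseline z-scored" else ""))
  invisible(x)
}

#' Bootstrap baseline z-scoring of a time-frequency representation
#'
#' Per frequency, the baseline distribution pools the power values of
#' every trial at every baseline time bin; \code{iterations} bootstrap
#' draws from this pool give the reference mean and SD, against which the
#' trial-averaged power map is z-scored. The SD is on the single-trial,
#' single-bin scale, the convention under which event-related power
#' changes of ~2x map to z values of a few units. Deterministic given
#' \code{seed}.
#'
#' @param tfr a \code{tfr_result}.
#' @param baseline baseline interval in seconds, default c(-2, -1.5).
#' @param iterations bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @return the \code{tfr_result} with a \code{zpower} matrix added.
#' @export
bootstrap_baseline_z <- function(tfr, baseline = c(-2, -1.5),
                                 iterations = 10000, seed = 1L) {
  stopifnot(inherits(tfr, "tfr_result"))
  ntrial <- dim(tfr$trial_power)[1]
  if (ntrial < 2) stop("bootstrap baseline requires at least 2 trials")
  bl <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (!length(bl)) stop("baseline interval outside the epoch")
  if (anyNA(tfr$trial_power[, bl, ]))
    stop("baseline interval includes missing (edge) time points")
  # pooled baseline values: (trials * baseline bins) x freqs
  pool <- matrix(tfr$trial_power[, bl, , drop = FALSE],
                 nrow = ntrial * length(bl))
  boot <- with_seed(seed, {
    pool[sample.int(nrow(pool), iterations, replace = TRUE), , drop = FALSE]
  })
  mu <- colMeans(boot)
  sdv <- apply(boot, 2, stats::sd)
  tfr$zpower <- sweep(sweep(tfr$power, 2, mu), 2, sdv, "/")
  tfr
}
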