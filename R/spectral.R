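# Sliding 15-s windows (start samples) inside continuous stage runs.
window_starts <- function(runs, fs, win_s, step_s) {
  nw <- round(win_s * fs)
  starts <- integer(0)
  for (i in seq_len(nrow(runs))) {
    s0 <- runs[i, 1]; s1 <- runs[i, 2]
    if (s1 - s0 + 1 < nw) next
    starts <- c(starts, seq(s0, s1 - nw + 1, by = round(step_s * fs)))
  }
  starts
}

# One-sided Hanning PSD of a channels-in-columns matrix segment.
# Returns list(freqs, psd) with psd channels in columns.
hanning_psd <- function(xm, fs) {
  n <- nrow(xm)
  w <- signal::hanning(n)
  xw <- (xm - rep(colMeans(xm), each = n)) * w
  X <- stats::mvfft(xw)
  nf <- floor(n / 2) + 1
  scale <- 2 / (fs * sum(w^2))
  psd <- (Mod(X[seq_len(nf), , drop = FALSE])^2) * scale
  psd[1, ] <- psd[1, ] / 2
  if (n %% 2 == 0) psd[nf, ] <- psd[nf, ] / 2
  list(freqs = (seq_len(nf) - 1) * fs / n, psd = psd)
}

# Row-wise median of a small-column matrix by vectorized selection of the
# middle order statistic (ties fall back to median()).
row_median <- function(m) {
  k <- ncol(m)
  if (k == 1) return(m[, 1])
  mid <- (k + 1) / 2
  res <- rep(NA_real_, nrow(m))
  todo <- rep(TRUE, nrow(m))
  if (k %% 2 == 1) {
    for (j in seq_len(k)) {
      cnt <- rowSums(m <= m[, j])
      hit <- todo & cnt == mid
      res[hit] <- m[hit, j]
      todo <- todo & !hit
    }
  }
  if (any(todo))
    res[todo] <- apply(m[todo, , drop = FALSE], 1, stats::median)
  res
}

# Fourier-domain resampling of matrix columns to m samples (same fs
# interpretation; stretches/compresses content, as IRASA requires).
resample_fourier <- function(xm, m) {
  n <- nrow(xm)
  X <- stats::mvfft(xm)
  nc <- ncol(xm)
  Y <- matrix(0 + 0i, m, nc)
  half <- min(floor(n / 2), floor(m / 2))
  Y[1, ] <- X[1, ]
  if (half >= 1) {
    Y[2:(half + 1), ] <- X[2:(half + 1), , drop = FALSE]
    Y[(m - half + 1):m, ] <- X[(n - half + 1):n, , drop = FALSE]
  }
  Re(stats::mvfft(Y, inverse = TRUE)) / n   # /n preserves amplitude
}

#' Average sliding-window power spectrum over selected sleep stages
#'
#' Hanning-tapered FFT power spectra on fixed-length windows (default 15 s)
#' advanced in 1-s steps, drawn only from continuous runs of the requested
#' stages, and averaged with equal weight across windows.
#'
#' @param recording an [eeg_recording()] (typically after [znorm_signal()]).
#' @param hypnogram a [hypnogram()].
#' @param stages stage labels to include (default NREM = N2 + N3).
#' @param fmin,fmax frequency range in Hz retained in the output.
#' @param win_s window length in seconds.
#' @param step_s slide step in seconds.
#' @return list with \code{freqs} (Hz) and \code{power}
#'   (channels x frequencies, uV^2/Hz).
#' @export
compute_spectrum <- function(recording, hypnogram, stages = c("N2", "N3"),
                             fmin = 0.1, fmax = 30, win_s = 15, step_s = 1) {
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  runs <- stage_runs(hypnogram, stages, fs, n)
  starts <- window_starts(runs, fs, win_s, step_s)
  if (!length(starts))
    stop("no continuous ", win_s, "-s segment of stage(s) ",
         paste(stages, collapse = "/"), " available")
  nw <- round(win_s * fs)
  acc <- NULL
  for (s0 in starts) {
    seg <- t(recording$signal[, s0:(s0 + nw - 1), drop = FALSE])
    p <- hanning_psd(seg, fs)
    acc <- if (is.null(acc)) p$psd else acc + p$psd
  }
  psd <- acc / length(starts)
  freqs <- (seq_len(nrow(psd)) - 1) * fs / nw
  keep <- freqs >= fmin & freqs <= fmax
  list(freqs = freqs[keep], power = t(psd[keep, , drop = FALSE]))
}

#' IRASA estimate of the fractal (1/f) spectral component
#'
#' Irregular-resampling auto-spectral analysis: every analysis window is
#' stretched and compressed by each non-integer factor h in \code{hset};
#' the spectra of each h-resampled pair are geometrically averaged, which
#' shifts oscillatory peaks in opposite directions while leaving the
#' scale-free 1/f background in place; the median across factors then
#' removes the displaced peaks. Window handling and output grid match
#' [compute_spectrum()] so the two can be subtracted bin by bin.
#'
#' @inheritParams compute_spectrum
#' @param hset resampling factors (default 1.1 to 1.9 in 0.05 steps).
#' @return list with \code{freqs} and \code{power} (the fractal component).
#' @export
irasa_fractal <- function(recording, hypnogram, stages = c("N2", "N3"),
                          fmin = 0.1, fmax = 30, win_s = 15, step_s = 1,
                          hset = seq(1.1, 1.9, by = 0.05)) {
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  runs <- stage_runs(hypnogram, stages, fs, n)
  starts <- window_starts(runs, fs, win_s, step_s)
  if (!length(starts))
    stop("no continuous ", win_s, "-s segment of stage(s) ",
         paste(stages, collapse = "/"), " available")
  nw <- round(win_s * fs)
  base_freqs <- (0:(floor(nw / 2))) * fs / nw
  # Both PSD grids are uniform (spacing fs/m), so interpolation onto the
  # base grid reduces to fractional indexing; precompute per factor.
  interp_map <- function(m) {
    nf <- floor(m / 2) + 1
    pos <- base_freqs * m / fs + 1
    j <- pmin(pmax(floor(pos), 1), nf - 1)
    list(j = j, w = pmin(pmax(pos - j, 0), 1))
  }
  maps <- lapply(hset, function(h)
    list(up = interp_map(round(nw * h)), dn = interp_map(round(nw / h))))
  interp_psd <- function(psd, mp) {
    psd[mp$j, , drop = FALSE] * (1 - mp$w) +
      psd[mp$j + 1, , drop = FALSE] * mp$w
  }
  # Accumulate window-averaged spectra per factor and direction first;
  # the geometric pair mean and the median across factors are then taken
  # on low-variance estimates (raw periodograms would bias the geometric
  # mean downward through their chi-square sampling noise).
  nch <- nrow(recording$signal)
  nf <- length(base_freqs)
  up_acc <- array(0, c(nf, nch, length(hset)))
  dn_acc <- array(0, c(nf, nch, length(hset)))
  for (s0 in starts) {
    seg <- t(recording$signal[, s0:(s0 + nw - 1), drop = FALSE])
    for (j in seq_along(hset)) {
      h <- hset[j]
      up <- hanning_psd(resample_fourier(seg, round(nw * h)), fs)
      dn <- hanning_psd(resample_fourier(seg, round(nw / h)), fs)
      up_acc[, , j] <- up_acc[, , j] + interp_psd(up$psd, maps[[j]]$up)
      dn_acc[, , j] <- dn_acc[, , j] + interp_psd(dn$psd, maps[[j]]$dn)
    }
  }
  geo <- sqrt(up_acc * dn_acc) / length(starts)
  frac <- matrix(row_median(matrix(geo, ncol = length(hset))), nrow = nf)
  keep <- base_freqs >= fmin & base_freqs <= fmax
  list(freqs = base_freqs[keep], power = t(frac[keep, , drop = FALSE]))
}

#' Total, fractal, and oscillatory-residual spectra
#'
#' Convenience wrapper running [compute_spectrum()] and [irasa_fractal()]
#' on identical windows and storing the oscillatory residual
#' (total - fractal), the basis for individualized peak detection.
#'
#' @inheritParams irasa_fractal
#' @return object of class \code{spectrum_set} with \code{freqs},
#'   \code{total}, \code{fractal}, \code{residual} (channels x freqs) and
#'   \code{channel_labels}.
#' @export
compute_spectra <- function(recording, hypnogram, stages = c("N2", "N3"),
                            fmin = 0.1, fmax = 30, win_s = 15, step_s = 1,
                            hset = seq(1.1, 1.9, by = 0.05)) {
  tot <- compute_spectrum(recording, hypnogram, stages, fmin, fmax,
                          win_s, step_s)
  fra <- irasa_fractal(recording, hypnogram, stages, fmin, fmax,
                       win_s, step_s, hset)
  stopifnot(isTRUE(all.equal(tot$freqs, fra$freqs)))
  structure(list(freqs = tot$freqs, total = tot$power,
                 fractal = fra$power, residual = tot$power - fra$power,
                 channel_labels = recording$channel_labels),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d channel(s), %d bins (%.3f-%.2f Hz)\n",
              nrow(x$total), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

# Highest local maximum of y inside [band[1], band[2]]; falls back to the
# band's global maximum (flagged) when no interior local maximum exists.
band_peak <- function(freqs, y, band) {
  inb <- which(freqs > band[1] & freqs <= band[2])
  if (length(inb) < 1) stop("frequency grid does not cover the band ",
                            band[1], "-", band[2], " Hz")
  is_loc <- vapply(inb, function(i) {
    i > 1 && i < length(y) && y[i] > y[i - 1] && y[i] > y[i + 1]
  }, logical(1))
  if (any(is_loc)) {
    cand <- inb[is_loc]
    i <- cand[which.max(y[cand])]
    list(freq = freqs[i], amp = y[i], flagged = FALSE)
  } else {
    i <- inb[which.max(y[inb])]
    list(freq = freqs[i], amp = y[i], flagged = TRUE)
  }
}

#' Individual SO and spindle peaks from the oscillatory residual
#'
#' Per channel, locates the highest residual peak inside the SO band and
#' the spindle band; the peak frequency individualizes the downstream
#' spindle detector. A peak must be a local maximum of the residual; if a
#' band is monotone the global band maximum is returned and the channel is
#' flagged with a warning.
#'
#' @param spectra a \code{spectrum_set} from [compute_spectra()].
#' @param so_band SO search band in Hz (default (0, 2]).
#' @param spindle_band spindle search band in Hz (default [10, 17]).
#' @return data.frame with one row per channel: \code{channel},
#'   \code{so_peak_freq}, \code{so_peak_amp}, \code{so_flagged},
#'   \code{spindle_peak_freq}, \code{spindle_peak_amp},
#'   \code{spindle_flagged}.
#' @export
find_peaks <- function(spectra, so_band = c(0, 2), spindle_band = c(10, 17)) {
  stopifnot(inherits(spectra, "spectrum_set"))
  out <- lapply(seq_len(nrow(spectra$residual)), function(ch) {
    y <- spectra$residual[ch, ]
    so <- band_peak(spectra$freqs, y, so_band)
    sp <- band_peak(spectra$freqs, y, spindle_band)
    data.frame(channel = spectra$channel_labels[ch],
               so_peak_freq = so$freq, so_peak_amp = so$amp,
               so_flagged = so$flagged,
               spindle_peak_freq = sp$freq, spindle_peak_amp = sp$amp,
               spindle_flagged = sp$flagged)
  })
  res <- do.call(rbind, out)
  if (any(res$so_flagged) || any(res$spindle_flagged))
    warning("no local residual maximum in band for channel(s): ",
            paste(res$channel[res$so_flagged | res$spindle_flagged],
                  collapse = ", "), "; returning band maximum")
  res
}
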