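#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state so generators are deterministic given
# their own seed without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Wrap angles into (-pi, pi].
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal \eqn{x + iH(x)} whose modulus is the
#' instantaneous amplitude envelope and whose argument is the instantaneous
#' phase (cosine convention: a pure \eqn{\cos(2\pi f t)} has phase 0 at its
#' positive peak and \eqn{\pm\pi} at its trough).
#'
#' @param x numeric vector or matrix (signals in columns).
#' @return complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  n <- nrow(xm)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(xm) * h
  out <- stats::mvfft(X, inverse = TRUE) / n
  if (vec) drop(out) else out
}

# Moving average with exact partial windows at the edges (cumsum based).
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half <- floor(k / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Zero-phase Butterworth filtering (forward-backward), order per pass.
butter_filtfilt <- function(x, fs, low = NULL, high = NULL, order = 3) {
  nyq <- fs / 2
  y <- x
  if (!is.null(low)) {
    if (low <= 0) stop("high-pass cutoff must be positive")
    b <- signal::butter(order, low / nyq, type = "high")
    y <- signal::filtfilt(b, y)
  }
  if (!is.null(high)) {
    if (high >= nyq) stop("low-pass cutoff must be below the Nyquist frequency")
    b <- signal::butter(order, high / nyq, type = "low")
    y <- signal::filtfilt(b, y)
  }
  y
}
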