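#' Simulation configuration for a synthetic sleep-EEG recording
#'
#' Defines the generative model for one subject-night: 1/f ("fractal")
#' background noise plus planted slow-oscillation (SO) half-wave pairs and
#' Gaussian-enveloped spindle bursts, with spindle peaks locked to the SO
#' waveform phase through a von Mises law.
#'
#' @param sampling_rate Hz.
#' @param channel_labels montage labels (default: the 11-channel 10-20 grid).
#' @param stage_plan data.frame with columns \code{stage}, \code{duration}
#'   (seconds); epochs are filled in order. Total duration is its sum.
#' @param fractal_slope spectral exponent alpha of the background
#'   (power ~ 1/f^alpha).
#' @param fractal_offset standard deviation (uV) of the background noise.
#' @param so_rate SO events (troughs) per minute of eligible sleep.
#' @param so_cycles cycles per planted SO train (slow oscillations occur in
#'   short runs; a lone cycle's boundary zero-crossings would be unpinned).
#' @param so_freq SO frequency in Hz, must lie in (0, 2).
#' @param so_amplitude SO half-wave amplitude (uV).
#' @param spindle_rate spindle events per minute of eligible sleep.
#' @param spindle_freq subject spindle peak frequency in Hz, in [10, 17].
#' @param spindle_duration spindle duration in seconds, in [0.5, 3].
#' @param spindle_amplitude peak envelope amplitude (uV).
#' @param coupling_mu preferred SO phase (rad) of the spindle envelope peak;
#'   0 is the SO up-state under the cosine convention.
#' @param coupling_kappa von Mises concentration (>= 0; 0 = uniform phase).
#' @param coupled_fraction fraction of spindles planted on an SO, in [0, 1].
#' @param event_stages stages eligible for event planting (default "N3").
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a \code{sim_config} list.
#' @examples
#' cfg <- sim_config(sampling_rate = 128, channel_labels = "Cz",
#'                   stage_plan = data.frame(stage = "N3", duration = 120))
#' sim <- generate_recording(cfg)
#' sim$recording
#' head(sim$truth$spindle_events)
#' @export
sim_config <- function(sampling_rate = 500,
                       channel_labels = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                                          "P3", "Pz", "P4", "O1", "O2"),
                       stage_plan = data.frame(
                         stage = c("W", "N2", "N3"),
                         duration = c(30, 300, 1200)),
                       fractal_slope = 2,
                       fractal_offset = 15,
                       so_rate = 4,
                       so_cycles = 2,
                       so_freq = 0.75,
                       so_amplitude = 75,
                       spindle_rate = 2,
                       spindle_freq = 13,
                       spindle_duration = 1,
                       spindle_amplitude = 20,
                       coupling_mu = 0,
                       coupling_kappa = 4,
                       coupled_fraction = 0.8,
                       event_stages = "N3",
                       seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, channel_labels = channel_labels,
              stage_plan = stage_plan, fractal_slope = fractal_slope,
              fractal_offset = fractal_offset, so_rate = so_rate,
              so_cycles = so_cycles,
              so_freq = so_freq, so_amplitude = so_amplitude,
              spindle_rate = spindle_rate, spindle_freq = spindle_freq,
              spindle_duration = spindle_duration,
              spindle_amplitude = spindle_amplitude,
              coupling_mu = coupling_mu, coupling_kappa = coupling_kappa,
              coupled_fraction = coupled_fraction,
              event_stages = event_stages, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (cfg$so_freq <= 0 || cfg$so_freq >= 2) stop("so_freq must lie in (0, 2)")
  if (cfg$spindle_rate > 0 &&
      (cfg$spindle_freq < 10 || cfg$spindle_freq > 17))
    stop("spindle_freq must lie in [10, 17]")
  if (cfg$spindle_duration < 0.5 || cfg$spindle_duration > 3)
    stop("spindle_duration must lie in [0.5, 3]")
  if (cfg$coupling_kappa < 0) stop("coupling_kappa must be >= 0")
  if (cfg$coupled_fraction < 0 || cfg$coupled_fraction > 1)
    stop("coupled_fraction must lie in [0, 1]")
  stopifnot(all(c("stage", "duration") %in% names(cfg$stage_plan)))
  invisible(cfg)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; \code{kappa = 0} reduces to the
#' uniform distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(wrap_phase(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_phase(out + mu)
}

#' Estimate the von Mises concentration from a mean resultant length
#'
#' Inverts the ratio \eqn{A(\kappa) = I_1(\kappa)/I_0(\kappa)} with the
#' standard piecewise approximation (Fisher 1993).
#'
#' @param R mean resultant length in [0, 1), e.g. from
#'   [coupling_strength()].
#' @return estimated concentration kappa.
#' @export
estimate_kappa <- function(R) {
  stopifnot(R >= 0, R < 1)
  if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
  else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
  else 1 / (R^3 - 4 * R^2 + 3 * R)
}

# 1/f^alpha Gaussian noise via spectral shaping, normalized to the target
# SD. The spectrum plateaus below f_plateau (amplifier high-pass / slow
# drift knee): without it an unbounded 1/f^alpha concentrates essentially
# all variance in the sub-0.01 Hz range, which no scalp recording shows.
# Above f_plateau the log-log slope is exactly -alpha.
fractal_noise <- function(n, alpha, sd_target, fs, f_plateau = 0.3) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w * sd_target / stats::sd(w))
  k <- 0:(n - 1)
  k2 <- pmin(k, n - k)            # two-sided bin index
  f <- k2 * fs / n
  shape <- pmax(f, f_plateau)^(-alpha / 2)
  shape[1] <- 0                   # keep the realization zero-mean
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x * sd_target / stats::sd(x)
}

# Hypnogram realizing a stage plan on the epoch grid.
plan_hypnogram <- function(stage_plan, epoch_length = 30) {
  stages <- unlist(mapply(function(st, d) {
    rep(st, ceiling(d / epoch_length))
  }, stage_plan$stage, stage_plan$duration, SIMPLIFY = FALSE))
  hypnogram(as.character(stages), epoch_length)
}

# Sample event center times inside stage runs, keeping min_gap between
# events and margin from run edges. Errors out when the requested count
# cannot be placed.
place_times <- function(runs, fs, n_events, min_gap, margin,
                        avoid = numeric(0), avoid_gap = 0) {
  if (n_events == 0) return(numeric(0))
  lo <- (runs[, 1] - 1) / fs + margin
  hi <- runs[, 2] / fs - margin
  ok <- hi > lo
  lo <- lo[ok]; hi <- hi[ok]
  if (!length(lo)) stop("recording too short to place requested events")
  lens <- hi - lo
  placed <- numeric(0)
  tries <- 0L
  while (length(placed) < n_events) {
    tries <- tries + 1L
    if (tries > 200L * n_events)
      stop("recording too short to place requested events")
    r <- sample.int(length(lo), 1, prob = lens)
    t0 <- stats::runif(1, lo[r], hi[r])
    if (length(placed) && min(abs(placed - t0)) < min_gap) next
    if (length(avoid) && min(abs(avoid - t0)) < avoid_gap) next
    placed <- c(placed, t0)
  }
  sort(placed)
}

#' Generate a synthetic sleep-EEG recording with ground truth
#'
#' Builds a multichannel recording as 1/f background noise (independent per
#' channel) plus planted SO waveforms (one negative then one positive
#' half-wave of a sinusoid at \code{so_freq}) and spindle bursts (sinusoid
#' at \code{spindle_freq} under a Gaussian envelope, sigma = duration/6).
#' Event times are shared across channels, as scalp SOs and spindles are
#' largely global. For coupled spindles the envelope peak is placed where
#' the SO waveform phase equals a von Mises(mu, kappa) draw, under the
#' cosine convention (up-state peak = 0 rad, trough = +/-pi). Uncoupled
#' spindles are planted at least 3 s away from any SO trough as negative
#' controls for co-occurrence gating.
#'
#' @param config a [sim_config()].
#' @return list with elements \code{recording} ([eeg_recording()]),
#'   \code{hypnogram} ([hypnogram()]) and \code{truth}, a list of
#'   \code{so_events}, \code{spindle_events} (data.frames; times in s) and
#'   the configuration echo.
#' @export
generate_recording <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    fs <- config$sampling_rate
    hyp <- plan_hypnogram(config$stage_plan)
    n <- length(hyp$stages) * hyp$epoch_length * fs
    nch <- length(config$channel_labels)
    sig <- matrix(0, nch, n)
    for (ch in seq_len(nch))
      sig[ch, ] <- fractal_noise(n, config$fractal_slope,
                                 config$fractal_offset, fs)

    runs <- stage_runs(hyp, config$event_stages, fs, n)
    elig_min <- if (nrow(runs)) sum(runs[, 2] - runs[, 1] + 1) / fs / 60 else 0
    nc <- max(1L, round(config$so_cycles))
    n_train <- round(config$so_rate * elig_min / nc)
    n_so <- n_train * nc
    n_sp <- round(config$spindle_rate * elig_min)
    if ((n_so > 0 || n_sp > 0) && nrow(runs) == 0)
      stop("no eligible stage epochs to place events in")

    so_T <- 1 / config$so_freq
    train_T <- nc * so_T
    so_margin <- train_T / 2 + 3    # keep full waveform + epoch margin inside
    so_t0 <- place_times(runs, fs, n_train, min_gap = train_T + 1.5,
                         margin = so_margin)
    # SO train: -A*sin(2*pi*f*tau) over nc cycles; troughs at T/4 + k*T,
    # up-state peaks at 3T/4 + k*T.  Event times index the troughs.
    so_trough <- sort(rep(so_t0, each = nc) +
                        so_T / 4 + (seq_len(nc) - 1) * so_T)
    so_uppeak <- so_t0 + 3 * so_T / 4          # host peak: first cycle
    tt <- seq(0, train_T, by = 1 / fs)
    so_wave <- -config$so_amplitude * sin(2 * pi * config$so_freq * tt)
    # raised-cosine ends (10% of a cycle each side) give a C1-smooth
    # junction with the background; an abrupt derivative step would inject
    # broadband clicks that masquerade as spindle-band events
    nr <- max(2L, round(0.1 * so_T * fs))
    ramp <- (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1))) / 2
    so_wave[seq_len(nr)] <- so_wave[seq_len(nr)] * ramp
    n_w <- length(so_wave)
    so_wave[(n_w - nr + 1):n_w] <- so_wave[(n_w - nr + 1):n_w] * rev(ramp)
    for (t0 in so_t0) {
      i0 <- round(t0 * fs) + 1
      idx <- i0:(i0 + length(so_wave) - 1)
      sig[, idx] <- sig[, idx] + rep(so_wave, each = nch)
    }

    n_coupled <- round(config$coupled_fraction * n_sp)
    if (n_coupled > n_train)
      stop("not enough slow oscillations to host the requested coupled ",
           "spindles; increase so_rate or duration")
    host <- if (n_coupled > 0) sample(seq_along(so_t0), n_coupled) else integer(0)
    planted_phase <- if (n_coupled > 0)
      rvonmises(n_coupled, config$coupling_mu, config$coupling_kappa)
    else numeric(0)
    # phase theta maps to time uppeak + theta/(2*pi*f)
    sp_coup_t <- so_uppeak[host] + planted_phase / (2 * pi * config$so_freq)

    n_unc <- n_sp - n_coupled
    sp_unc_t <- place_times(runs, fs, n_unc,
                            min_gap = config$spindle_duration + 1,
                            margin = config$spindle_duration + 3,
                            avoid = so_trough, avoid_gap = 3)
    sp_t <- c(sp_coup_t, sp_unc_t)
    sp_phase <- c(planted_phase, rep(NA_real_, n_unc))
    sp_coupled <- c(rep(TRUE, n_coupled), rep(FALSE, n_unc))

    sigma <- config$spindle_duration / 6
    half <- config$spindle_duration / 2
    tt <- seq(-half, half, by = 1 / fs)
    for (k in seq_along(sp_t)) {
      burst <- config$spindle_amplitude * exp(-tt^2 / (2 * sigma^2)) *
        cos(2 * pi * config$spindle_freq * tt)
      i0 <- round((sp_t[k] - half) * fs) + 1
      idx <- i0:(i0 + length(burst) - 1)
      idx_ok <- idx >= 1 & idx <= n
      sig[, idx[idx_ok]] <- sig[, idx[idx_ok]] + rep(burst[idx_ok], each = nch)
    }

    ord <- order(sp_t)
    truth <- list(
      so_events = if (n_so > 0) do.call(rbind, lapply(
        config$channel_labels, function(ch)
          data.frame(channel = ch, trough_time = so_trough,
                     uppeak_time = so_uppeak))) else
        data.frame(channel = character(0), trough_time = numeric(0),
                   uppeak_time = numeric(0)),
      spindle_events = if (n_sp > 0) do.call(rbind, lapply(
        config$channel_labels, function(ch)
          data.frame(channel = ch, peak_time = sp_t[ord],
                     frequency = config$spindle_freq,
                     coupled = sp_coupled[ord],
                     planted_phase = sp_phase[ord]))) else
        data.frame(channel = character(0), peak_time = numeric(0),
                   frequency = numeric(0), coupled = logical(0),
                   planted_phase = numeric(0)),
      planted_phase = planted_phase,
      config = config)

    rec <- eeg_recording(sig, fs, config$channel_labels)
    list(recording = rec, hypnogram = hyp, truth = truth)
  })
}

#' Generate a synthetic behavioral cohort tied to coupling concentration
#'
#' Draws a per-subject von Mises concentration kappa and constructs an
#' overnight task-proficiency gain whose rank correlation with kappa
#' matches \code{target_rho}: a noise component is blended with the
#' normal scores of the kappa ranks, and the blend weight is calibrated
#' so the sample Spearman correlation itself lands on the target (the
#' closest achievable value; exact monotone construction at |rho| = 1).
#' Block-level cascade counts follow a noisy linear within-test model
#' (truncated at zero and rounded to integers) consistent with the
#' learning-curve fit: the test-2 proficiency (y1) exceeds the test-1
#' proficiency by exactly the latent \code{gain}, and the slope flattens
#' in proportion to the gain (the proficiency/learning-curve trade-off).
#'
#' @param n_subjects number of subjects (>= 4).
#' @param kappa_range interval the subject kappas are drawn from.
#' @param target_rho target Spearman correlation between kappa and the
#'   overnight proficiency gain, in [-1, 1].
#' @param noise SD of the block-score noise (cascades); 0 gives exact
#'   latent counts.
#' @param seed integer seed.
#' @param base_config a [sim_config()] used as template for the per-subject
#'   EEG configurations (kappa and spindle frequency are overridden).
#' @param age_groups vector of "adolescent"/"adult" recycled over subjects;
#'   adolescents do 3 blocks per test, adults 5.
#' @return list with \code{configs} (per-subject [sim_config()]s),
#'   \code{behavior} (block-level data.frame), and \code{truth}
#'   (per-subject latents: kappa, baseline, learning rate, overnight gain).
#' @export
generate_cohort <- function(n_subjects, kappa_range = c(0.5, 6),
                            target_rho = 0.6, noise = 1.5, seed = 1L,
                            base_config = sim_config(),
                            age_groups = c("adolescent", "adult")) {
  if (n_subjects < 4) stop("n_subjects must be >= 4")
  if (abs(target_rho) > 1) stop("|target_rho| must be <= 1")
  with_seed(seed, {
    kappa <- stats::runif(n_subjects, kappa_range[1], kappa_range[2])
    zk <- stats::qnorm(rank(kappa, ties.method = "average") /
                         (n_subjects + 1))
    if (abs(target_rho) == 1) {
      lat <- sign(target_rho) * zk
    } else {
      eps <- stats::rnorm(n_subjects)
      # calibrate the blend weight so the sample Spearman hits the target
      lams <- seq(0, 1, by = 0.001)
      achieved <- vapply(lams, function(l) {
        stats::cor(kappa, l * zk + (1 - l) * eps, method = "spearman")
      }, numeric(1))
      lam <- lams[which.min(abs(achieved - abs(target_rho)))]
      lat <- sign(target_rho) * (lam * zk + (1 - lam) * eps)
    }
    lat <- (lat - mean(lat)) / max(stats::sd(lat), 1e-12)
    gain <- 5 + 3 * lat                     # overnight change in y1, cascades

    baseline <- pmax(2, stats::rnorm(n_subjects, 15, 5))  # test-1 proficiency
    rate <- pmax(0.5, stats::rnorm(n_subjects, 4, 1))     # blocks slope
    age <- rep_len(age_groups, n_subjects)
    group <- rep_len(c("sleep_first", "wake_first"), n_subjects)

    rows <- list()
    truth_m <- matrix(NA_real_, n_subjects, 3)
    for (i in seq_len(n_subjects)) {
      nb <- if (age[i] == "adolescent") 3 else 5
      m1 <- rate[i]
      y1_1 <- baseline[i]
      y1_2 <- y1_1 + gain[i]
      m2 <- max(0, m1 - 0.5 * gain[i])   # proficiency gain flattens the slope
      y1_3 <- y1_2 + m2 * (nb - 1) * 0.5
      m3 <- m2
      y1s <- c(y1_1, y1_2, y1_3); ms <- c(m1, m2, m3)
      truth_m[i, ] <- ms
      for (tst in 1:3) {
        x <- seq_len(nb)
        latent <- y1s[tst] + ms[tst] * (x - 1)
        score <- round(pmax(0, latent +
                              if (noise > 0) stats::rnorm(nb, 0, noise)
                              else 0))
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("S%02d", i), group = group[i],
          age_group = age[i], test = tst, block = x, cascades = score)
      }
    }
    behavior <- do.call(rbind, rows)

    configs <- lapply(seq_len(n_subjects), function(i) {
      cfg <- base_config
      cfg$coupling_kappa <- kappa[i]
      cfg$spindle_freq <- stats::runif(1, 11, 15)
      cfg$seed <- as.integer((seed + i * 1000L) %% .Machine$integer.max)
      class(cfg) <- "sim_config"
      cfg
    })
    names(configs) <- sprintf("S%02d", seq_len(n_subjects))

    truth <- data.frame(subject = sprintf("S%02d", seq_len(n_subjects)),
                        kappa = kappa, baseline = baseline,
                        learning_rate = rate, gain_y1 = gain,
                        age_group = age, group = group)
    list(configs = configs, behavior = behavior, truth = truth)
  })
}
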