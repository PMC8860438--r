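# Small deterministic fixtures shared across the suite.

# Compact single/few-channel simulation config for unit tests.
quick_cfg <- function(channels = "Cz", n3_s = 600, fs = 128, ...) {
  sim_config(sampling_rate = fs, channel_labels = channels,
             stage_plan = data.frame(stage = "N3", duration = n3_s), ...)
}

# Recording holding pure sinusoids (one per channel frequency).
sine_recording <- function(freqs, fs = 128, dur = 120, amp = 1,
                           labels = paste0("ch", seq_along(freqs))) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- do.call(rbind, lapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  eeg_recording(sig, fs, labels)
}

all_stage_hyp <- function(stage, dur_s, epoch = 30) {
  hypnogram(rep(stage, ceiling(dur_s / epoch)), epoch)
}

# Greedy match of detections to ground-truth times within a tolerance;
# returns precision/recall/F1. Independent of the detector internals.
match_events <- function(detected, truth, tol = 0.25) {
  if (!length(detected))
    return(c(precision = NA_real_, recall = 0, f1 = 0))
  tp <- sum(vapply(truth, function(t0) any(abs(detected - t0) <= tol),
                   logical(1)))
  fp <- sum(vapply(detected, function(d) all(abs(truth - d) > tol),
                   logical(1)))
  precision <- (length(detected) - fp) / length(detected)
  recall <- tp / length(truth)
  c(precision = precision, recall = recall,
    f1 = 2 * precision * recall / (precision + recall))
}

# Hand-built event_set with given centers and epochs (for gating tests).
toy_event_set <- function(kind, channel, centers, fs = 100, half_s = 2.5,
                          epoch_fun = function(n) stats::rnorm(n)) {
  nsamp <- 2 * round(half_s * fs) + 1
  n <- length(centers)
  ev <- data.frame(id = seq_len(n),
                   channel = rep_len(channel, n),
                   center_time = centers, onset = centers - 0.5,
                   offset = centers + 0.5, duration = rep(1, n),
                   amplitude = rep(1, n), stage = rep("N3", n))
  ep <- t(vapply(seq_along(centers), function(i) epoch_fun(nsamp),
                 numeric(nsamp)))
  sospindle:::new_event_set(kind, ev, ep, fs, half_s)
}
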