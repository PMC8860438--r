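peaks_for <- function(cfg) {
  data.frame(channel = cfg$channel_labels,
             spindle_peak_freq = cfg$spindle_freq)
}

test_that("spindle detector recovers planted events with high recall", {
  cfg <- quick_cfg(n3_s = 600, seed = 51)
  sim <- generate_recording(cfg)
  det <- detect_spindles(sim$recording, sim$hypnogram, peaks_for(cfg), "N3")
  m <- match_events(det$events$center_time,
                    sim$truth$spindle_events$peak_time)
  expect_gte(m["recall"], 0.9)
  # percentile-threshold detections also fire on background fluctuations;
  # the detector's amplitude criterion is relative, so this is intrinsic
  expect_true(nrow(det$events) >= sum(sim$truth$spindle_events$coupled >= 0))
})

test_that("spindle detection is invariant to a global gain change", {
  cfg <- quick_cfg(n3_s = 300, seed = 52)
  sim <- generate_recording(cfg)
  det1 <- detect_spindles(sim$recording, sim$hypnogram, peaks_for(cfg), "N3")
  rec10 <- sim$recording; rec10$signal <- rec10$signal * 10
  det10 <- detect_spindles(rec10, sim$hypnogram, peaks_for(cfg), "N3")
  expect_equal(det1$events$center_time, det10$events$center_time)
  so1 <- detect_slow_oscillations(sim$recording, sim$hypnogram, "N3")
  so10 <- detect_slow_oscillations(rec10, sim$hypnogram, "N3")
  expect_equal(so1$events$center_time, so10$events$center_time)
})

test_that("raising the percentile never increases the event count", {
  cfg <- quick_cfg(n3_s = 300, seed = 53)
  sim <- generate_recording(cfg)
  counts <- vapply(c(60, 75, 90), function(p)
    nrow(detect_spindles(sim$recording, sim$hypnogram, peaks_for(cfg),
                         "N3", percentile = p)$events), numeric(1))
  expect_true(all(diff(counts) <= 0))
  so_counts <- vapply(c(60, 75, 90), function(p)
    nrow(detect_slow_oscillations(sim$recording, sim$hypnogram, "N3",
                                  percentile = p)$events), numeric(1))
  expect_true(all(diff(so_counts) <= 0))
})

test_that("a pure sinusoid produces no spindle events (duration ceiling)", {
  rec <- sine_recording(13, dur = 120)
  hyp <- all_stage_hyp("N3", 120)
  pk <- data.frame(channel = "ch1", spindle_peak_freq = 13)
  det <- detect_spindles(rec, hyp, pk, "N3")
  expect_equal(nrow(det$events), 0)
})

test_that("events whose epoch would cross the recording end are dropped", {
  fs <- 128; dur <- 60
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- rnorm(length(t)) * 0.5
  burst <- function(t0) 20 * exp(-(t - t0)^2 / (2 * (1 / 6)^2)) *
    cos(2 * pi * 13 * (t - t0))
  x <- x + burst(30) + burst(dur - 1)       # one clean, one at the edge
  rec <- eeg_recording(matrix(x, 1), fs, "Cz")
  hyp <- all_stage_hyp("N3", dur)
  det <- detect_spindles(rec, hyp,
                         data.frame(channel = "Cz", spindle_peak_freq = 13),
                         "N3")
  expect_true(all(det$events$center_time <= dur - 2.5))
  expect_true(any(abs(det$events$center_time - 30) < 0.25))
  expect_gte(attr(det, "dropped"), 1)
})

test_that("slow-oscillation detector honors time and amplitude criteria", {
  # the 75th-percentile criterion keeps the top quarter of candidates, so
  # precision against planted truth is capped by the plant share of the
  # candidate pool (~0.66 at these densities); recall is the fidelity axis
  stats <- t(vapply(55:57, function(s) {
    cfg <- quick_cfg(n3_s = 1200, seed = s)
    sim <- generate_recording(cfg)
    det <- detect_slow_oscillations(sim$recording, sim$hypnogram, "N3")
    expect_true(all(det$events$duration >= 0.8 & det$events$duration <= 2))
    match_events(det$events$center_time,
                 unique(sim$truth$so_events$trough_time))
  }, c(precision = 0, recall = 0, f1 = 0)))
  expect_gte(median(stats[, "recall"]), 0.85)
  expect_gte(median(stats[, "f1"]), 0.7)
})

test_that("a 3 Hz sinusoid yields no slow oscillations (half-waves too short)", {
  rec <- sine_recording(3, dur = 60)
  hyp <- all_stage_hyp("N3", 60)
  expect_warning(det <- detect_slow_oscillations(rec, hyp, "N3"),
                 "candidates")
  expect_equal(nrow(det$events), 0)
})

test_that("identical candidate amplitudes all pass the tie-inclusive rule", {
  # 100 identical candidates: the percentile threshold equals the common
  # value and the >= comparison keeps every one
  amps <- rep(42, 100)
  thr <- amplitude_threshold(amps, 75)
  expect_equal(thr, 42)
  expect_true(all(amps >= thr))
  # linear interpolation between order statistics (a stated convention)
  expect_equal(amplitude_threshold(1:5, 75), 4)
  expect_equal(amplitude_threshold(c(0, 10), 75), 7.5)
})

test_that("a clean SO train is detected cycle by cycle", {
  rec <- sine_recording(0.8, dur = 120, amp = 50)
  hyp <- all_stage_hyp("N3", 120)
  det <- detect_slow_oscillations(rec, hyp, "N3")
  # the percentile criterion keeps the top quarter of (numerically almost
  # identical) cycles; each kept event is a full 1.25-s cycle at a trough
  expect_gte(nrow(det$events), 20)
  expect_true(all(abs(det$events$duration - 1.25) < 0.02))
  troughs <- sort(det$events$center_time)
  expect_lt(max(abs(troughs %% 1.25 - mean(troughs %% 1.25))), 0.02)
})

test_that("epoch z-normalization standardizes and drops degenerate epochs", {
  cfg <- quick_cfg(n3_s = 180, seed = 56)
  sim <- generate_recording(cfg)
  det <- detect_spindles(sim$recording, sim$hypnogram, peaks_for(cfg), "N3")
  z <- znorm_epochs(det)
  expect_equal(unname(rowMeans(z$norm_epochs)),
               rep(0, nrow(z$norm_epochs)), tolerance = 1e-6)
  expect_equal(unname(apply(z$norm_epochs, 1, sd)),
               rep(1, nrow(z$norm_epochs)), tolerance = 1e-6)
  # gain invariance of the normalized epochs
  det10 <- det; det10$epochs <- det10$epochs * 10
  expect_equal(znorm_epochs(det10)$norm_epochs, z$norm_epochs,
               tolerance = 1e-9)
  # constant epoch is dropped with a warning
  flat <- det
  flat$epochs[1, ] <- 5
  expect_warning(zf <- znorm_epochs(flat), "zero-variance")
  expect_equal(nrow(zf$events), nrow(det$events) - 1)
})

test_that("co-occurrence gating keeps spindles with a nearby SO partner", {
  sp <- toy_event_set("spindle", "Cz", c(100, 200, 300))
  so <- toy_event_set("slow_oscillation", "Cz", c(101, 203, 299.6, 302))
  g <- gate_cooccurrence(sp, so, window = 2.5)
  expect_equal(g$events$center_time, c(100, 300))
  expect_equal(g$events$lag[1], 1.0)          # SO trough - spindle peak
  expect_equal(g$events$lag[2], -0.4)         # nearest of -0.4 and +2.0
  # spindle at 200 has nearest SO 3 s away: dropped
  expect_false(200 %in% g$events$center_time)
  # partner must be on the same channel
  so_other <- toy_event_set("slow_oscillation", "C4", c(100.5))
  g2 <- gate_cooccurrence(sp, so_other, window = 2.5)
  expect_equal(nrow(g2$events), 0)
})

test_that("co-occurrence rate reflects the planted coupled fraction", {
  cfg <- quick_cfg(n3_s = 900, spindle_rate = 4, coupled_fraction = 0.5,
                   seed = 57)
  sim <- generate_recording(cfg)
  tr <- sim$truth$spindle_events
  sp <- toy_event_set("spindle", "Cz", tr$peak_time)
  so <- toy_event_set("slow_oscillation", "Cz",
                      unique(sim$truth$so_events$trough_time))
  rate <- cooccurrence_rate(sp, so, sim$hypnogram)
  expect_equal(rate$rate[rate$stage == "N3"], 0.5, tolerance = 0.1)
  # uncoupled plants are guaranteed >= 3 s from any SO trough
  unc <- tr$peak_time[!tr$coupled]
  gaps <- vapply(unc, function(t0)
    min(abs(unique(sim$truth$so_events$trough_time) - t0)), numeric(1))
  expect_true(all(gaps >= 3))
  # a stage with no spindles reports NA, not zero
  sp_none <- toy_event_set("spindle", "Cz", numeric(0))
  expect_equal(nrow(sp_none$events), 0)
})
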