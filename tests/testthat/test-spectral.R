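test_that("time-domain z-normalization behaves as a proper standardization", {
  rec <- sine_recording(c(5, 9), dur = 30)
  z <- znorm_signal(rec)
  expect_equal(unname(rowMeans(z$signal)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z$signal, 1, sd)), c(1, 1), tolerance = 1e-12)
  # idempotent and gain-invariant
  z2 <- znorm_signal(z)
  expect_equal(z2$signal, z$signal, tolerance = 1e-12)
  rec10 <- rec; rec10$signal <- rec10$signal * 10
  expect_equal(znorm_signal(rec10)$signal, z$signal, tolerance = 1e-12)
  # zero-variance channel errors with the channel named
  bad <- eeg_recording(rbind(rnorm(100), rep(1, 100)), 10, c("good", "flat"))
  expect_error(znorm_signal(bad), "flat")
})

test_that("sliding Hanning spectrum localizes a pure tone", {
  rec <- sine_recording(10, dur = 60)
  hyp <- all_stage_hyp("N3", 60)
  sp <- compute_spectrum(rec, hyp, "N3", fmin = 0.5, fmax = 30)
  peak_bin <- which.max(sp$power[1, ])
  expect_lt(abs(sp$freqs[peak_bin] - 10), 0.1)
  away <- abs(sp$freqs - 10) >= 1
  expect_true(all(sp$power[1, peak_bin] > sp$power[1, away]))
  # requesting an absent stage errors
  expect_error(compute_spectrum(rec, hyp, "REM"), "REM")
})

test_that("white-noise spectrum is flat in log-log space", {
  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(128 * 300), 1), 128, "Cz")
  hyp <- all_stage_hyp("N3", 300)
  sp <- compute_spectrum(rec, hyp, "N3", fmin = 1, fmax = 20, step_s = 5)
  slope <- unname(coef(lm(log(sp$power[1, ]) ~ log(sp$freqs)))[2])
  expect_lt(abs(slope), 0.1)
})

test_that("spectrum set stores an exactly additive decomposition", {
  cfg <- quick_cfg(n3_s = 120, seed = 8)
  sim <- generate_recording(cfg)
  ss <- compute_spectra(sim$recording, sim$hypnogram, "N3", step_s = 10)
  expect_equal(ss$residual, ss$total - ss$fractal, tolerance = 1e-12)
  expect_true(all(diff(ss$freqs) > 0))
})

test_that("IRASA isolates an oscillatory peak from 1/f background", {
  cfg <- quick_cfg(n3_s = 300, so_rate = 0, spindle_rate = 0,
                   fractal_slope = 1, seed = 12)
  sim <- generate_recording(cfg)
  # add a 13 Hz oscillation on top of the pure 1/f background
  t <- seq_len(ncol(sim$recording$signal)) / 128
  osc <- sim$recording
  osc$signal[1, ] <- osc$signal[1, ] + 6 * sin(2 * pi * 13 * t)
  ss <- compute_spectra(osc, sim$hypnogram, "N3", fmin = 2, fmax = 20,
                        step_s = 5)
  fpk <- ss$freqs[which.max(ss$residual[1, ])]
  expect_lt(abs(fpk - 13), 0.5)
  # fractal estimate carries no major peak at the planted frequency
  at13 <- abs(ss$freqs - 13) <= 0.2
  expect_lt(max(ss$fractal[1, at13]), 0.2 * max(ss$total[1, at13]))
})

test_that("residual of pure 1/f noise is small relative to total power", {
  # long simulation: the residual is pure estimator noise shrinking as
  # 1/sqrt(windows)
  cfg <- quick_cfg(n3_s = 3600, fs = 64, so_rate = 0, spindle_rate = 0,
                   fractal_slope = 1, seed = 13)
  sim <- generate_recording(cfg)
  ss <- compute_spectra(sim$recording, sim$hypnogram, "N3",
                        fmin = 2, fmax = 20, step_s = 5)
  expect_lt(mean(abs(ss$residual[1, ])), 0.05 * mean(ss$total[1, ]))
})

test_that("peak finding follows the argmax-of-local-maxima rule", {
  freqs <- seq(0.2, 20, by = 0.1)
  bump <- function(f0, a, w = 0.5) a * exp(-(freqs - f0)^2 / (2 * w^2))
  mk <- function(y) structure(list(freqs = freqs, total = rbind(y),
                                   fractal = rbind(0 * y), residual = rbind(y),
                                   channel_labels = "Cz"),
                              class = "spectrum_set")
  one <- find_peaks(mk(bump(0.8, 1) + bump(12.5, 0.5)))
  expect_equal(one$spindle_peak_freq, 12.5, tolerance = 0.05)
  expect_equal(one$so_peak_freq, 0.8, tolerance = 0.05)
  expect_false(one$spindle_flagged)
  two <- find_peaks(mk(bump(0.8, 1) + bump(11, 0.4) + bump(14, 0.6)))
  expect_equal(two$spindle_peak_freq, 14, tolerance = 0.05)
  # monotone residual in the band: flagged, endpoint returned, warning
  expect_warning(mono <- find_peaks(mk(1 / freqs)), "band maximum")
  expect_true(mono$spindle_flagged)
  expect_equal(mono$spindle_peak_freq, freqs[which(freqs > 10)][1],
               tolerance = 0.05)
  # grid not covering the band errors
  short <- mk(bump(0.8, 1))
  short$freqs <- freqs[freqs < 5]
  short$residual <- short$residual[, freqs < 5, drop = FALSE]
  expect_error(find_peaks(short), "cover")
})

test_that("IRASA recovers fractal slopes across exponents", {
  # module-level single exponent; the full grid runs in the acceptance suite
  cfg <- quick_cfg(n3_s = 300, so_rate = 0, spindle_rate = 0,
                   fractal_slope = 1.5, seed = 14)
  sim <- generate_recording(cfg)
  fr <- irasa_fractal(sim$recording, sim$hypnogram, "N3",
                      fmin = 1, fmax = 20, step_s = 5)
  slope <- unname(coef(lm(log(fr$power[1, ]) ~ log(fr$freqs)))[2])
  expect_lt(abs(slope + 1.5), 0.15)
})
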