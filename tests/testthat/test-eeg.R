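test_that("band-pass passes the band and kills drift, with zero phase", {
  srate <- 1000
  t <- (0:19999) / srate
  tone <- sin(2 * pi * 8 * t)
  drift <- sin(2 * pi * 0.2 * t)
  y_tone <- bandpass(tone, 1, 30, srate = srate)
  y_drift <- bandpass(drift, 1, 30, srate = srate)
  mid <- 5000:15000
  gain_tone <- sqrt(mean(y_tone[mid]^2) / mean(tone[mid]^2))
  gain_drift <- sqrt(mean(y_drift[mid]^2) / mean(drift[mid]^2))
  expect_lt(abs(gain_tone - 1), 0.01)
  expect_lt(20 * log10(gain_drift), -40)
  # zero phase: cross-correlation between input and output peaks at lag 0
  burst <- exp(-((t - 10)^2) / 0.5) * sin(2 * pi * 10 * t)
  y_burst <- bandpass(burst, 1, 30, srate = srate)
  lags <- -100:100
  xc <- vapply(lags, function(l) {
    i <- 3000:17000
    sum(burst[i] * y_burst[i + l])
  }, numeric(1))
  expect_lte(abs(lags[which.max(xc)]), 1)
  expect_error(bandpass(tone, 30, 1, srate = srate), "invalid band")
  expect_error(bandpass(tone, 1, 600, srate = srate), "invalid band")
})

test_that("Laplacian reference is the central-minus-surround mean", {
  rec <- quick_eeg()
  rec$data[] <- 0
  ci <- match(SSVEP_MONTAGE$central, rec$channels)
  si <- match(SSVEP_MONTAGE$surround, rec$channels)
  rec$data[ci, ] <- 3; rec$data[si, ] <- 1.25
  expect_equal(unique(laplacian_reference(rec)$data), 3 - 1.25)
  # common-mode rejection
  rec$data[] <- rep(rnorm(ncol(rec$data)), each = nrow(rec$data))
  expect_lt(max(abs(laplacian_reference(rec)$data)), 1e-10)
  # central-only planted component passes at full amplitude
  t <- (seq_len(ncol(rec$data)) - 1) / rec$srate
  rec$data[] <- 0
  rec$data[ci, ] <- rep(0.7 * sin(2 * pi * 8 * t), each = length(ci))
  lap <- laplacian_reference(rec)
  expect_lt(abs(sqrt(2 * mean(lap$data^2)) - 0.7), 0.007)
  rec$channels[1] <- "XX"
  expect_error(laplacian_reference(rec), "O1")
})

test_that("trial averaging windows correctly and gains ~sqrt(n) in SNR", {
  rec <- quick_eeg(n_trials = 1)
  lap <- laplacian_reference(rec)
  avg <- average_trials(lap, rec$trials$condition[1], window = c(1, 6))
  expect_length(avg, 5 * rec$srate)
  expect_equal(attr(avg, "n_trials"), 1)
  one <- lap$data[rec$trials$onset_sample[1] + (1000:5999)]
  expect_equal(as.numeric(avg), one)
  expect_error(average_trials(lap, "nope"), "no trials")
  # sqrt(n) SNR gain with phase-locked signal + white noise
  set.seed(5)
  n_tr <- 20; ns <- 1000
  sig <- sin(2 * pi * 8 * (0:(ns - 1)) / 1000)
  trials <- vapply(1:n_tr, function(i) sig + rnorm(ns, sd = 1), numeric(ns))
  err_one <- sd(trials[, 1] - sig)
  err_avg <- sd(rowMeans(trials) - sig)
  expect_lt(abs(err_one / err_avg - sqrt(n_tr)) / sqrt(n_tr), 0.2)
})

test_that("amplitude spectrum normalisation, leakage, and Parseval", {
  srate <- 1000; t <- (0:4999) / srate
  x <- sin(2 * pi * 8 * t)
  sp <- amplitude_spectrum(x, srate)
  expect_equal(attr(sp, "resolution"), 0.2)
  expect_equal(sp$amp[sp$freq == 8], 1, tolerance = 1e-9)
  x2 <- 2 * sin(2 * pi * 7.2 * t) + 0.5 * cos(2 * pi * 8 * t)
  sp2 <- amplitude_spectrum(x2, srate)
  expect_equal(sp2$amp[sp2$freq == 7.2], 2, tolerance = 1e-9)
  expect_equal(sp2$amp[sp2$freq == 8], 0.5, tolerance = 1e-9)
  expect_lt(max(sp2$amp[!sp2$freq %in% c(7.2, 8)]), 1e-9)
  # Parseval: signal energy from the single-sided amplitudes
  n <- length(x2)
  mid <- sp2$amp[2:(nrow(sp2) - 1)] # n is even: last row is Nyquist
  energy_spec <- n * (sp2$amp[1]^2 + sp2$amp[nrow(sp2)]^2 + sum(mid^2) / 2)
  expect_equal(energy_spec, sum(x2^2), tolerance = 1e-6)
})

test_that("tagged amplitude sums the first two harmonics", {
  srate <- 1000; t <- (0:4999) / srate
  x <- 2 * sin(2 * pi * 7.2 * t) + 1 * sin(2 * pi * 14.4 * t)
  sp <- amplitude_spectrum(x, srate)
  expect_equal(tagged_amplitude(sp, 7.2), 3, tolerance = 1e-9)
  expect_error(tagged_amplitude(sp, 7.25), "off-grid")
})

test_that("intermodulation amplitude sits on its own bin", {
  srate <- 1000; t <- (0:4999) / srate
  x <- sin(2 * pi * 14.4 * t) + sin(2 * pi * 16 * t) +
    0.5 * sin(2 * pi * 15.2 * t)
  sp <- amplitude_spectrum(x, srate)
  expect_equal(im_amplitude(sp, 7.2, 8), 0.5, tolerance = 1e-9)
  # the IM bin is distinct from both second harmonics
  expect_false(15.2 %in% c(14.4, 16))
  expect_error(im_amplitude(sp, 300, 300), "Nyquist")
})

test_that("monocular recordings carry only that eye's tags; no IM", {
  truth <- ssvep_truth(noise_sd = 0)
  rec <- quick_eeg(truth, n_trials = 1, surround_gain = 0)
  lap <- laplacian_reference(bandpass(rec, 1, 30))
  # AE monocular, assignment A: energy at 7.2/14.4, none at 8/16 or 15.2
  avg <- average_trials(lap, "low_AE_A", c(1, 6))
  sp <- amplitude_spectrum(avg)
  expect_gt(sp$amp[sp$freq == 7.2], 1)
  expect_lt(sp$amp[sp$freq == 8], 0.02)
  expect_lt(sp$amp[sp$freq == 15.2], 0.02)
  # binocular: both eyes' tags and the IM component
  avgb <- average_trials(lap, "low_binocular_A", c(1, 6))
  spb <- amplitude_spectrum(avgb)
  expect_gt(spb$amp[spb$freq == 7.2], 0.5)
  expect_gt(spb$amp[spb$freq == 8], 1)
  expect_equal(spb$amp[spb$freq == 15.2], 0.5, tolerance = 0.02)
  # with im_amp = 0 the IM bin drops to the noise floor
  rec0 <- quick_eeg(ssvep_truth(noise_sd = 0, im_amp = 0), n_trials = 1,
                    surround_gain = 0)
  lap0 <- laplacian_reference(bandpass(rec0, 1, 30))
  sp0 <- amplitude_spectrum(average_trials(lap0, "low_binocular_A", c(1, 6)))
  floor0 <- spectrum_noise_floor(sp0, 15.2, exclude = c(7.2, 8, 14.4, 16))
  expect_lt(sp0$amp[sp0$freq == 15.2], floor0 + 0.02)
})

test_that("planted amplitudes are recovered through the full pipeline", {
  truth <- ssvep_truth(noise_sd = 0, adi = 0.3)
  rec <- quick_eeg(truth, n_trials = 2, surround_gain = 0)
  lap <- laplacian_reference(bandpass(rec, 1, 30))
  sp <- amplitude_spectrum(average_trials(lap, "low_FE_B", c(1, 6)))
  # FE tagged at 7.2 in assignment B; amp1 + amp2 = 3
  expect_equal(tagged_amplitude(sp, 7.2), 3, tolerance = 0.03)
})

test_that("indices follow the stated arithmetic and recover planted BSI", {
  v <- indices_from_amplitudes(2, 4, 1, 3.8)
  expect_equal(v$ADI_mono, 0.5)
  expect_equal(v$ADI_bino, (3.8 - 1) / 3.8)
  expect_equal(v$BSI_AE, 0.5)
  expect_equal(v$BSI_FE, 0.05, tolerance = 1e-12)
  expect_error(indices_from_amplitudes(0, 1, 1, 1), "positive")
  flagged <- indices_from_amplitudes(0.1, 4, 0.1, 3.8, noise_floor = 0.2)
  expect_true(flagged$unreliable[["AE"]])
  # equal binocular and monocular amplitudes: zero suppression
  v0 <- indices_from_amplitudes(2, 4, 2, 4)
  expect_equal(v0$BSI_AE, 0); expect_equal(v0$BSI_FE, 0)
  # noisy recovery at high spectral SNR
  truth <- ssvep_truth(noise_sd = 3, bsi_AE = 0.4, bsi_FE = 0.05)
  rec <- quick_eeg(truth, n_trials = 8, seed = 12)
  res <- analyze_ssvep_recording(rec)
  expect_lt(abs(res$indices$BSI_AE - 0.4), 0.05)
  expect_lt(abs(res$indices$BSI_FE - 0.05), 0.05)
  expect_lt(abs(res$indices$ADI_mono - 0.3), 0.05)
})

test_that("amplitude pipeline is linear; indices are scale-free", {
  truth <- ssvep_truth(noise_sd = 1)
  rec <- quick_eeg(truth, n_trials = 2, seed = 9)
  res1 <- analyze_ssvep_recording(rec)
  rec$data <- rec$data * 3
  res3 <- analyze_ssvep_recording(rec)
  expect_equal(res3$amplitudes$amp_sum, 3 * res1$amplitudes$amp_sum,
               tolerance = 1e-9)
  expect_equal(res3$indices$BSI_AE, res1$indices$BSI_AE, tolerance = 1e-9)
  expect_equal(res3$indices$ADI_mono, res1$indices$ADI_mono, tolerance = 1e-9)
})

test_that("least-squares phase follows the cosine convention", {
  srate <- 1000; t <- (0:3749) / srate
  expect_equal(lsq_phase(cos(2 * pi * 8 * t), 8, srate)$phase, 0,
               tolerance = 1e-9)
  expect_equal(lsq_phase(sin(2 * pi * 8 * t), 8, srate)$phase, -pi / 2,
               tolerance = 1e-9)
  # planted 12.81 ms lag at 7.2 Hz, recovered against an undelayed reference
  lag <- 0.01281
  ph_ref <- lsq_phase(cos(2 * pi * 7.2 * t), 7.2, srate)$phase
  ph_del <- lsq_phase(cos(2 * pi * 7.2 * (t - lag)), 7.2, srate)$phase
  expect_equal(phase_to_delay(ph_ref, ph_del, 7.2), 12.81, tolerance = 0.1)
  expect_warning(lsq_phase(cos(2 * pi * 7.3 * t), 7.3, srate), "cycles")
})

test_that("phase-to-delay arithmetic and wrapping", {
  expect_equal(phase_to_delay(pi / 4, 0, 8), 15.625)
  expect_equal(phase_to_delay(0.3, 0.3, 8), 0)
  # a near-full-period difference wraps to a small negative delay
  eps <- 1e-3
  expect_lt(abs(phase_to_delay(2 * pi - eps, 0, 8)), 1)
  expect_lt(phase_to_delay(-eps, 0, 8), 0)
  expect_error(phase_to_delay(0, 0, -1), "positive")
})

test_that("the phase pipeline recovers the planted delay within 1 ms", {
  truth <- ssvep_truth(noise_sd = 3, delay_AE_ms = 12.81)
  rec <- quick_eeg(truth, n_trials = 6, seed = 77)
  res <- analyze_ssvep_recording(rec)
  expect_lt(abs(res$delay_AE_FE_ms - 12.81), 1)
})

test_that("recordings are seed-deterministic", {
  r1 <- quick_eeg(ssvep_truth(noise_sd = 2), seed = 4)
  r2 <- quick_eeg(ssvep_truth(noise_sd = 2), seed = 4)
  r3 <- quick_eeg(ssvep_truth(noise_sd = 2), seed = 5)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))
})

test_that("simulation guards: sampling, trial length, off-grid tags", {
  truth <- ssvep_truth(noise_sd = 0)
  expect_error(simulate_ssvep_recording(truth, srate = 32), "srate")
  expect_error(simulate_ssvep_recording(truth, trial_s = 2), "trial_s")
  expect_warning(
    simulate_ssvep_recording(ssvep_truth(noise_sd = 0, f_tags = c(7.3, 8)),
                             n_trials = 1,
                             conditions = enumerate_conditions(c(7.3, 8))[1, ]),
    "off the analysis grid")
})
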