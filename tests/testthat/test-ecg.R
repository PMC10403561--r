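test_that("back-up paced beats are all detected at the right times", {
  acq <- gen_tdi_ecg(synth_config("paced_250ms", seed = 1))
  beats <- detect_r_peaks(acq$tdi$simultaneous_ecg)
  expect_length(beats$r_indices, 4)
  truth_idx <- round(acq$truth$ventricular_beat_times * 1000) + 1
  expect_true(all(abs(beats$r_indices - truth_idx) <= 20))
})

test_that("a flat trace yields zero beats, not an error", {
  e0 <- structure(list(samples = rep(0, 6000), fs = 1000, lead = "II"),
                  class = "ecg_record")
  expect_length(detect_r_peaks(e0)$r_indices, 0)
})

test_that("irregularly conducted beats are detected without misses or false alarms", {
  cfg <- synth_config("af", ventricular_mode = "af_conducted_irregular",
                      seed = 7)
  acq <- gen_tdi_ecg(cfg)
  beats <- detect_r_peaks(acq$tdi$simultaneous_ecg)
  truth_idx <- round(acq$truth$ventricular_beat_times * 1000) + 1
  expect_length(beats$r_indices, length(truth_idx))
  expect_true(all(abs(beats$r_indices - truth_idx) <= 20))
})

test_that("inadequate records are rejected by the detector", {
  short <- structure(list(samples = stats::rnorm(800), fs = 1000,
                          lead = "II"), class = "ecg_record")
  expect_error(detect_r_peaks(short), "2 s")
  slow <- structure(list(samples = stats::rnorm(2000), fs = 250,
                         lead = "II"), class = "ecg_record")
  expect_error(detect_r_peaks(slow), "500")
})

test_that("subtraction with zero beats is a no-op", {
  e0 <- structure(list(samples = stats::rnorm(6000) * 0, fs = 1000,
                       lead = "II"), class = "ecg_record")
  out <- subtract_qrst_pca(e0, detect_r_peaks(e0))
  expect_identical(out$samples, e0$samples)
  expect_identical(out$diagnostics$method, "none")
})

test_that("ventricular-only records are suppressed by at least 20 dB", {
  cfg <- synth_config("af", electrical_freq = 6, mechanical_freq = 6,
                      atrial_wave_amplitude = 0, baseline_wander_amp = 0,
                      snr_db = Inf, seed = 4)
  acq <- gen_tdi_ecg(cfg)
  ecg <- acq$tdi$simultaneous_ecg
  out <- subtract_qrst_pca(ecg, detect_r_peaks(ecg))
  win <- which(acq$truth$component_traces$qrst_ecg != 0)
  ratio <- sum(out$samples[win]^2) / sum(ecg$samples[win]^2)
  expect_lte(ratio, 0.01)
})

test_that("samples outside beat windows are returned bit-identical", {
  acq <- gen_tdi_ecg(synth_config("af", seed = 9))
  ecg <- acq$tdi$simultaneous_ecg
  beats <- detect_r_peaks(ecg)
  out <- subtract_qrst_pca(ecg, beats)
  w0 <- -round(beats$window[1] * ecg$fs / 1000) - 35  # alignment slack
  w1 <- round(beats$window[2] * ecg$fs / 1000) + 35
  inside <- rep(FALSE, length(ecg$samples))
  for (r in out$diagnostics$r_indices) {
    idx <- (r + w0):(r + w1)
    inside[idx[idx >= 1 & idx <= length(inside)]] <- TRUE
  }
  expect_identical(out$samples[!inside], ecg$samples[!inside])
})

test_that("the subtracted ECG recovers the atrial dominant frequency", {
  cfg <- synth_config("af", electrical_freq = 6, mechanical_freq = 6,
                      freq_jitter = 0, seed = 11)
  acq <- gen_tdi_ecg(cfg)
  ecg <- acq$tdi$simultaneous_ecg
  out <- subtract_qrst_pca(ecg, detect_r_peaks(ecg))
  df_out <- estimate_df(out$samples, out$fs)$df
  df_clean <- estimate_df(acq$truth$component_traces$atrial_ecg, ecg$fs)$df
  expect_equal(df_out, 6)
  expect_equal(df_out, df_clean)
})

test_that("QRS-T suppression and atrial preservation hold on noisy mixtures", {
  # compact version of the full cancellation sweep: one seed per SNR
  for (snr in c(10, Inf)) {
    cfg <- synth_config("af", electrical_freq = 6.2, mechanical_freq = 4.3,
                        snr_db = snr, seed = 1001)
    acq <- gen_tdi_ecg(cfg)
    ecg <- acq$tdi$simultaneous_ecg
    qrst <- acq$truth$component_traces$qrst_ecg
    out <- subtract_qrst_pca(ecg, detect_r_peaks(ecg))
    n <- length(ecg$samples)
    win <- unlist(lapply(acq$truth$ventricular_beat_times, function(tb) {
      idx <- round(tb * 1000) + 1 + (-60):400
      idx[idx >= 1 & idx <= n]
    }))
    resid_vent <- out$samples - (ecg$samples - qrst)
    sup <- 10 * log10(sum(qrst[win]^2) / sum(resid_vent[win]^2))
    expect_gte(sup, 20)
    ref <- ecg$samples - qrst
    dist <- abs(10 * log10(band_power(out$samples, 1000, c(3, 12)) /
                             band_power(ref, 1000, c(3, 12))))
    expect_lte(dist, 1)
  }
})

test_that("fewer than three beats triggers the flagged template fallback", {
  cfg <- synth_config("af", duration = 2.6, seed = 13)
  acq <- gen_tdi_ecg(cfg)
  ecg <- acq$tdi$simultaneous_ecg
  beats <- detect_r_peaks(ecg)
  expect_length(beats$r_indices, 2)  # beats at 0.5 and 2.0 s
  out <- subtract_qrst_pca(ecg, beats)
  expect_identical(out$diagnostics$method, "template")
})
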