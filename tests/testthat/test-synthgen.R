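test_that("identical configurations reproduce byte-identical acquisitions", {
  a <- gen_tdi_ecg(synth_config("af", seed = 7))
  b <- gen_tdi_ecg(synth_config("af", seed = 7))
  expect_identical(a, b)
  c <- gen_tdi_ecg(synth_config("af", seed = 8))
  expect_false(identical(a$tdi$velocity, c$tdi$velocity))
})

test_that("ground truth reflects the programmed stimulation", {
  t300 <- gen_tdi_ecg(synth_config("paced_300ms", seed = 1))$truth
  expect_equal(t300$true_ear, 1 / 0.300)
  expect_equal(t300$true_mar, 1 / 0.300)
  expect_equal(t300$true_dissociation, 0)
  taf <- gen_tdi_ecg(synth_config("af", electrical_freq = 6.2,
                                  mechanical_freq = 4.3, seed = 1))$truth
  expect_equal(taf$true_dissociation, 1.9)
  tb <- gen_tdi_ecg(synth_config("burst_af", seed = 1))$truth
  expect_equal(tb$true_ear, 10)
})

test_that("back-up ventricular pacing beats fall exactly every 1.5 s", {
  tr <- gen_tdi_ecg(synth_config("paced_250ms", seed = 3))$truth
  bt <- tr$ventricular_beat_times
  expect_equal(bt, c(0.5, 2.0, 3.5, 5.0))
  expect_equal(unique(diff(bt)), 1.5)
})

test_that("irregular conducted beats are increasing and inside the record", {
  for (s in 1:5) {
    cfg <- synth_config("af", ventricular_mode = "af_conducted_irregular",
                        seed = s)
    bt <- gen_tdi_ecg(cfg)$truth$ventricular_beat_times
    expect_true(all(diff(bt) > 0))
    expect_true(all(diff(bt) >= 0.35 & diff(bt) <= 1.1))
    expect_true(all(bt >= 0 & bt <= cfg$duration))
  }
})

test_that("noise-free wall pixels equal the clean mechanical trace exactly", {
  cfg <- synth_config("af", electrical_freq = 6, mechanical_freq = 6,
                      snr_db = Inf, ventricular_tdi_amplitude = 0,
                      echo_noise_sd = 0, seed = 2)
  acq <- gen_tdi_ecg(cfg)
  v <- matrix(acq$tdi$velocity, dim(acq$tdi$velocity)[1])
  for (px in which(acq$truth$wall_mask)) {
    expect_identical(v[, px], acq$truth$component_traces$mechanical)
  }
})

test_that("wall-signal power concentrates at the mechanical rate and harmonics", {
  for (sc in c("paced_200ms", "af")) {
    mech <- gen_tdi_ecg(synth_config(sc, seed = 4))$truth
    sig <- mech$component_traces$mechanical
    fm <- mech$true_mar
    est <- power_spectrum(sig, 250, window = "rectangular",
                          padding_factor = 1L)
    near <- rep(FALSE, length(est$freqs))
    for (h in 1:3) near <- near | abs(est$freqs - h * fm) <= 0.5
    expect_gte(sum(est$psd[near]) / sum(est$psd), 0.9)
  }
})

test_that("velocities stay inside the 15 cm/s Doppler scale", {
  acq <- gen_tdi_ecg(synth_config("burst_af", seed = 5))
  expect_lte(max(abs(acq$tdi$velocity)), 15)
})

test_that("out-of-range frequencies and invalid configs are rejected", {
  expect_error(synth_config("af", mechanical_freq = 130), "Nyquist")
  expect_error(synth_config("af", electrical_freq = -1), "Nyquist")
  expect_error(synth_config("paced_300ms", electrical_freq = 4,
                            mechanical_freq = 5), "equal")
  expect_error(synth_config("af", duration = 0), "duration")
  expect_error(synth_config("af", tdi_frame_rate = 150), "200")
  expect_error(synth_config("af", motion_mod_depth = 1.2), "motion_mod_depth")
})

test_that("optical channels are clean antiphase pairs when motionless", {
  cfg <- synth_config("optical", motion_mod_depth = 0, snr_db = Inf, seed = 1)
  o <- gen_optical(cfg, vm_freq = 7, ca_freq = 7)
  s_vm <- o$truth$component_traces$s_vm
  expect_equal(o$recording$vm_num, 1000 * (1 + 0.25 * s_vm))
  expect_equal(o$recording$vm_den, 1000 * (1 - 0.25 * s_vm))
  expect_equal(o$truth$true_dissociation, 0)
})

test_that("optical ground-truth dissociation is the frequency difference", {
  cfg <- synth_config("optical", snr_db = Inf, seed = 1)
  o <- gen_optical(cfg, vm_freq = 9, ca_freq = 4.5)
  expect_equal(o$truth$true_dissociation, 4.5)
  expect_true(all(vapply(o$recording[c("vm_num", "vm_den", "ca_num",
                                       "ca_den")],
                         function(ch) all(ch > 0), logical(1))))
})

test_that("optical generator rejects unphysical settings", {
  expect_error(synth_config("optical", motion_mod_depth = 1), "motion")
  cfg <- synth_config("optical", snr_db = Inf, seed = 1)
  expect_error(gen_optical(cfg, vm_freq = 300, ca_freq = 5), "Nyquist")
  expect_error(gen_optical(synth_config("af"), vm_freq = 7, ca_freq = 7),
               NA)  # af config is still usable for optical fields
})
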