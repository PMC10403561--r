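#' Configuration for synthetic electromechanical acquisitions
#'
#' Bundles every knob of the synthetic generator and validates the physical
#' constraints. Defaults reproduce the experimental acquisition settings:
#' 6-s simultaneous TDI + lead II segments, TDI frame rate above 200 Hz,
#' tissue-Doppler scale of 15 cm/s, back-up ventricular pacing at 40 bpm,
#' and 500 frames/s optical recordings.
#'
#' @param scenario One of `"paced_300ms"`, `"paced_250ms"`, `"paced_200ms"`
#'   (programmed atrial stimulation; electrical and mechanical rates locked
#'   to the pacing rate), `"burst_af"` (10 Hz burst-pacing segment),
#'   `"af"` (sustained AF; electrical and mechanical rates independently
#'   settable, with mild stochastic frequency jitter), or `"optical"`
#'   (dual-excitation optical recording; see [gen_optical()]).
#' @param duration Segment duration in seconds (default 6).
#' @param ecg_fs ECG sampling rate in Hz (default 1000, must be >= 500).
#' @param tdi_frame_rate TDI frame rate in Hz (default 250, must be > 200).
#' @param electrical_freq Atrial electrical activation rate (Hz). Defaults
#'   per scenario: 1/0.300, 1/0.250, 1/0.200 s for the paced scenarios,
#'   10 Hz for `burst_af`, 6.2 Hz for `af`.
#' @param mechanical_freq Atrial mechanical activation rate (Hz). Must equal
#'   `electrical_freq` for paced/burst scenarios; independently settable for
#'   `af` (default 4.3 Hz).
#' @param ventricular_mode `"backup_paced_40bpm"` (default: the animals were
#'   AV-node ablated with back-up ventricular pacing at 40 bpm, so ventricular
#'   beats fall exactly every 1.5 s starting at 0.5 s) or
#'   `"af_conducted_irregular"` (irregular RR ~ U(0.35, 1.1) s).
#' @param qrst_amplitude R-wave amplitude in mV (default 0.8, about 10x the
#'   atrial wave so QRS-T cancellation is a meaningful problem).
#' @param atrial_wave_amplitude Fibrillatory/paced atrial wave fundamental
#'   amplitude in mV (default 0.08).
#' @param tdi_velocity_amplitude Atrial wall velocity fundamental amplitude
#'   in cm/s (default 3; all velocities stay inside the +/-15 cm/s
#'   aliasing-free Doppler scale).
#' @param ventricular_tdi_amplitude Amplitude (cm/s) of the low-frequency
#'   ventricular motion transient added to wall pixels at each ventricular
#'   beat (default 2; set 0 for a motionless ventricle).
#' @param snr_db Additive white-noise level in dB relative to the clean
#'   atrial component (atrial ECG wave for the ECG trace, mechanical wave for
#'   TDI pixels). `Inf` disables noise. Default 10.
#' @param baseline_wander_amp Baseline wander amplitude in mV (default 0.05).
#' @param seed Integer RNG seed; identical configurations reproduce
#'   byte-identical outputs.
#' @param optical_fs Optical sampling rate in frames/s (default 500).
#' @param motion_mod_depth Multiplicative motion-artifact modulation depth
#'   for optical recordings, in [0, 1) (default 0.3).
#' @param motion_freq Motion-artifact frequency in Hz (default 1.5).
#' @param frame_h,frame_w TDI frame dimensions in pixels (default 24 x 32,
#'   a sector crop around the atrial wall).
#' @param echo_noise_sd Standard deviation of echogenicity noise in
#'   arbitrary units (default 0.1; wall level is 1.0, background 0.05).
#' @param freq_jitter Relative s.d. of the slow stochastic frequency
#'   modulation of the atrial waves; defaults to 0.02 for the `af` scenario
#'   and 0 otherwise (pacing is metronomic).
#' @param alias_wrap If `TRUE`, wrap velocities at the +/-15 cm/s Doppler
#'   scale (aliasing). Default `FALSE`: the scale was chosen to display
#'   aliasing-free velocities.
#' @return A validated `synth_config` object.
#' @seealso [gen_tdi_ecg()], [gen_optical()]
#' @export
synth_config <- function(scenario = c("paced_300ms", "paced_250ms",
                                      "paced_200ms", "burst_af", "af",
                                      "optical"),
                         duration = 6, ecg_fs = 1000, tdi_frame_rate = 250,
                         electrical_freq = NULL, mechanical_freq = NULL,
                         ventricular_mode = c("backup_paced_40bpm",
                                              "af_conducted_irregular"),
                         qrst_amplitude = 0.8, atrial_wave_amplitude = 0.08,
                         tdi_velocity_amplitude = 3,
                         ventricular_tdi_amplitude = 2,
                         snr_db = 10, baseline_wander_amp = 0.05, seed = 1L,
                         optical_fs = 500, motion_mod_depth = 0.3,
                         motion_freq = 1.5, frame_h = 24, frame_w = 32,
                         echo_noise_sd = 0.1, freq_jitter = NULL,
                         alias_wrap = FALSE) {
  scenario <- match.arg(scenario)
  ventricular_mode <- match.arg(ventricular_mode)

  defaults <- switch(scenario,
    paced_300ms = 1 / 0.300, paced_250ms = 1 / 0.250,
    paced_200ms = 1 / 0.200, burst_af = 10,
    af = NA_real_, optical = NA_real_)

  if (scenario %in% c("paced_300ms", "paced_250ms", "paced_200ms",
                      "burst_af")) {
    fa <- if (is.null(electrical_freq)) defaults else electrical_freq
    fm <- if (is.null(mechanical_freq)) defaults else mechanical_freq
    if (!isTRUE(all.equal(fa, fm)))
      stop("electrical and mechanical rates must be equal for paced scenarios",
           call. = FALSE)
  } else {
    fa <- if (is.null(electrical_freq)) 6.2 else electrical_freq
    fm <- if (is.null(mechanical_freq)) 4.3 else mechanical_freq
  }
  if (is.null(freq_jitter)) freq_jitter <- if (scenario == "af") 0.02 else 0

  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (tdi_frame_rate <= 200)
    stop("tdi_frame_rate must be > 200 Hz", call. = FALSE)
  if (ecg_fs < 500) stop("ecg_fs must be >= 500 Hz", call. = FALSE)
  if (motion_mod_depth < 0 || motion_mod_depth >= 1)
    stop("motion_mod_depth must lie in [0, 1)", call. = FALSE)
  if (scenario != "optical") {
    if (fa < 0 || fa >= tdi_frame_rate / 2 || fa >= ecg_fs / 2)
      stop("electrical_freq outside [0, Nyquist): frequency-range error",
           call. = FALSE)
    if (fm < 0 || fm >= tdi_frame_rate / 2)
      stop("mechanical_freq outside [0, Nyquist): frequency-range error",
           call. = FALSE)
  }
  if (frame_h < 8 || frame_w < 8)
    stop("frame dimensions too small for a sector geometry", call. = FALSE)

  structure(list(scenario = scenario, duration = duration, ecg_fs = ecg_fs,
                 tdi_frame_rate = tdi_frame_rate, electrical_freq = fa,
                 mechanical_freq = fm, ventricular_mode = ventricular_mode,
                 qrst_amplitude = qrst_amplitude,
                 atrial_wave_amplitude = atrial_wave_amplitude,
                 tdi_velocity_amplitude = tdi_velocity_amplitude,
                 ventricular_tdi_amplitude = ventricular_tdi_amplitude,
                 snr_db = snr_db, baseline_wander_amp = baseline_wander_amp,
                 seed = as.integer(seed), optical_fs = optical_fs,
                 motion_mod_depth = motion_mod_depth,
                 motion_freq = motion_freq,
                 frame_h = as.integer(frame_h), frame_w = as.integer(frame_w),
                 echo_noise_sd = echo_noise_sd, freq_jitter = freq_jitter,
                 alias_wrap = isTRUE(alias_wrap)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$scenario, "\n")
  cat(sprintf("  %g s | ECG %g Hz | TDI %g Hz | fa = %g Hz, fm = %g Hz\n",
              x$duration, x$ecg_fs, x$tdi_frame_rate,
              x$electrical_freq, x$mechanical_freq))
  cat(sprintf("  ventricular: %s | SNR %g dB | seed %d\n",
              x$ventricular_mode, x$snr_db, x$seed))
  invisible(x)
}

# Slowly frequency-modulated phase track; the jitter track is demeaned so the
# realized mean rate equals f0 (the ground-truth rate).
phase_track <- function(f0, n, fs, jitter_sd) {
  if (jitter_sd > 0) {
    z <- stats::rnorm(n)
    bf <- signal::butter(2, min(0.5 / (fs / 2), 0.99), type = "low")
    z <- as.numeric(signal::filtfilt(bf, z))
    z <- z - mean(z)
    s <- stats::sd(z)
    if (s > 0) z <- z / s
    finst <- f0 * (1 + jitter_sd * z)
  } else {
    finst <- rep(f0, n)
  }
  2 * pi * cumsum(finst) / fs
}

# Harmonic quasi-sawtooth atrial wave: fundamental + 2 decaying harmonics.
harmonic_wave <- function(phase, amp, harm = c(1, 0.5, 0.25),
                          hphase = c(0, 0.5, 1.0)) {
  out <- numeric(length(phase))
  for (k in seq_along(harm))
    out <- out + harm[k] * sin(k * phase + hphase[k])
  amp * out
}

# Gaussian-sum QRS-T template on a time axis relative to the R apex (s).
qrst_shape <- function(trel) {
  lobe <- function(t0, a, s) a * exp(-(trel - t0)^2 / (2 * s^2))
  lobe(-0.028, -0.12, 0.010) + lobe(0, 1, 0.012) +
    lobe(0.030, -0.18, 0.010) + lobe(0.200, 0.30, 0.045)
}

ventricular_beat_times <- function(config) {
  if (config$ventricular_mode == "backup_paced_40bpm") {
    bt <- seq(0.5, config$duration, by = 1.5)
  } else {
    bt <- numeric(0)
    t <- 0
    repeat {
      t <- t + stats::runif(1, 0.35, 1.1)
      if (t > config$duration) break
      bt <- c(bt, t)
    }
  }
  bt
}

# Fan-shaped imaging sector with a curved wall band; returns h x w masks.
sector_masks <- function(h, w) {
  apex_row <- -4
  apex_col <- (w + 1) / 2
  half_angle <- 35 * pi / 180
  r_max <- (h - apex_row) * 1.05
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- rows - apex_row
  dc <- cols - apex_col
  r <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  sector <- abs(theta) <= half_angle & r <= r_max
  wall_fr <- c(0.58, 0.80)
  wall <- sector & r / r_max >= wall_fr[1] & r / r_max <= wall_fr[2]
  list(sector = sector, wall = wall,
       geometry = list(apex = c(row = apex_row, col = apex_col),
                       half_angle_deg = 35, r_max = r_max,
                       wall_radius_fraction = wall_fr))
}

rms <- function(x) sqrt(mean(x^2))

noise_sd_for <- function(clean, snr_db) {
  if (!is.finite(snr_db)) return(0)
  rms(clean) * 10^(-snr_db / 20)
}

#' Generate a synthetic simultaneous TDI + ECG acquisition
#'
#' Produces a tissue-Doppler velocity frame stack with a co-registered
#' echogenicity stack and a simultaneous lead II ECG, plus the ground truth
#' needed for parameter-recovery testing. Wall pixels carry a quasi-periodic
#' velocity wave at the mechanical rate (fundamental plus two decaying
#' harmonics), a low-frequency ventricular motion transient time-locked to
#' each ventricular beat, and white noise; non-wall pixels carry
#' low-echogenicity noise. The ECG is the sum of a harmonic sawtooth-like
#' atrial wave at the electrical rate, Gaussian-sum QRS-T complexes at the
#' ventricular beat times, baseline wander and white noise.
#'
#' @param config A [synth_config()] with a non-optical scenario.
#' @return A list with components `tdi` (a `tdi_sequence`: `velocity` and
#'   `echogenicity` arrays of dimension T x H x W, `frame_rate`,
#'   `sector_geometry`, `simultaneous_ecg`) and `truth` (a `ground_truth`:
#'   `true_ear`, `true_mar`, `true_dissociation`, `ventricular_beat_times`,
#'   `wall_mask` (H x W), `component_traces` with the clean constituent
#'   signals).
#' @examples
#' acq <- gen_tdi_ecg(synth_config("paced_300ms", seed = 1))
#' acq$truth$true_mar # 3.3333 Hz = 1 / 0.300 s
#' @export
gen_tdi_ecg <- function(config) {
  if (!inherits(config, "synth_config"))
    stop("config must be a synth_config", call. = FALSE)
  if (config$scenario == "optical")
    stop("use gen_optical() for the optical scenario", call. = FALSE)
  set.seed(config$seed)

  fa <- config$electrical_freq
  fm <- config$mechanical_freq
  dur <- config$duration
  fr <- config$tdi_frame_rate
  fs <- config$ecg_fs
  nf <- round(dur * fr)
  ne <- round(dur * fs)
  t_tdi <- (seq_len(nf) - 1) / fr
  t_ecg <- (seq_len(ne) - 1) / fs
  h <- config$frame_h
  w <- config$frame_w

  beat_times <- ventricular_beat_times(config)

  ## --- mechanical (TDI) side -------------------------------------------
  mech_phase <- phase_track(fm, nf, fr, config$freq_jitter)
  mech <- harmonic_wave(mech_phase, config$tdi_velocity_amplitude,
                        harm = c(1, 0.4, 0.2))
  vent_tdi <- numeric(nf)
  if (config$ventricular_tdi_amplitude > 0) {
    for (tb in beat_times)
      vent_tdi <- vent_tdi -
        config$ventricular_tdi_amplitude * exp(-(t_tdi - tb)^2 / (2 * 0.12^2))
  }

  geom <- sector_masks(h, w)
  wall_idx <- which(geom$wall)
  noise_sd <- noise_sd_for(mech, config$snr_db)
  bg_sd <- if (is.finite(config$snr_db)) 0.5 else 0

  vmat <- matrix(stats::rnorm(nf * h * w), nf, h * w)
  clean_wall <- mech + vent_tdi
  vmat[, wall_idx] <- vmat[, wall_idx] * noise_sd + clean_wall
  vmat[, -wall_idx] <- vmat[, -wall_idx] * bg_sd
  if (config$alias_wrap) vmat <- ((vmat + 15) %% 30) - 15
  velocity <- array(vmat, c(nf, h, w))

  base_echo <- ifelse(geom$wall, 1, ifelse(geom$sector, 0.05, 0))
  emat <- if (config$echo_noise_sd > 0) {
    matrix(stats::rnorm(nf * h * w, 0, config$echo_noise_sd), nf, h * w)
  } else {
    matrix(0, nf, h * w)
  }
  emat <- sweep(emat, 2, as.numeric(base_echo), "+")
  emat[emat < 0] <- 0
  echogenicity <- array(emat, c(nf, h, w))

  ## --- electrical (ECG) side -------------------------------------------
  atr_phase <- phase_track(fa, ne, fs, config$freq_jitter)
  atrial <- harmonic_wave(atr_phase, config$atrial_wave_amplitude)
  qrst <- numeric(ne)
  if (length(beat_times) && config$qrst_amplitude > 0) {
    toff <- round(-0.06 * fs):round(0.34 * fs)
    shape <- qrst_shape(toff / fs) * config$qrst_amplitude
    for (tb in beat_times) {
      idx <- round(tb * fs) + 1L + toff
      ok <- idx >= 1L & idx <= ne
      qrst[idx[ok]] <- qrst[idx[ok]] + shape[ok]
    }
  }
  wander <- config$baseline_wander_amp * sin(2 * pi * 0.3 * t_ecg + 0.7)
  ecg_noise <- stats::rnorm(ne) * noise_sd_for(atrial, config$snr_db)
  ecg <- structure(list(samples = atrial + qrst + wander + ecg_noise,
                        fs = fs, lead = "II"),
                   class = "ecg_record")

  tdi <- structure(list(velocity = velocity, echogenicity = echogenicity,
                        frame_rate = fr, sector_geometry = geom$geometry,
                        simultaneous_ecg = ecg),
                   class = "tdi_sequence")
  truth <- structure(list(true_ear = fa, true_mar = fm,
                          true_dissociation = fa - fm,
                          ventricular_beat_times = beat_times,
                          wall_mask = geom$wall,
                          component_traces = list(
                            mechanical = mech,
                            ventricular_tdi = vent_tdi,
                            atrial_ecg = atrial,
                            qrst_ecg = qrst,
                            baseline_wander = wander),
                          scenario = config$scenario, seed = config$seed),
                     class = "ground_truth")
  list(tdi = tdi, truth = truth)
}

#' Generate a synthetic dual-excitation ratiometric optical recording
#'
#' Emulates simultaneous voltage and calcium excitation ratiometry in a
#' contracting heart: each dye contributes a numerator/denominator channel
#' pair modulated in antiphase by the clean signal, and all four channels
#' are multiplied by the same motion artifact
#' `m(t) = 1 + depth * sin(2 * pi * f_motion * t)`. Taking the channel
#' ratio therefore cancels the artifact exactly (see [ratiometric_demix()]).
#'
#' @param config A [synth_config()]; `optical_fs`, `motion_mod_depth`,
#'   `motion_freq`, `duration`, `snr_db` and `seed` are used.
#' @param vm_freq,ca_freq Voltage and calcium activation rates in Hz; must
#'   be below `optical_fs / 2`.
#' @return List with `recording` (a `ratiometric_recording`: positive
#'   channels `vm_num`, `vm_den`, `ca_num`, `ca_den`, `fs`, `motion_trace`)
#'   and `truth` (`true_vm_freq`, `true_ca_freq`, `true_dissociation`,
#'   clean `component_traces`).
#' @export
gen_optical <- function(config, vm_freq = 7, ca_freq = 7) {
  if (!inherits(config, "synth_config"))
    stop("config must be a synth_config", call. = FALSE)
  if (config$motion_mod_depth >= 1)
    stop("motion_mod_depth >= 1 would allow non-positive intensities",
         call. = FALSE)
  fs <- config$optical_fs
  if (vm_freq >= fs / 2 || ca_freq >= fs / 2)
    stop("vm_freq/ca_freq above Nyquist: frequency-range error",
         call. = FALSE)
  set.seed(config$seed)

  n <- round(config$duration * fs)
  tt <- (seq_len(n) - 1) / fs

  norm1 <- function(x) x / max(abs(x))
  s_vm <- norm1(harmonic_wave(2 * pi * vm_freq * tt, 1,
                              harm = c(1, 0.45, 0.2)))
  s_ca <- norm1(harmonic_wave(2 * pi * ca_freq * tt, 1,
                              harm = c(1, 0.35, 0.12),
                              hphase = c(0.6, 1.0, 1.4)))
  m <- 1 + config$motion_mod_depth * sin(2 * pi * config$motion_freq * tt)

  F0 <- 1000
  a_vm <- 0.25
  a_ca <- 0.20
  ch <- list(vm_num = F0 * (1 + a_vm * s_vm),
             vm_den = F0 * (1 - a_vm * s_vm),
             ca_num = F0 * (1 + a_ca * s_ca),
             ca_den = F0 * (1 - a_ca * s_ca))
  snr <- config$snr_db
  # optical default is a clean (shot-noise-free) recording; additive noise
  # can be enabled through snr_db but is kept small against F0
  ch <- lapply(ch, function(x) {
    y <- x * m
    if (is.finite(snr)) y <- y + stats::rnorm(n) * noise_sd_for(x - F0, snr)
    y
  })

  rec <- structure(c(ch, list(fs = fs, motion_trace = m)),
                   class = "ratiometric_recording")
  truth <- structure(list(true_vm_freq = vm_freq, true_ca_freq = ca_freq,
                          true_dissociation = vm_freq - ca_freq,
                          component_traces = list(s_vm = s_vm, s_ca = s_ca,
                                                  motion = m),
                          scenario = "optical", seed = config$seed),
                     class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' @export
print.tdi_sequence <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf("<tdi_sequence> %d frames of %d x %d px @ %g Hz (%.2f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[1] / x$frame_rate))
  cat(sprintf("  simultaneous ECG: lead %s, %d samples @ %g Hz\n",
              x$simultaneous_ecg$lead, length(x$simultaneous_ecg$samples),
              x$simultaneous_ecg$fs))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", x$scenario, "\n")
  if (!is.null(x$true_ear))
    cat(sprintf("  EAR %.4g Hz, MAR %.4g Hz, dissociation %.4g Hz\n",
                x$true_ear, x$true_mar, x$true_dissociation))
  if (!is.null(x$true_vm_freq))
    cat(sprintf("  Vm %.4g Hz, Ca %.4g Hz, dissociation %.4g Hz\n",
                x$true_vm_freq, x$true_ca_freq, x$true_dissociation))
  invisible(x)
}
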