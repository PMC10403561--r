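# shared fixtures: all built in code at test time

tone <- function(freq, fs = 250, duration = 6, amp = 1, phase = 0) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  amp * sin(2 * pi * freq * t + phase)
}

# minimal hand-built TDI sequence: `wall` is an H x W logical matrix, every
# wall pixel carries `signal` (plus optional iid noise), background is zero
make_tdi <- function(signal, wall, frame_rate = 250, noise_sd = 0,
                     echo_wall = 1, echo_bg = 0, ecg = NULL) {
  nf <- length(signal)
  h <- nrow(wall)
  w <- ncol(wall)
  v <- matrix(0, nf, h * w)
  idx <- which(wall)
  if (noise_sd > 0) {
    v[, idx] <- matrix(stats::rnorm(nf * length(idx), 0, noise_sd),
                       nf, length(idx))
  }
  v[, idx] <- v[, idx] + signal
  e <- matrix(echo_bg, nf, h * w)
  e[, idx] <- echo_wall
  if (is.null(ecg)) {
    ecg <- structure(list(samples = stats::rnorm(round(nf / frame_rate * 1000)),
                          fs = 1000, lead = "II"), class = "ecg_record")
  }
  structure(list(velocity = array(v, c(nf, h, w)),
                 echogenicity = array(e, c(nf, h, w)),
                 frame_rate = frame_rate,
                 sector_geometry = NULL,
                 simultaneous_ecg = ecg),
            class = "tdi_sequence")
}

band_power <- function(x, fs, band) {
  est <- power_spectrum(x, fs, window = "rectangular", padding_factor = 1L)
  sel <- est$freqs >= band[1] & est$freqs <= band[2]
  sum(est$psd[sel]) * (est$freqs[2] - est$freqs[1])
}
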