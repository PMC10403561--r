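test_that("noise-free segmentation recovers the wall exactly", {
  acq <- gen_tdi_ecg(synth_config("paced_300ms", echo_noise_sd = 0,
                                  seed = 1))
  m <- segment_wall(acq$tdi, echo_threshold = 0.5)
  nf <- dim(m$mask)[1]
  for (i in c(1, nf %/% 2, nf)) {
    expect_equal(dice_coefficient(m$mask[i, , ], acq$truth$wall_mask), 1)
  }
})

test_that("segmentation is robust to echogenicity noise", {
  for (s in 1:10) {
    acq <- gen_tdi_ecg(synth_config("paced_250ms", seed = s))  # sd 0.1
    m <- segment_wall(acq$tdi, echo_threshold = 0.5)
    d <- vapply(seq_len(dim(m$mask)[1]), function(i) {
      dice_coefficient(m$mask[i, , ], acq$truth$wall_mask)
    }, numeric(1))
    expect_gte(min(d), 0.95)
  }
})

test_that("a threshold above the global maximum is unprocessable", {
  acq <- gen_tdi_ecg(synth_config("paced_300ms", seed = 1))
  expect_error(segment_wall(acq$tdi,
                            echo_threshold = max(acq$tdi$echogenicity) + 1),
               "unprocessable")
})

test_that("a region-of-interest polygon restricts the mask", {
  acq <- gen_tdi_ecg(synth_config("paced_300ms", echo_noise_sd = 0,
                                  seed = 1))
  h <- dim(acq$tdi$velocity)[2]
  w <- dim(acq$tdi$velocity)[3]
  left_half <- cbind(row = c(0, h + 1, h + 1, 0),
                     col = c(0, 0, w / 2, w / 2))
  m <- segment_wall(acq$tdi, roi = left_half, echo_threshold = 0.5)
  expect_true(all(!m$mask[1, , (floor(w / 2) + 1):w]))
  expect_gt(sum(m$mask[1, , ]), 0)
})

test_that("averaging identical wall pixels returns the signal exactly", {
  sig <- tone(4, amp = 2)
  wall <- matrix(FALSE, 10, 12)
  wall[4:6, 3:9] <- TRUE
  seq <- make_tdi(sig, wall)
  mask <- segment_wall(seq, echo_threshold = 0.5)
  expect_equal(average_wall_velocity(seq, mask), sig,
               ignore_attr = TRUE)
})

test_that("averaging N noisy pixels shrinks noise variance like 1/N", {
  wall <- matrix(FALSE, 12, 14)
  wall[4:9, 3:12] <- TRUE          # N = 60 pixels
  N <- sum(wall)
  sigma <- 1
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    sig <- tone(4, amp = 2)
    seq <- make_tdi(sig, wall, noise_sd = sigma)
    mask <- segment_wall(seq, echo_threshold = 0.5)
    out <- average_wall_velocity(seq, mask)
    stats::var(out - sig) / (sigma^2 / N)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("an everywhere-empty mask is an error", {
  sig <- tone(4)
  wall <- matrix(FALSE, 8, 8)
  wall[3:5, 3:5] <- TRUE
  seq <- make_tdi(sig, wall)
  mask <- segment_wall(seq, echo_threshold = 0.5)
  mask$mask[] <- FALSE
  expect_error(average_wall_velocity(seq, mask), "empty")
})

test_that("constant signals produce no modes and a perfect residual", {
  out <- emd_sift(rep(3.2, 100))
  expect_length(out$imfs, 0)
  expect_equal(out$residual, rep(3.2, 100))
})

test_that("a pure tone survives sifting as a single significant mode", {
  x <- tone(5)
  out <- emd_sift(x, fs = 250)
  p_in <- sum(x^2)
  sig_modes <- which(vapply(out$imfs, function(im) sum(im^2), numeric(1)) >
                       0.01 * p_in)
  expect_length(sig_modes, 1)
  expect_gte(stats::cor(out$imfs[[sig_modes]], x), 0.99)
  expect_lte(sum(out$residual^2), 0.01 * p_in)
})

test_that("sifting separates a two-tone mixture into its components", {
  hi <- tone(8)
  lo <- tone(2)
  out <- emd_sift(hi + lo, fs = 250)
  expect_gte(length(out$imfs), 2)
  df1 <- estimate_df(out$imfs[[1]], 250, band = c(0.5, 30))$df
  df2 <- estimate_df(out$imfs[[2]], 250, band = c(0.5, 30))$df
  expect_equal(df1, 8, tolerance = 0.05)
  expect_equal(df2, 2, tolerance = 0.1)
  expect_gte(stats::cor(out$imfs[[1]], hi), 0.95)
  expect_gte(stats::cor(out$imfs[[2]], lo), 0.95)
})

test_that("sifting reconstructs every input to rounding error", {
  set.seed(99)
  cases <- list(
    stats::rnorm(1000),
    tone(5) + 0.3 * tone(11, phase = 1),
    cumsum(stats::rnorm(800)) / 10,
    tone(3, amp = 2) * (1 + 0.5 * tone(0.5))
  )
  for (x in cases) {
    out <- emd_sift(x)
    expect_lte(max(abs(x - imf_reconstruct(out))), 1e-8 * max(abs(x)))
  }
})

test_that("mode dominant frequencies are ordered high to low", {
  ok <- logical(0)
  for (s in 21:25) {
    acq <- gen_tdi_ecg(synth_config("af", seed = s))
    mask <- segment_wall(acq$tdi, echo_threshold = 0.5)
    vel <- average_wall_velocity(acq$tdi, mask)
    out <- emd_sift(vel, fs = 250)
    dfs <- vapply(out$imfs, function(im) {
      dominant_frequency(power_spectrum(im, 250), c(0.01, 125))
    }, numeric(1))
    dfs <- dfs[!is.na(dfs)]
    ok <- c(ok, diff(dfs) <= 0.5)  # slack for near-tied adjacent modes
  }
  expect_gte(mean(ok), 0.95)
})

test_that("sifting rejects unusable inputs", {
  expect_error(emd_sift(c(tone(5)[1:100], NA)), "non-finite")
  expect_error(emd_sift(1:4), "16")
})

test_that("band selection keeps the in-band mode and reports indices", {
  out <- emd_sift(tone(8) + tone(2), fs = 250)
  sel <- select_imfs(out, band = c(3, 15))
  expect_true(1 %in% sel$selected)
  expect_equal(estimate_df(sel$signal, 250, band = c(3, 15))$df, 8,
               tolerance = 0.05)
})

test_that("a full-band selection reproduces input minus residual", {
  x <- tone(8) + tone(2)
  out <- emd_sift(x, fs = 250)
  sel <- select_imfs(out, band = c(0, 125))
  expect_equal(sel$signal, x - out$residual, tolerance = 1e-10)
})

test_that("an empty band selection is an unassessable error", {
  out <- emd_sift(tone(8) + tone(2), fs = 250)
  expect_error(select_imfs(out, band = c(20, 30)), "unassessable")
})

test_that("the mechanical rate survives the whole TDI chain", {
  # end-to-end recovery at on-bin rates with ventricular contamination
  for (fm in c(3, 5.5, 8, 10)) {
    for (s in 1:3) {
      cfg <- synth_config("af", electrical_freq = 6, mechanical_freq = fm,
                          snr_db = 10, seed = 3000 + 10 * fm + s)
      acq <- gen_tdi_ecg(cfg)
      mask <- segment_wall(acq$tdi, echo_threshold = 0.5)
      vel <- average_wall_velocity(acq$tdi, mask)
      sel <- select_imfs(emd_sift(vel, fs = 250), band = c(2.5, 15))
      df <- estimate_df(sel$signal, 250, band = c(2.5, 15))$df
      expect_lte(abs(df - fm), 1 / 6)
    }
  }
})

test_that("mean amplitude excursion matches the per-cycle definition", {
  expect_equal(mean_amplitude_excursion(tone(5, amp = 3)), 6,
               tolerance = 0.01)
  # alternating cycle amplitudes 2 and 4 -> excursions 4 and 8, mean 6
  cyc <- function(a) a * sin(2 * pi * seq(0, 1, length.out = 51)[-51])
  x <- unlist(rep(list(cyc(2), cyc(4)), 10))
  expect_equal(mean_amplitude_excursion(x), 6, tolerance = 0.05)
})

test_that("mean amplitude excursion is undefined without two crossings", {
  expect_true(is.na(mean_amplitude_excursion(rep(0, 100))))
  expect_true(is.na(mean_amplitude_excursion(seq(1, 2, length.out = 50))))
  expect_error(mean_amplitude_excursion(numeric(0)), "non-empty")
})
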