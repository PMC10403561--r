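#' Detect ventricular beats (R peaks) in an ECG record
#'
#' Pan-Tompkins-style detector: zero-phase band-pass (5-25 Hz), squared
#' derivative, 150-ms moving-window integration, fixed-fraction threshold
#' on the integrated energy, refractory enforcement, and apex refinement on
#' the band-passed trace. A flat or empty trace yields an empty beat set
#' (zero beats is a valid observation, not an error); an inadequate sampling
#' rate or record length is an error.
#'
#' @param ecg An `ecg_record` (list with `samples` in mV and `fs` in Hz).
#' @param min_rr_ms Refractory period in ms; candidate beats closer than
#'   this keep only the stronger one. Default 250.
#' @param pre_ms,post_ms Beat-window bounds relative to the R apex used to
#'   populate `beat_matrix` (defaults -60 / +400 ms cover the QRS-T).
#' @return A `beat_set`: `r_indices` (strictly increasing sample indices),
#'   `window = c(pre_ms, post_ms)`, `beat_matrix` (beats x window samples,
#'   `NA` where a window leaves the record), `edge` (logical flag per beat),
#'   `fs`.
#' @export
detect_r_peaks <- function(ecg, min_rr_ms = 250, pre_ms = 60, post_ms = 400) {
  if (!inherits(ecg, "ecg_record"))
    stop("ecg must be an ecg_record", call. = FALSE)
  x <- ecg$samples
  fs <- ecg$fs
  if (fs < 500) stop("sampling rate must be >= 500 Hz", call. = FALSE)
  if (length(x) < 2 * fs)
    stop("record must be at least 2 s long", call. = FALSE)
  if (!all(is.finite(x)))
    stop("ECG contains non-finite samples", call. = FALSE)

  empty <- function() {
    structure(list(r_indices = integer(0), window = c(pre_ms, post_ms),
                   beat_matrix = matrix(numeric(0), nrow = 0,
                                        ncol = win_len(fs, pre_ms, post_ms)),
                   edge = logical(0), fs = fs),
              class = "beat_set")
  }
  if (stats::sd(x) == 0) return(empty())

  bf <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  f <- as.numeric(signal::filtfilt(bf, x))
  sq <- c(0, diff(f))^2
  win <- max(1L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0

  thr <- 0.3 * max(integ)
  if (thr <= 0) return(empty())
  above <- integ > thr
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L

  half <- round(0.1 * fs)
  n <- length(x)
  apex <- integer(0)
  strength <- numeric(0)
  for (k in seq_along(starts)) {
    seg <- starts[k]:ends[k]
    c0 <- seg[which.max(integ[seg])]
    lo <- max(1L, c0 - half)
    hi <- min(n, c0 + half)
    a <- lo + which.max(abs(f[lo:hi])) - 1L
    apex <- c(apex, a)
    strength <- c(strength, integ[c0])
  }
  o <- order(apex)
  apex <- apex[o]
  strength <- strength[o]

  # refractory: strongest-first greedy, drop candidates within min_rr of a
  # kept beat
  min_rr <- round(min_rr_ms * fs / 1000)
  keep <- logical(length(apex))
  for (i in order(strength, decreasing = TRUE)) {
    if (!any(keep & abs(apex - apex[i]) < min_rr)) keep[i] <- TRUE
  }
  apex <- apex[keep]

  bm <- beat_windows(x, apex, fs, pre_ms, post_ms)
  structure(list(r_indices = apex, window = c(pre_ms, post_ms),
                 beat_matrix = bm$mat, edge = bm$edge, fs = fs),
            class = "beat_set")
}

win_len <- function(fs, pre_ms, post_ms) {
  round(post_ms * fs / 1000) + round(pre_ms * fs / 1000) + 1L
}

beat_windows <- function(x, r, fs, pre_ms, post_ms) {
  w0 <- -round(pre_ms * fs / 1000)
  w1 <- round(post_ms * fs / 1000)
  L <- w1 - w0 + 1L
  n <- length(x)
  mat <- matrix(NA_real_, length(r), L)
  for (b in seq_along(r)) {
    idx <- r[b] + w0:w1
    ok <- idx >= 1L & idx <= n
    mat[b, ok] <- x[idx[ok]]
  }
  list(mat = mat, edge = apply(is.na(mat), 1, any), w0 = w0, w1 = w1, L = L)
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats @ %g Hz, window [-%g, +%g] ms",
              length(x$r_indices), x$fs, x$window[1], x$window[2]))
  if (any(x$edge)) cat(sprintf(" (%d at record edge)", sum(x$edge)))
  cat("\n")
  invisible(x)
}

#' Subtract QRS-T complexes by principal component analysis
#'
#' Removes the ventricular component of an ECG to expose the atrial
#' fibrillatory wave. Beat windows are aligned by cross-correlation against
#' the mean beat (within +/-30 ms), stacked, and decomposed by SVD of the
#' uncentered beat matrix. Each beat's projection onto the smallest number
#' of leading components whose cumulative squared singular values reach
#' `variance_target` (capped at `max_components`) is subtracted, with a
#' raised-cosine taper at the window borders so no step discontinuity is
#' introduced. Samples outside every beat window are returned bit-identical.
#'
#' With fewer than 3 beats no meaningful basis exists and the mean-template
#' subtraction fallback is used (flagged in the diagnostics). Overlapping
#' windows are truncated at the midpoint between beats (flagged). With zero
#' beats the record is returned unchanged.
#'
#' @param ecg An `ecg_record`.
#' @param beats A `beat_set` from [detect_r_peaks()].
#' @param variance_target Fraction of in-window energy the retained
#'   components must explain (default 0.95).
#' @param max_components Rank cap (default 5).
#' @param taper_ms Raised-cosine blend length at each window border
#'   (default 10 ms).
#' @return An `atrial_ecg`: `samples` (mV, ventricular-subtracted), `fs`,
#'   `lead`, and `diagnostics` (method, `components_used`, per-beat
#'   `residual_power_ratio`, truncation/edge flags).
#' @export
subtract_qrst_pca <- function(ecg, beats, variance_target = 0.95,
                              max_components = 5L, taper_ms = 10) {
  if (!inherits(ecg, "ecg_record"))
    stop("ecg must be an ecg_record", call. = FALSE)
  if (!inherits(beats, "beat_set"))
    stop("beats must be a beat_set", call. = FALSE)
  x <- ecg$samples
  n <- length(x)
  fs <- ecg$fs
  r <- beats$r_indices

  if (length(r) == 0L) {
    return(structure(list(samples = x, fs = fs, lead = ecg$lead,
                          diagnostics = list(method = "none", n_beats = 0L,
                                             components_used = 0L,
                                             residual_power_ratio = numeric(0),
                                             truncated = logical(0),
                                             edge = logical(0))),
                     class = "atrial_ecg"))
  }

  w0 <- -round(beats$window[1] * fs / 1000)
  w1 <- round(beats$window[2] * fs / 1000)
  L <- w1 - w0 + 1L

  fetch <- function(ri) {
    idx <- ri + w0:w1
    ok <- idx >= 1L & idx <= n
    v <- rep(NA_real_, L)
    v[ok] <- x[idx[ok]]
    v
  }

  nb <- length(r)
  template_mode <- nb < 3L
  ramp <- max(1L, round(taper_ms * fs / 1000))
  maxlag <- round(0.03 * fs)

  taper_weights <- function(m) {
    wgt <- rep(1, m)
    rl <- min(ramp, floor(m / 2))
    if (rl > 0L) {
      ease <- 0.5 * (1 - cos(pi * seq_len(rl) / (rl + 1)))
      wgt[seq_len(rl)] <- ease
      wgt[m - rl + seq_len(rl)] <- rev(ease)
    }
    wgt
  }

  ## iterative cross-correlation alignment (+/- 30 ms) against the mean
  ## beat, restricted to the QRS subwindow (-60..+80 ms): there the R wave
  ## dominates the atrial wave by more than an order of magnitude, so the
  ## correlation peak is not biased by atrial interference
  lags <- -maxlag:maxlag
  qrs_sub <- seq_len(min(L, round(0.14 * fs)))  # first 140 ms of the window
  for (round in 1:3) {
    M0 <- vapply(r, fetch, numeric(L))
    complete0 <- colSums(is.na(M0)) == 0L
    if (sum(complete0) < 2L) break
    ref <- rowMeans(M0[, complete0, drop = FALSE])[qrs_sub]
    shifted <- FALSE
    for (b in seq_along(r)) {
      sc <- vapply(lags, function(l) {
        v <- fetch(r[b] + l)[qrs_sub]
        ok <- !is.na(v)
        if (sum(ok) < length(qrs_sub) / 2) return(-Inf)
        sum(v[ok] * ref[ok]) / sum(ok)
      }, numeric(1))
      l_best <- lags[which.max(sc)]
      if (l_best != 0L) shifted <- TRUE
      r[b] <- r[b] + l_best
    }
    r <- sort(r)
    if (!shifted) break
  }

  ## window limits: truncate overlaps at the midpoint between beats
  if (nb > 1L) {
    mid <- floor((r[-nb] + r[-1L]) / 2)
    lo_lim <- c(1L, mid + 1L)
    hi_lim <- c(mid, n)
  } else {
    lo_lim <- 1L
    hi_lim <- n
  }
  start <- pmax(r + w0, lo_lim)
  end <- pmin(r + w1, hi_lim)
  truncated <- (start > r + w0) | (end < r + w1)
  edge <- (r + w0 < 1L) | (r + w1 > n)
  full <- !truncated & !edge

  k <- 0L
  basis <- NULL
  dbasis <- NULL
  coherence <- numeric(0)
  use_template <- template_mode || sum(full) < 2L

  # Build the ventricular basis by SVD of the (optionally atrial-cleaned)
  # beat matrix. A cross-beat coherence gate keeps, beyond the leading
  # component, only components whose loadings have a consistent sign and
  # magnitude on every beat: a component that mostly captures the atrial
  # wave caught inside the windows loads with fluctuating sign (the
  # atrial phase at each beat is arbitrary), and subtracting it would
  # strip atrial power.
  build_basis <- function(M) {
    sv <- svd(M)
    energy <- sv$d^2
    k_var <- which(cumsum(energy) / sum(energy) >= variance_target)[1L]
    if (is.na(k_var)) k_var <- length(sv$d)
    k_var <- min(k_var, max_components, length(sv$d))
    loadings <- sv$u %*% diag(sv$d, length(sv$d))
    coh <- abs(colMeans(loadings)) /
      (apply(loadings, 2, stats::sd) / sqrt(nrow(loadings)) + 1e-300)
    accept <- c(1L, setdiff(which(coh > 3), 1L))
    accept <- accept[accept <= k_var]
    B <- sv$v[, accept, drop = FALSE]
    dB <- apply(B, 2, function(col) c(0, diff(col)))
    d2B <- apply(dB, 2, function(col) c(0, diff(col)))
    dim(dB) <- dim(B)
    dim(d2B) <- dim(B)
    list(basis = B, dbasis = cbind(dB, d2B), k = length(accept),
         coherence = coh)
  }

  if (use_template) {
    Mall <- t(vapply(r, fetch, numeric(L)))
    tmpl <- apply(Mall, 2, function(col) mean(col, na.rm = TRUE))
    tmpl[is.na(tmpl)] <- 0
  } else {
    M <- t(vapply(r[full], fetch, numeric(L)))
    bb <- build_basis(M)
    basis <- bb$basis
    dbasis <- bb$dbasis
    k <- bb$k
    coherence <- bb$coherence
  }

  ## indices inside any beat window (ventricular-contaminated samples)
  in_window <- rep(FALSE, n)
  for (b in seq_len(nb)) in_window[start[b]:end[b]] <- TRUE

  # Extrapolate the atrial wave into a beat window from its QRS-free
  # flanks: outside the beat windows the record contains no ventricular
  # activity, so a harmonic fit (3 harmonics of the atrial frequency,
  # free amplitude and phase, plus a baseline line) on up to +/-0.6 s of
  # out-of-window samples predicts the atrial course inside the window
  # without any bias from the QRS-T itself.
  atrial_extrapolate <- function(fa_hat, seg) {
    flank <- max(1L, seg[1] - round(0.4 * fs)):min(n, seg[length(seg)] +
                                                     round(0.4 * fs))
    flank <- flank[!in_window[flank]]
    if (length(flank) < round(0.2 * fs)) return(NULL)
    t0 <- mean(seg / fs)
    harm <- function(idx) {
      ts <- idx / fs
      tc <- ts - t0
      out <- cbind(1, tc)
      for (hk in 1:3) {
        s1 <- sin(2 * pi * hk * fa_hat * ts)
        c1 <- cos(2 * pi * hk * fa_hat * ts)
        # tc- and tc^2-modulated terms track the slow phase/amplitude
        # drift of the fibrillatory wave across the extrapolation span
        out <- cbind(out, s1, c1, tc * s1, tc * c1,
                     tc^2 * s1, tc^2 * c1)
      }
      out
    }
    fit <- stats::lm.fit(harm(flank), x[flank])
    co <- fit$coefficients
    co[is.na(co)] <- 0
    # evaluate the harmonic part only: the intercept/slope belong to
    # baseline wander, which must stay in the output
    as.numeric(harm(seg)[, -(1:2), drop = FALSE] %*% co[-(1:2)])
  }

  # One subtraction sweep. The subtractable (ventricular) columns are the
  # basis components plus their time derivative, which absorbs residual
  # sub-sample misalignment of individual beats. The extrapolated atrial
  # wave is removed before the fit and added back afterwards; intercept
  # and slope nuisance regressors absorb local baseline wander. Neither
  # is subtracted from the output, so the ventricular coefficients are
  # not biased by the atrial wave caught inside the window.
  sweep_subtract <- function(fa_hat = NULL) {
    y <- x
    resid_ratio <- numeric(nb)
    for (b in seq_len(nb)) {
      seg <- start[b]:end[b]
      off <- seg - (r[b] + w0) + 1L   # positions within the template window
      yseg <- x[seg]
      atr <- if (!is.null(fa_hat) && is.finite(fa_hat))
        atrial_extrapolate(fa_hat, seg) else NULL
      target <- if (is.null(atr)) yseg else yseg - atr
      recon <- if (use_template) {
        tmpl[off]
      } else {
        vent <- cbind(basis[off, , drop = FALSE],
                      dbasis[off, , drop = FALSE])
        tg <- off / L
        cc <- qr.solve(cbind(vent, 1, tg), target)
        as.numeric(vent %*% cc[seq_len(ncol(vent))])
      }
      y[seg] <- yseg - taper_weights(length(seg)) * recon
      p0 <- sum(yseg^2)
      resid_ratio[b] <- if (p0 > 0) sum(y[seg]^2) / p0 else NA_real_
    }
    list(y = y, resid_ratio = resid_ratio)
  }

  # First sweep without atrial extrapolation gives a provisional atrial
  # signal; its dominant frequency parameterizes the harmonic model.
  first <- sweep_subtract(NULL)
  fa_hat <- tryCatch({
    est <- power_spectrum(first$y, fs)
    dominant_frequency(est, c(2.5, 15))
  }, error = function(e) NULL)

  res_sweep <- first
  if (!use_template && !is.null(fa_hat) && !is.na(fa_hat)) {
    # Rebuild the basis from atrial-cleaned windows: subtracting the
    # flank-extrapolated atrial wave from each beat before the SVD keeps
    # the beat-coherent part of the atrial wave out of the leading
    # component, which a plain SVD of a handful of beats cannot separate.
    rf <- r[full]
    clean_window <- function(ri) {
      seg <- ri + w0:w1
      v <- fetch(ri)
      atr <- atrial_extrapolate(fa_hat, pmin(pmax(seg, 1L), n))
      if (!is.null(atr)) v <- v - atr
      v
    }
    Mc <- t(vapply(rf, clean_window, numeric(L)))
    # realign on the cleaned windows (QRS subwindow): with the atrial wave
    # removed the correlation peak is unbiased
    refc <- colMeans(Mc)[qrs_sub]
    shift <- integer(length(rf))
    small_lags <- -5:5
    for (b in seq_along(rf)) {
      sc <- vapply(small_lags, function(l) {
        idx <- rf[b] + l + w0:w1
        if (idx[1] < 1L || idx[length(idx)] > n) return(-Inf)
        sum(clean_window(rf[b] + l)[qrs_sub] * refc)
      }, numeric(1))
      shift[b] <- small_lags[which.max(sc)]
    }
    if (any(shift != 0L)) {
      rf <- rf + shift
      r[full] <- rf
      start <- pmax(r + w0, lo_lim)
      end <- pmin(r + w1, hi_lim)
      Mc <- t(vapply(rf, clean_window, numeric(L)))
    }
    bb <- build_basis(Mc)
    basis <- bb$basis
    dbasis <- bb$dbasis
    k <- bb$k
    coherence <- bb$coherence
    res_sweep <- sweep_subtract(fa_hat)
  }
  y <- res_sweep$y
  resid_ratio <- res_sweep$resid_ratio

  structure(list(samples = y, fs = fs, lead = ecg$lead,
                 diagnostics = list(
                   method = if (use_template) "template" else "pca",
                   n_beats = nb, components_used = k,
                   component_coherence = coherence,
                   residual_power_ratio = resid_ratio,
                   truncated = truncated, edge = edge,
                   r_indices = r)),
            class = "atrial_ecg")
}

#' @export
print.atrial_ecg <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<atrial_ecg> %d samples @ %g Hz (lead %s)\n",
              length(x$samples), x$fs, x$lead))
  cat(sprintf("  QRS-T subtraction: %s, %d beats, %d component(s)\n",
              d$method, d$n_beats, d$components_used))
  invisible(x)
}
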