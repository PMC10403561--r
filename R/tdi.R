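#' Segment the atrial wall in a TDI sequence
#'
#' Per-frame echogenicity thresholding inside a (static) region of interest,
#' restricted to the valid imaging sector, keeping the largest connected
#' component in each frame. Frames whose mask comes out empty are flagged;
#' a sequence with more than 10% empty frames is rejected as unprocessable.
#'
#' @param seq A `tdi_sequence`.
#' @param roi Optional polygon (matrix/data.frame with columns `row`, `col`
#'   in pixel coordinates) delimiting the user-selected region of interest;
#'   `NULL` uses the whole imaging sector.
#' @param echo_threshold Echogenicity cutoff (arbitrary units, >= 0);
#'   pixels at or above it are wall candidates. Default 0.5, halfway between
#'   the generator's background (0.05) and wall (1.0) levels.
#' @return A `wall_mask`: `mask` (logical T x H x W), `roi`,
#'   `echo_threshold`, `empty_frames` (logical per frame).
#' @export
segment_wall <- function(seq, roi = NULL, echo_threshold = 0.5) {
  if (!inherits(seq, "tdi_sequence"))
    stop("seq must be a tdi_sequence", call. = FALSE)
  if (!is.numeric(echo_threshold) || echo_threshold < 0)
    stop("echo_threshold must be >= 0", call. = FALSE)
  e <- seq$echogenicity
  dm <- dim(e)
  nf <- dm[1]; h <- dm[2]; w <- dm[3]

  sector <- sector_valid_mask(seq$sector_geometry, h, w)
  base <- sector
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    if (ncol(roi) != 2L)
      stop("roi must have two columns (row, col)", call. = FALSE)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    inside <- pracma::inpolygon(as.numeric(rows), as.numeric(cols),
                                roi[, 1], roi[, 2], boundary = TRUE)
    base <- base & matrix(inside, h, w)
  }

  thr <- e >= echo_threshold
  tm <- matrix(thr, nf, h * w)
  tm[, !as.logical(base)] <- FALSE

  # largest connected component per frame (4-connectivity via EBImage)
  stack <- array(aperm(array(tm, c(nf, h, w)), c(2, 3, 1)), c(h, w, nf))
  labels <- EBImage::bwlabel(stack)
  out <- array(FALSE, c(h, w, nf))
  empty <- logical(nf)
  for (i in seq_len(nf)) {
    li <- labels[, , i]
    mx <- max(li)
    if (mx == 0) {
      empty[i] <- TRUE
    } else {
      counts <- tabulate(li, nbins = mx)
      out[, , i] <- li == which.max(counts)
    }
  }
  if (mean(empty) > 0.1)
    stop(sprintf(
      "unprocessable sequence: empty wall mask in %d of %d frames (>10%%)",
      sum(empty), nf), call. = FALSE)

  structure(list(mask = aperm(out, c(3, 1, 2)), roi = roi,
                 echo_threshold = echo_threshold, empty_frames = empty),
            class = "wall_mask")
}

sector_valid_mask <- function(geom, h, w) {
  if (is.null(geom)) return(matrix(TRUE, h, w))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- rows - geom$apex[["row"]]
  dc <- cols - geom$apex[["col"]]
  r <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  abs(theta) <= geom$half_angle_deg * pi / 180 & r <= geom$r_max
}

#' @export
print.wall_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<wall_mask> %d frames, %d x %d px, threshold %g, mean wall area %.0f px\n",
    d[1], d[2], d[3], x$echo_threshold, mean(apply(x$mask, 1, sum))))
  if (any(x$empty_frames))
    cat(sprintf("  %d empty frame(s) flagged\n", sum(x$empty_frames)))
  invisible(x)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b Logical arrays of equal dimension.
#' @return Scalar in [0, 1] (`NaN` if both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) stop("masks differ in size", call. = FALSE)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Average wall-pixel velocities into a single mechanical signal
#'
#' Per-frame arithmetic mean of the velocities of all pixels inside the
#' wall mask; averaging N pixels with independent noise reduces the noise
#' variance by about 1/N, which is what makes the 6-s segment spectrally
#' usable. Frames with an empty mask are interpolated linearly from their
#' neighbours and flagged.
#'
#' @param seq A `tdi_sequence`.
#' @param mask A `wall_mask` from [segment_wall()].
#' @return Numeric vector (cm/s) of length T with attribute
#'   `interpolated_frames` (integer indices, possibly empty).
#' @export
average_wall_velocity <- function(seq, mask) {
  if (!inherits(seq, "tdi_sequence"))
    stop("seq must be a tdi_sequence", call. = FALSE)
  if (!inherits(mask, "wall_mask"))
    stop("mask must be a wall_mask", call. = FALSE)
  dv <- dim(seq$velocity)
  if (!identical(dv, dim(mask$mask)))
    stop("mask and velocity dimensions differ", call. = FALSE)
  nf <- dv[1]
  v <- matrix(seq$velocity, nf, dv[2] * dv[3])
  m <- matrix(mask$mask, nf, dv[2] * dv[3])
  cnt <- rowSums(m)
  if (all(cnt == 0)) stop("wall mask is empty in every frame", call. = FALSE)
  out <- rowSums(v * m) / cnt
  bad <- which(cnt == 0)
  if (length(bad)) {
    good <- which(cnt > 0)
    out[bad] <- stats::approx(good, out[good], xout = bad, rule = 2)$y
  }
  attr(out, "interpolated_frames") <- bad
  out
}

# --- empirical mode decomposition -------------------------------------------

local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(mx = integer(0), mn = integer(0)))
  d <- diff(x)
  up <- d > 0
  dn <- d < 0
  list(mx = which(up[-(n - 1L)] & dn[-1L]) + 1L,
       mn = which(dn[-(n - 1L)] & up[-1L]) + 1L)
}

# Mean of the cubic-spline upper/lower envelopes, with mirror extension of
# two extrema at each end to control spline behaviour at the boundaries.
envelope_mean <- function(x) {
  n <- length(x)
  e <- local_extrema(x)
  if (length(e$mx) < 2L || length(e$mn) < 2L) return(NULL)
  ext <- function(idx) {
    l <- idx[seq_len(min(2L, length(idx)))]
    r <- idx[seq(to = length(idx), length.out = min(2L, length(idx)))]
    ti <- c(2 - rev(l), idx, 2 * n - rev(r))
    vi <- c(x[rev(l)], x[idx], x[rev(r)])
    keep <- !duplicated(ti)
    stats::spline(ti[keep], vi[keep], xout = seq_len(n), method = "fmm")$y
  }
  (ext(e$mx) + ext(e$mn)) / 2
}

#' Empirical mode decomposition by classic sifting
#'
#' Decomposes a 1-D signal into intrinsic mode functions (IMFs) and a
#' residual slow trend, fully data-driven and without assuming periodicity.
#' Each sifting pass finds local extrema, fits cubic-spline upper and lower
#' envelopes (with mirror extension of two extrema at each end), and
#' subtracts the envelope mean; the pass is accepted when the Cauchy-type
#' standard-deviation criterion drops below `sd_stop` or `max_sift_iters`
#' is reached. Extraction stops when the residual is monotone, has fewer
#' than 3 extrema, or `max_imfs` is reached. By construction the sum of all
#' IMFs plus the residual reconstructs the input to rounding error (perfect
#' reconstruction).
#'
#' @param x Numeric vector, length >= 16, all finite. A constant signal has
#'   no extrema and yields zero IMFs with `residual = x`.
#' @param fs Optional sampling rate in Hz, stored for [select_imfs()].
#' @param max_imfs Maximum number of modes to extract (default 12).
#' @param sd_stop Sifting stop threshold
#'   `sum((h_prev - h)^2) / sum(h_prev^2)` (default 0.2).
#' @param max_sift_iters Iteration cap per mode (default 100).
#' @return An `imf_set`: `imfs` (list, index 1 = highest-frequency mode),
#'   `residual`, `sift_counts`, `stop_reason` per mode, `fs`, `n`.
#' @export
emd_sift <- function(x, fs = NULL, max_imfs = 12L, sd_stop = 0.2,
                     max_sift_iters = 100L) {
  if (!is.numeric(x) || length(x) < 16L)
    stop("signal must be numeric with at least 16 samples", call. = FALSE)
  if (!all(is.finite(x)))
    stop("signal contains non-finite values", call. = FALSE)

  r <- as.numeric(x)
  imfs <- list()
  sift_counts <- integer(0)
  stop_reason <- character(0)

  repeat {
    e <- local_extrema(r)
    if (length(e$mx) + length(e$mn) < 3L || length(imfs) >= max_imfs) break
    h <- r
    iters <- 0L
    reason <- "max_iters"
    while (iters < max_sift_iters) {
      m <- envelope_mean(h)
      if (is.null(m)) {
        reason <- "too_few_extrema"
        break
      }
      h2 <- h - m
      sd_val <- sum(m^2) / max(sum(h^2), .Machine$double.eps)
      h <- h2
      iters <- iters + 1L
      if (sd_val < sd_stop) {
        reason <- "sd_criterion"
        break
      }
    }
    imfs[[length(imfs) + 1L]] <- h
    sift_counts <- c(sift_counts, iters)
    stop_reason <- c(stop_reason, reason)
    r <- r - h
  }

  structure(list(imfs = imfs, residual = r, sift_counts = sift_counts,
                 stop_reason = stop_reason, fs = fs, n = length(x)),
            class = "imf_set")
}

#' Reconstruct the original signal from an IMF set
#'
#' Sum of all IMFs plus the residual; equals the sifted input to rounding
#' error.
#'
#' @param imfset An `imf_set`.
#' @return Numeric vector of length `imfset$n`.
#' @export
imf_reconstruct <- function(imfset) {
  if (!inherits(imfset, "imf_set"))
    stop("imfset must be an imf_set", call. = FALSE)
  Reduce(`+`, imfset$imfs, imfset$residual)
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residual, n = %d", length(x$imfs), x$n))
  if (!is.null(x$fs)) cat(sprintf(" @ %g Hz", x$fs))
  cat("\n")
  if (length(x$imfs))
    cat("  sift iterations:", paste(x$sift_counts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.imf_set <- function(x, ...) {
  k <- length(x$imfs)
  op <- graphics::par(mfrow = c(k + 1, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(k))
    graphics::plot(x$imfs[[i]], type = "l", ylab = paste0("IMF ", i),
                   xlab = "", ...)
  graphics::plot(x$residual, type = "l", ylab = "residual", xlab = "sample",
                 ...)
  invisible(x)
}

#' Select IMFs in a physiological frequency band and reconstruct
#'
#' Keeps the modes whose dominant frequency falls inside the band of
#' plausible atrial mechanical rates, excluding very low-frequency modes
#' (residual ventricular motion) and very high-frequency modes (noise),
#' then sums the retained modes into the denoised atrial mechanical signal.
#'
#' @param imfset An `imf_set` with a known sampling rate (either stored at
#'   [emd_sift()] time or passed as `fs`).
#' @param band `c(lo, hi)` in Hz; default 2.5-15.
#' @param fs Sampling rate override in Hz.
#' @return An `imf_selection`: `signal` (the reconstruction), `selected`
#'   (mode indices), `imf_dfs` (dominant frequency of every mode), `band`.
#'   An empty selection is an error (the acquisition is unassessable).
#' @export
select_imfs <- function(imfset, band = c(2.5, 15), fs = imfset$fs) {
  if (!inherits(imfset, "imf_set"))
    stop("imfset must be an imf_set", call. = FALSE)
  if (is.null(fs))
    stop("sampling rate unknown: pass fs", call. = FALSE)
  if (length(band) != 2L || band[1] >= band[2])
    stop("band must be c(lo, hi) with lo < hi", call. = FALSE)
  if (!length(imfset$imfs))
    stop("no IMF with dominant frequency inside band: unassessable",
         call. = FALSE)

  dfs <- vapply(imfset$imfs, function(im) {
    est <- power_spectrum(im, fs)
    dominant_frequency(est, c(0, fs / 2))
  }, numeric(1))
  selected <- which(!is.na(dfs) & dfs >= band[1] & dfs <= band[2])
  if (!length(selected))
    stop("no IMF with dominant frequency inside band: unassessable",
         call. = FALSE)
  sig <- Reduce(`+`, imfset$imfs[selected])
  structure(list(signal = sig, selected = selected, imf_dfs = dfs,
                 band = band, fs = fs),
            class = "imf_selection")
}

#' @export
print.imf_selection <- function(x, ...) {
  cat(sprintf("<imf_selection> modes %s of %d in [%g, %g] Hz\n",
              paste(x$selected, collapse = ","), length(x$imf_dfs),
              x$band[1], x$band[2]))
  invisible(x)
}

#' Mean amplitude excursion of a velocity signal
#'
#' Average per-cycle peak-to-peak velocity excursion, a surrogate of
#' contractile amplitude. Cycles are delimited by successive positive-going
#' zero crossings of the (band-selected) signal; each cycle contributes its
#' max-minus-min excursion. Fewer than two crossings leave the quantity
#' undefined (`NA`).
#'
#' @param x Numeric vector (cm/s), non-empty.
#' @return Scalar mean excursion in cm/s, or `NA_real_`.
#' @export
mean_amplitude_excursion <- function(x) {
  if (!is.numeric(x) || !length(x))
    stop("signal must be a non-empty numeric vector", call. = FALSE)
  n <- length(x)
  if (n < 2L) return(NA_real_)
  cross <- which(x[-n] < 0 & x[-1L] >= 0) + 1L
  if (length(cross) < 2L) return(NA_real_)
  exc <- vapply(seq_len(length(cross) - 1L), function(i) {
    seg <- x[cross[i]:(cross[i + 1L] - 1L)]
    max(seg) - min(seg)
  }, numeric(1))
  mean(exc)
}
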