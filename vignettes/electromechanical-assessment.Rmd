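---
title: "Non-invasive assessment of atrial electromechanical dissociation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive assessment of atrial electromechanical dissociation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdecho)
```

## The problem

During atrial fibrillation (AF) the atria are activated electrically at
rates of 4-10 Hz, but the myocardium does not necessarily contract at the
rate it is excited. As the atrial myopathy progresses, excitation and
contraction decouple: the wall mechanically follows a slower rhythm than
the fibrillatory electrical activity. This *electromechanical dissociation*
is measurable non-invasively from two simultaneous 6-s observations:

* the **electrical activation rate (EAR)** — the dominant frequency (DF) of
  the surface ECG after the ventricular QRS-T complexes are removed, and
* the **mechanical activation rate (MAR)** — the DF of the tissue-Doppler
  (TDI) wall-velocity signal after segmentation, pixel averaging and
  empirical-mode-decomposition denoising.

The dissociation index is

$$\mathrm{EMD} = \mathrm{EAR} - \mathrm{MAR},$$

with the bilateral (two-atria) variant
$\mathrm{EMD} = \tfrac{1}{2}\left[(\mathrm{EAR}-\mathrm{MAR}_{RA}) +
(\mathrm{EAR}-\mathrm{MAR}_{LA})\right]$.
An acquisition is labelled *dissociated* when the index reaches the
threshold of 0.32 Hz. The threshold guarantees that the two spectral peaks
are separated by at least two resolvable bins of the 6-s segments; it is a
configurable constant (`threshold` argument throughout), with 0.32 Hz as
the default. The boundary is inclusive (an index of exactly 0.32 Hz is
dissociated), and negative indices — a mechanical rate faster than the
electrical one — are reported as-is and are by definition below threshold:
classification is one-sided.

## Spectral estimation

All rates are dominant frequencies of a mean-detrended, Hann-windowed
periodogram with 4x zero padding (`power_spectrum()`). The spectral
resolution of a segment is `1/duration` (0.1667 Hz at 6 s) regardless of
padding, which only interpolates peak positions. The DF search band
defaults to 2.5-15 Hz, covering programmed stimulation at 300 ms cycle
length (3.33 Hz) through accelerated AF above 8.5 Hz. Ties break toward
the lower frequency, a flat in-band spectrum has no DF, and `run_assessment()`
additionally requires the in-band peak to stand at least 3x above the
median in-band PSD (`min_prominence`) — an acquisition failing this gate is
reported *unassessable* rather than given a spurious DF.

The defaults were chosen once for peak localization quality; on-bin
frequencies (multiples of `1/duration`) are recovered exactly, and off-bin
frequencies within one un-padded bin. Every `spectral_estimate` records the
window and padding used.

## The TDI chain

1. **Segmentation** (`segment_wall()`): per-frame echogenicity thresholding
   inside a user polygon and the valid imaging sector, keeping the largest
   connected component. Full deformable wall tracking is out of scope: the
   synthetic walls are quasi-static, and the chain needs only a stable set
   of wall pixels. A sequence with more than 10% empty frames is rejected.
2. **Averaging** (`average_wall_velocity()`): the per-frame mean over wall
   pixels. With N pixels of independent noise the noise variance drops by
   about 1/N, which is what makes a single 6-s segment spectrally usable.
3. **Empirical mode decomposition** (`emd_sift()`): classic sifting with
   cubic-spline envelopes, mirror extension of two extrema at each end,
   and a Cauchy-type stopping rule (envelope-mean energy below `sd_stop =
   0.2` of the current mode energy, capped at 100 iterations per mode).
   The decomposition is exactly additive, so the sum of IMFs plus the
   residual reproduces the input to rounding error — this perfect
   reconstruction is asserted in the test suite over 50 varied inputs.
4. **Mode selection** (`select_imfs()`): modes whose DF falls in the
   physiological band (default 2.5-15 Hz) are summed; very slow modes
   (residual ventricular motion) and very fast modes (noise) are excluded.
   Selection is by frequency rather than by fixed mode index because the
   mode count depends on the noise realization. An empty selection marks
   the recording unassessable.
5. **Mean amplitude excursion** (`mean_amplitude_excursion()`): the mean
   per-cycle peak-to-peak velocity, cycles delimited by positive-going
   zero crossings of the band-selected signal. This per-cycle definition
   is a declared choice; with fewer than two crossings the quantity is
   reported missing.

## QRS-T cancellation

The atrial ECG is exposed by removing the ventricular complexes
(`detect_r_peaks()` + `subtract_qrst_pca()`). Detection is a
Pan-Tompkins-style energy detector (5-25 Hz zero-phase band-pass, squared
derivative, 150-ms integration, adaptive threshold, refractory period).

Subtraction is per-beat projection onto a ventricular basis obtained by
SVD of the aligned beat matrix (windows -60 to +400 ms around each R
apex; overlapping windows truncate at the midpoint between beats, edge
beats are flagged). The number of components is the smallest count whose
cumulative squared singular values reach `variance_target` (default 0.95,
capped at 5). A 6-s record at 40 bpm back-up pacing contains only 4
beats, which makes the naive rank rule fragile: the second component of
so small a beat matrix is typically dominated by the atrial wave caught
inside the windows, and subtracting it would strip atrial power. Three
safeguards keep the basis ventricular:

* **Coherence gate** — beyond the leading component, a component is kept
  only when its loadings have consistent sign and magnitude across beats
  (a genuinely ventricular morphology loads on every beat alike; atrial
  phases at the beat times are arbitrary).
* **Atrial flank extrapolation** — outside the beat windows the record is
  ventricle-free, so a harmonic model (three harmonics of the atrial DF
  with slowly drifting amplitude/phase) fitted on up to 0.4 s of flanking
  samples predicts the atrial course *inside* each window without QRS-T
  bias. The prediction is removed before the basis is built and before
  projection coefficients are fit, and is never subtracted from the
  output.
* **Nuisance regressors** — an intercept and slope per window absorb
  baseline wander; derivative and second-derivative copies of the basis
  absorb residual sub-sample beat misalignment. These columns are fit
  alongside the ventricular ones, and only the ventricular part of the
  fit is subtracted, with a 10-ms raised-cosine taper at the window
  borders.

Beat alignment itself uses cross-correlation restricted to the QRS
subwindow (-60 to +80 ms), where the R wave exceeds the atrial wave by
an order of magnitude, and is repeated after atrial cleaning. With fewer
than three beats no basis can be estimated and a flagged mean-template
subtraction is used; with zero beats the record passes through unchanged.
Samples outside every beat window are returned bit-identical.

One caveat is worth stating explicitly: when the atrial rate is an exact
multiple of the ventricular rate (for example 6 Hz against the 0.667 Hz
back-up pacing), the atrial wave is identical in every beat window and no
subtraction method — template, PCA or otherwise — can separate the two on
algebraic grounds. The test suite therefore evaluates cancellation at a
generic, non-beat-synchronous atrial rate.

## Optical ratiometry

For dual-dye optical mapping of contracting tissue, each dye is excited at
two wavelengths whose emissions move in antiphase with the signal while
contraction scales both by the same factor. `ratiometric_demix()` divides
the channel pairs, cancelling any strictly positive multiplicative motion
artifact exactly (to machine precision), and normalizes each ratio by its
temporal mean so spectral estimation sees a zero-mean fluctuation.
`vca_dissociation()` then computes DF(Vm), DF(Ca), their difference (the
cellular correlate of electromechanical dissociation, thresholded at the
same 0.32 Hz) and the voltage-frequency stratum with edges 6.5 and 8.5 Hz.
The strata partition the axis as [0, 6.5), [6.5, 8.5], (8.5, Inf): the
printed ranges leave the edge membership open, and the middle-bin closure
is a declared choice. The mapping of the four physical channels to the two
numerator/denominator pairs is hardware-specific; generator, demixer and
container share one declared convention (`vm_num`, `vm_den`, `ca_num`,
`ca_den`).

## The synthetic generator

`gen_tdi_ecg()` and `gen_optical()` emulate the experimental acquisitions
with known ground truth; all tests run against them.

* Acquisition constants are the experimental ones: 6-s segments, TDI frame
  rate 250 Hz (protocol requires >200 Hz), ECG at 1000 Hz, a 15 cm/s
  aliasing-free Doppler scale, back-up ventricular pacing at 40 bpm
  (beats at 0.5, 2.0, 3.5, 5.0 s), optical recordings at 500 frames/s.
* Scenarios: programmed stimulation at 300/250/200 ms cycle length
  (electrical = mechanical rate), a 10 Hz burst-pacing segment, and
  sustained AF with independently settable electrical and mechanical
  rates plus 2% slow frequency jitter (demeaned, so the realized mean
  rate equals the configured one).
* The atrial ECG wave is a harmonic quasi-sawtooth (fundamental + 2
  decaying harmonics); the QRS-T complex is a Gaussian-sum morphology
  (Q, R, S, T lobes, 400 ms, R amplitude 10x the atrial wave); baseline
  wander is a 0.3 Hz sinusoid. The wall velocity is the same harmonic
  construction at 3 cm/s with a spatially uniform low-frequency
  ventricular transient (Gaussian, sigma 120 ms, 2 cm/s) time-locked to
  each ventricular beat. White noise enters at `snr_db` relative to the
  clean atrial component (10 dB default).
* Geometry: a fan-shaped imaging sector of 24 x 32 px with a curved wall
  band (roughly 200 pixels), echogenicity 1.0 against a 0.05 background
  with sigma = 0.1 noise. Frame size is a quality/runtime compromise; the
  pipeline is insensitive to it beyond the 1/N averaging gain.
* The optical generator multiplies all four channels by
  `1 + depth * sin(2 pi f_motion t)` and keeps intensities strictly
  positive for any depth < 1; by default the optical recording is clean,
  since the ratio identity it validates is algebraic.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: speckle and B-mode texture, wall
deformation and through-plane motion, pacing-spike artifacts, ectopy and
variable QRS morphology, dye photobleaching and shot noise, and genuinely
non-stationary AF dynamics. The generator's AF f-wave morphology is a
declared stand-in (narrowband harmonic with mild jitter), chosen to match
the narrowband DF peaks seen in real recordings without inventing
physiology.

## Numerical choices and degenerate inputs

* Sifting: mirror extension of two extrema controls spline end effects;
  constant signals return zero modes with `residual = input`; non-finite
  input is an error. Signals must have at least 16 samples.
* DF estimation: mean detrending removes the DC bin; an all-zero in-band
  spectrum yields a missing DF, which propagates to a missing index and an
  unassessable label rather than an arbitrary value.
* Wall averaging interpolates isolated empty-mask frames linearly and
  flags them; an everywhere-empty mask is an error.
* The dissociation recovery sweep in the acceptance tests uses on-bin
  rates (integer Hz) so the check is insensitive to window/padding
  choices; problem sizes there (56 rate pairs x 10 seeds, full pipeline on
  24 x 32 x 1500 stacks) keep the suite to a few minutes.

## Known limitations

* Wall "tracking" is per-frame thresholding in a static ROI; real moving
  walls need deformable tracking before this chain applies.
* The coherence gate assumes ventricular morphology is near-constant
  across the handful of beats in a 6-s segment; strongly varying
  morphology (bigeminy, bundle-branch alternation) would be rejected from
  the basis and left partially uncancelled.
* Beat-synchronous atrial rates are algebraically unseparable from the
  ventricular template (see above); real AF is jittery enough that exact
  synchrony is transient.
* The 0.32 Hz threshold is tied to ~6-s segments; for other durations the
  two-bin separation argument implies a different threshold, which the
  user can supply but the package does not derive automatically.
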