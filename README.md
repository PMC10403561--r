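# emdecho

Non-invasive assessment of **atrial electromechanical dissociation** during
atrial fibrillation (AF), for cardiac electrophysiologists and biomedical
signal-processing researchers working with simultaneous tissue-Doppler
(TDI) and surface-ECG acquisitions.

During AF the atria can be excited electrically much faster than they
contract. The package quantifies this decoupling from a single 6-s
simultaneous acquisition:

* **EAR** (electrical activation rate): dominant frequency (DF) of the
  surface ECG after the ventricular QRS-T complexes are removed by
  PCA-based cancellation;
* **MAR** (mechanical activation rate): DF of the atrial wall velocity
  signal obtained from a TDI frame stack by wall segmentation, pixel
  averaging and empirical-mode-decomposition denoising;
* the dissociation index

  ```
  EMD = EAR − MAR          (bilateral: EMD = [(EAR − MAR_RA) + (EAR − MAR_LA)] / 2)
  ```

  classified as **dissociated** when it reaches the 0.32 Hz threshold
  (two resolvable spectral bins of a 6-s segment; boundary inclusive,
  negative indices reported as-is).

A companion module implements dual-excitation **ratiometric optical
mapping** analysis: dividing the paired emission channels cancels the
multiplicative contraction artifact exactly, and the voltage–calcium DF
difference (the cellular correlate of electromechanical dissociation) is
thresholded at the same 0.32 Hz and stratified by voltage DF
(<6.5 / 6.5–8.5 / >8.5 Hz).

Every input can be produced by the built-in synthetic generator
(`gen_tdi_ecg()`, `gen_optical()`) with known ground truth — programmed
atrial stimulation at 300/250/200 ms cycle length, 10 Hz burst-pacing
segments, sustained AF with independently controllable electrical and
mechanical rates, 40-bpm back-up ventricular pacing or irregular
conduction, baseline wander and additive noise — so the whole pipeline is
testable without any external data.

## Worked example

```r
library(emdecho)

cfg <- synth_config("af", electrical_freq = 6.2, mechanical_freq = 4.3,
                    seed = 42)
acq <- gen_tdi_ecg(cfg)
acq$tdi
#> <tdi_sequence> 1500 frames of 24 x 32 px @ 250 Hz (6.00 s)
#>   simultaneous ECG: lead II, 6000 samples @ 1000 Hz

res <- run_assessment(acq$tdi)
res
#> <dissociation_result>
#>   EAR 6.1667 Hz | MAR 4.2500 Hz | index +1.9167 Hz
#>   label: dissociated (threshold 0.32 Hz)
#>   mean amplitude excursion: 7.27 cm/s
```

The generator was asked for an AF episode whose wall contracts at 4.3 Hz
while the fibrillatory ECG runs at 6.2 Hz (the 2% stochastic frequency
jitter of the AF scenario shifts both rates slightly off their nominal
values). The pipeline recovers both rates to within one spectral bin
(1/6 Hz), yields a dissociation index of about 1.9 Hz — well above the
0.32 Hz threshold, hence *dissociated* — and reports the mean per-cycle
peak-to-peak wall-velocity excursion. `res$provenance` holds every
intermediate: detected beats, PCA rank, selected intrinsic mode
functions, and both spectral estimates.

Individual stages are exported (`detect_r_peaks()`, `subtract_qrst_pca()`,
`segment_wall()`, `average_wall_velocity()`, `emd_sift()`,
`select_imfs()`, `power_spectrum()`, `dominant_frequency()`, ...), as are
HDF5/CSV container readers and writers (`write_tdi_container()`,
`read_tdi_container()`, `write_ecg_csv()`, ...). For optical recordings:

```r
o <- gen_optical(synth_config("optical", seed = 1), vm_freq = 9, ca_freq = 4.5)
vca_dissociation(ratiometric_demix(o$recording))
#> <ratio_signals> 3000 samples @ 500 fps
#>   DF(Vm) 9.000 Hz | DF(Ca) 4.500 Hz | dissociation +4.500 Hz (dissociated, bin >8.5)
```

See the vignette (`vignettes/electromechanical-assessment.Rmd`) for the
model, its assumptions, the tunable parameters and known limitations.

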