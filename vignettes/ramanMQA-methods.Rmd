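---
title: "Methods: internal-standard semi-quantification of single-cell Raman cubes"
author: "ramanMQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: internal-standard semi-quantification of single-cell Raman cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A confocal Raman area scan of a single cell yields a hyperspectral cube:
one spectrum per ~450 nm pixel on a shared wavenumber axis.  Raman
intensity is *not* proportional to analyte abundance across pixels or
samples: it is modulated by scattering cross-sections, focus, local
optical properties and instrument drift.  ramanMQA therefore treats a
pixel spectrum as

  S(x, y, w) = g(x, y) * sum_m c_m(x, y) * R_m(w) + b(x, y, w) + noise,

where `g` is an unknown per-pixel gain, `c_m` the metabolite
concentrations, `R_m` pure-component spectra, and `b` a smooth
fluorescence baseline.  After baseline removal, the band area
`A = integral of S over a peak window` inherits the gain, so the package's
central quantity is the internal-standard ratio

  dA = A_metabolite / A_internal_standard,

in which `g` cancels exactly.  dA is *semi-quantitative*: per metabolite
it is proportional to concentration with an unidentified constant (the
ratio of Raman cross-sections), so it supports comparisons across
pixels, compartments, cells and treatment groups, but not absolute
concentrations.  The assumptions are (i) linearity of the Raman response
(no resonance enhancement at the excitation wavelength), (ii) an
internal-standard band whose underlying component is uniformly
distributed and stable across conditions, and (iii) adequate baseline
removal.  The shipped default internal standard is the 1341 cm^-1 band
(tentatively assigned to threonine); `selectInternalStandard()`
re-derives the choice on any cube by ranking candidate bands by spatial
coefficient of variation, and a between-group CV report serves as the
stability cross-check.

## Preprocessing

Stages run in a configurable order; the default is despiking, baseline
correction, Savitzky-Golay smoothing.

* **Axis calibration.** A silicon wafer's 520 cm^-1 phonon band is the
  single-point calibrant.  The apex is located by quadratic
  interpolation of the three channels around the grid maximum inside a
  +/-30 cm^-1 search window and a rigid shift is applied.  On a 2 cm^-1
  grid the interpolation bias for a Gaussian band (sigma 4 cm^-1) is
  below 0.03 cm^-1.  Offsets above 15 cm^-1 are applied but flagged.
* **Cosmic-ray removal.**  Detector hits are narrow (1–2 channels) and
  spatially isolated.  Each pixel is compared to the channel-wise median
  of its valid 8-connected neighbours; the deviation is scored with a
  modified z-score whose centre and scale are *running medians* (window
  15 channels, constant end-rule) — a global MAD would over-flag
  strong-signal channels, because shot-like noise scales with signal.  A
  channel is flagged only if it also exceeds the threshold (default 8)
  on the same score applied to the spectral second difference; this
  narrowness test is what separates spikes from genuine band differences
  at compartment boundaries, which are spectrally broad.  Flagged runs
  are repaired by linear interpolation from the nearest clean channels;
  unflagged channels are never touched.  Pixels with fewer than three
  valid neighbours fall back to the spectral score alone.
* **Baseline.**  Default is asymmetric least squares (a Whittaker
  smoother with weights p = 0.01 above the baseline and 1 - p below,
  iterated to weight stability, at most 20 passes).  The smoother
  stiffness is lambda = 1e6: at 1e5 the estimate bends into the
  Lorentzian tails of strong bands, which both biases band areas and
  breaks idempotence (re-correcting a corrected cube changed its RMS by
  ~1.4%); at 1e6 re-correction changes the RMS by < 1% and Gaussian
  area recovery on a sloped background improves from ~2.2% to ~1.7%
  error.  Because the weights depend only on the residual's sign, the
  correction is exactly equivariant under positive rescaling.  A small
  residual bias of order the noise floor remains (the baseline settles
  near the lower envelope of the noise); it cancels in dA to first
  order.  An iterative-polynomial alternative (degree 3) is provided.
* **Smoothing.**  Savitzky-Golay, window 9 / order 3; edges are refit on
  the truncated window rather than mirror-padded so no intensity is
  invented outside the measured range.
* **PCA denoising** is available but *off by default* in quantification
  paths: low-rank reconstruction can redistribute band area between
  correlated channels.  Segmentation does not need it switched on, since
  clustering already operates on PCA scores internally.

The despike-first default departs from a baseline-first convention
deliberately: a cosmic spike is a gross outlier that corrupts any
baseline estimate through its channel, while despiking is insensitive to
a smooth baseline.  The order remains configurable.

## Compartmentalization

`kmeansCluster()` vector-normalizes spectra (unit L2 norm) so that
segmentation reflects spectral *shape*, not brightness, then runs
k-means (10 restarts, up to 200 iterations) on the top 10 PCA scores.
`selectK()` scans k and picks the maximum mean silhouette width, ties
going to the smaller k; the full profile is always reported because the
operator may prefer a biologically motivated k.  `trueComponentAnalysis()`
is an open reimplementation of linear-combination component imaging:
endmembers are sought among observed pixel spectra by a deterministic
successive-projection (greedy simplex-volume) search on PCA scores
augmented with a constant coordinate, and abundances come from
non-negative least squares on *unnormalized* spectra so they track
quantity.  The vertex sequence is nested in the component count, which
makes the per-pixel residual weakly decreasing in the number of
components — a useful sanity invariant.  It is an approximation of
proprietary component-imaging tools, not a clone.  Cluster attribution
follows the difference-peak idiom: each cluster's contrast spectrum
(cluster mean minus the mean of the other clusters) is scanned for
prominent maxima, which are matched against the band library and voted
into a compartment class (nucleus / lipid droplet / symbiont /
cytoplasm), with the conventional red / yellow / green-cyan / blue
palette for composites.

## Quantification

`integratePeak()` integrates the closed window (default half-width
8 cm^-1) by the trapezoid rule, linearly interpolating intensity at the
exact window bounds, so the operator is linear in intensity and exact
for piecewise-linear spectra.  An optional chord baseline (the line
joining the window endpoints) supports inputs that skipped global
baseline correction.  `ratioMap()` floors the denominator at
epsilon = 1e-6 x max(A_IS) to avoid ratio blow-up at near-empty pixels;
negative areas (over-subtraction) are kept and flagged rather than
clipped so linearity and conservation checks stay exact, with an
optional clip-at-zero mode in the statistics.  Group comparisons are
descriptive (mean +/- SD per compartment), deliberately without
hypothesis testing.  `fitCalibration()` is ordinary least squares of dA
on concentration.  In the mock-sample design the analyte (glucose) is
varied against a fixed internal standard; the published account of that
experiment once names the fixed component as the regressor, which is
internally inconsistent — the calibration here regresses on the *varied*
analyte's concentration.

A note on band collisions: univariate windows are not selective.  The
library itself records near-coincident markers (nucleic-acid 1078 vs
cholesterol 1083; NADH 1114 vs glucose 1127; lanosterol 1643,
palmitoleic 1656 and squalene 1666), so a window's dA in a compartment
dominated by the colliding component reflects that component, not the
nominal analyte.  This is a property of univariate band imaging itself
and is the reason the multivariate step exists; end-to-end recovery
tests therefore assert proportionality on windows that are not
confounded in the phantom, and monotone/proportional response for the
rest via controlled concentration sweeps.

## The phantom generator

Every quantitative claim in the test suite is scored against synthetic
bacteriocyte phantoms with known truth.  The default phantom is a
48 x 48 grid (450 nm pixels, axis 400–3100 cm^-1 at 2 cm^-1, near the
3 cm^-1 resolution of a typical dispersive system): an elliptical cell
with a nucleus disc at the basal pole, three lipid-droplet discs beside
it, an outer apical symbiont shell split into strain A (outermost,
glycogen-rich) and strain B (inward), and cytoplasm.  Reference spectra
are pseudo-Voigt renderings of the library bands plus 2–4 fixed
"filler" bands per metabolite (positions chosen away from every
analysis window) so components overlap realistically.  Compartment
concentration profiles encode only ordinal relations that matter to the
analysis (strain A glycogen > strain B; threonine constant everywhere);
the magnitudes are package choices, not biological claims.  Noise is
Gaussian with variance a x signal + floor — a continuously tunable
approximation of shot noise (SNR 20 by default, defined at the peak of
the mean in-cell spectrum); the baseline is a smooth decaying
fluorescence-like profile with spatially varying amplitude; a smooth
deterministic gain field spans roughly 0.75–1.25; twelve cosmic spikes
are injected at seeded positions.  Phantoms are bit-reproducible from
(parameters, seed): one `set.seed(childSeed(seed, "phantom"))` at entry,
then droplet jitter, the noise matrix, and spike positions/amplitudes
are drawn in that fixed order.  The noiseless limit is exactly linear in
the concentrations, which the analytic oracles rely on.

What the phantom does *not* emulate: optical point-spread mixing at
compartment boundaries, confocal depth sectioning, detector
nonlinearity, fixation chemistry, and within-compartment concentration
texture.  Passing tests therefore demonstrate correctness of the
algorithms under the stated model, not performance on real tissue.

The calibration series emulates the mock experiment: six analyte levels
(1–6 arbitrary units of glucose) against threonine fixed at 2.  Its
default SNR is *calibrated, not tuned*: `calibrationNoiseSweep()` runs
seeded replicate sweeps over an SNR grid and the shipped default (250)
is the noisiest grid level at which at least 95% of replicates reach
the R^2 >= 0.9998 linearity benchmark.  The sweep is exported so the
choice can be audited.

## Numerical choices and tie-breaks

* Pixel addressing is 0-based, row-major, top-left origin, everywhere.
* Non-finite intensities on ingest: reject by default, mask on request;
  nothing is silently propagated or rescaled at I/O.
* k-means ties go to the lowest cluster index (stats::kmeans behavior);
  silhouette ties to smaller k; internal-standard CV ties to the lower
  band center; cluster/endmember matching in tests uses best-permutation
  assignment.
* Degenerate inputs: flat cubes abort k selection; empty clusters yield
  an NA mean with a warning; labels with no valid pixels are omitted
  from statistics with a warning; all-flagged pixels are masked.
* Problem sizes in the shipped tests (48 x 48 x 1351 default phantom,
  24–32 pixel grids for sweeps, 100-replicate calibration runs) keep
  the whole suite in the low minutes on a single core while leaving
  every compartment with enough pixels for stable statistics.

## Known limitations

dA is comparative only; absolute quantification would need external
calibration per metabolite and correction of depth-dependent signal
loss, both out of scope.  The internal-standard assumption is itself
empirical: the package verifies spatial uniformity and cross-group
stability on the data at hand, but cannot prove the underlying
component is biologically invariant.  Band-collision cross-talk bounds
the interpretability of univariate maps for the colliding pairs listed
above.  The AsLS baseline carries a noise-floor offset of order one
noise SD, common to all pixels and largely cancelled by the ratio.
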