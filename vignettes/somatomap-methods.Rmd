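---
title: "Methods: somatotopic mapping from event-related and phase-encoding fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatotopic mapping from event-related and phase-encoding fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Vibrotactile stimulation of a single fingertip activates a band of primary
somatosensory cortex (S1), and the bands for the five digits are laid out in
an orderly somatotopic sequence. The scientific question this package is
built around is not *where* each fingertip maps, but *how much the maps
overlap*: the anterior strip of S1 (posterior bank of the central sulcus,
putative area 3b) responds with high fingertip specificity, while the
posterior strip (post-central gyrus, areas 1/2) responds to several adjacent
— sometimes all five — fingertips. `somatomap` implements the single-subject
analysis chain that quantifies this overlap from 7T BOLD data, and a
synthetic-data generator that provides ground truth for every stage.

## Pipeline overview

1. **Localizer (traveling wave).** The fingertips are stimulated cyclically
   (digit 1 to 5, `forward`, or 5 to 1, `reverse`). After high-pass
   filtering (0.01 Hz brick-wall DFT filter) and percent-signal conversion,
   forward and time-reversed reverse runs are averaged, which cancels the
   common hemodynamic phase delay. The DFT bin at the stimulation frequency
   gives per-voxel amplitude, phase and coherence (amplitude at the
   stimulation frequency over root-total non-DC amplitude). Fingertip ROIs
   are the largest connected components of gray-matter voxels with coherence
   above 0.25 inside each of five phase bins of width 2&#960;/5.
2. **Analysis volume.** The ROI union is dilated by 5 voxels (Euclidean
   lattice ball) inside the brain mask; all event-related statistics are
   restricted to this small volume to limit the number of tests.
3. **Event-related GLM (two-step).** Each 1 s trial is convolved with a
   canonical double-gamma HRF and its orthogonalized temporal derivative
   (10 task regressors, plus one intercept per run). Step 1 is OLS with
   default timing (6 s / 16 s times-to-peak); the subject's hemodynamic
   timing is then read off the reconstructed per-ROI response, and step 2
   refits by GLS with a tile-wise, Tukey-tapered noise autocorrelation.
   One-sided t-tests per fingertip are corrected across voxels by adaptive
   step-down FWE (Holm with estimated true-null count) and adaptive step-up
   FDR; adjusted p-values are converted to standard-normal Z.
4. **FIR deconvolution.** An independent nonparametric HRF estimate: 13
   time-shifted indicator regressors per fingertip (0–12 TRs of delay).
5. **Overlap quantification.** Per-voxel counts of activating fingertips,
   exactly-*k* proportions across Z thresholds, and the adjacent-pair
   overlap ratio |A&#8745;B| / ((|A|+|B|)/2) (a Dice coefficient), computed
   within anterior-ROI, posterior-ROI and posterior-to-ROI voxel sets.
6. **Vein mapping.** A susceptibility phase volume is unwrapped, high-pass
   filtered (subtraction of a Gaussian-smoothed copy), thresholded, and
   dilated by a 2 mm spherical element; activation can then be stratified by
   0.5 mm vein proximity.

## The synthetic world

The generator's defaults state a specific world, chosen once:

* **Grid**: 32 × 32 × 8 voxels at 1.5 mm isotropic (the acquisition's voxel
  size; the grid is desk-scale so a full study simulates in seconds).
* **Bands**: five finger-preference bands along the first axis, centres
  5.5 mm apart — the observed adjacent-digit centre-of-mass separation on
  the cortical surface. Tuning falls off as exp(−d²/2&#963;²) with
  &#963; = 3 mm in the anterior compartment and 6 mm in the posterior
  (2:1, encoding "narrow anterior, broad posterior"). Gray matter occupies
  the first 85% of the second axis; the brain extends one shell further, so
  a "posterior to the ROIs" region exists.
* **ER paradigm**: 30 trials per run, 6 per fingertip, onsets locked to
  volume starts, inter-trial intervals uniform on {4, 6, 8, 10, 12} s, each
  fingertip exactly once per successive block of five trials; a 20 s tail is
  appended because the run length is otherwise unstated. Six runs by
  default.
* **Localizer**: the cycle period and count are inherited from a prior
  localizer design and are free parameters here; the defaults (40 s cycles,
  8 cycles) give a 320 s run with 8 s per-finger epochs.
* **Signal and noise**: single-trial peak amplitude 2% of baseline (100);
  stationary AR(1) noise with marginal SD 0.4% and &#961; = 0.3; one
  sinusoidal drift of 1% at 128 s period (below the 0.01 Hz cut-off so the
  filter stage can be shown to remove it). Peak SNR is therefore 5.
* **Seeds**: one master seed; sub-seeds by fixed documented offsets
  (`seed+100+r` for ER run r, `seed+200/201+2q` for localizer pairs).

What the generator does **not** emulate: head motion, geometric distortion,
physiological (cardiac/respiratory) noise, spatial noise correlations,
partial-volume effects, and the surface-based registration round trip (the
gray-matter restriction is a mask, and synthetic meshes live directly in the
volume's mm frame). A green test therefore establishes correctness of the
statistical machinery under the stated model, not robustness to artifacts
the model omits.

## Numerical and statistical choices

**Gamma parameterization.** Only the times-to-peak are constrained by the
design, so each gamma has unit dispersion and shape `t_peak + 1`: its mode
is exactly the requested time-to-peak. The undershoot amplitude ratio is
1/6, the conventional canonical value. The curve is peak-normalized to 1.

**Curve peaks versus gamma parameters.** Subtracting the undershoot gamma
moves the minimum of the *curve* later than the undershoot gamma's mode: for
timing (6, 16) the curve minimum is at 16.97 s, and for (3.08, 9.18) at
10.95 s. The timing estimator reads peak times directly off the
reconstructed response (the reported convention), so what it returns — and
what recovery is measured against — are the numerically computed peak times
of the generating curve, not the gamma parameters. `timing_from_peaks()`
inverts the peak-time map when a basis must be rebuilt from measured peaks;
the inverse is not unique (a narrow and a wide undershoot can place the
minimum at the same time) and the wider, more physiological branch is taken.

**Iterated timing step.** A single canonical + derivative reconstruction is
a linearization around the basis timing and cannot track peak shifts of
several seconds (it reads ~3.9 s for a curve peaking at 3.07 s when started
from 6 s). The pipeline therefore repeats the measurement with a re-timed
basis until the measured peaks move by less than 0.05 s (at most 3
iterations by default). Each iteration is exactly the single measurement
operation; only the basis changes.

**Noise model.** Residuals are averaged within 20 × 20 in-slice tiles
(excluding non-brain voxels; empty tiles inherit their nearest populated
neighbour). Because least-squares residuals underestimate serial correlation
(their autocovariances are a known linear map, through the hat matrix, of
the true ones), the map is inverted on the first M lags before tapering —
without this correction the one-sided GLS test runs at ~6.5% instead of 5%.
The Tukey taper 0.5(1+cos(&#960;k/M)) with M = round(2&#8730;T) lags
stabilizes the estimate; the whitened-model degrees of freedom are
T − rank(X) with no small-sample correction, a documented approximation.
Noise is treated as independent across runs: whitening and autocovariance
estimation act within runs only. The tile ACF needs several runs to be
accurate deep in the tail: at a single 130-frame run the familywise error of
the end-to-end null pipeline inflates to roughly double its nominal level,
which is why calibration claims are made at the default six-run design.

**Estimated true-null count.** The least-squares m0 estimator is a
changepoint fit: with m0 true nulls the m − m0 smallest sorted p-values sit
near zero and the m0 largest follow the uniform order-statistic line
p_(m−m0+j) = j/(m0+1); the total squared deviation is minimized over a
candidate grid with local refinement. On pure null vectors it estimates
m0 &#8776; m, on pure signal 0, and on a 50/50 mixture &#8776; m/2. Note that
adaptive FDR q-values computed with m0 < m can legitimately fall below the
raw p-value, as q-values do; FWE-adjusted values always dominate raw p.

**Phase bins and ties.** Phase bins are half-open, so a phase of exactly 0
belongs to digit 1's bin. In the phantom, voxels exactly equidistant from
two band centres (which the 5.5 mm spacing places on the lattice) are
assigned to the finger nearer the middle of the array, because the
asymmetric tails of the distant fingers pull the measured traveling-wave
phase toward the array centre at such voxels. With the default overlapping
tuning this same pull biases edge-of-array voxels, so perfect agreement
between phase-defined ROIs and the tuning argmax is only attainable for
phantoms with well-separated ("distinct") bands; the default world reaches
about 93%.

**FIR window.** The deconvolution design models 0–12 TRs (0–24 s) of
response. Exact noiseless recovery is only possible when the generating
kernel's support fits inside that window, so exactness tests generate with a
24 s kernel; the default 32 s kernel leaves a ~0.6% tail outside the window.

**Phase unwrapping.** Deterministic sequential integration of wrapped
finite differences (anchor line along the third axis, anchor plane along the
second, all remaining lines along the first). This is exact — up to one
global multiple of 2&#960; — whenever the true phase changes by less than
&#960; between neighbouring voxels along the integration paths, which the
vein phantom guarantees. A Laplacian/DCT solver was considered and rejected:
it attenuates low-frequency ramps, failing exactly the ramp-recovery case
that matters for the background field. The phase high-pass uses odd
(antisymmetric) reflection padding so that constants *and* linear ramps pass
through the smoother unchanged at the volume edges. The vein threshold
default of 0.3 rad was calibrated once on the vein phantom (sensitivity 1.0,
false-positive fraction &#8804; 0.02 across seeds) and is configurable.

**Overlap ratio.** Implemented exactly as printed — intersection over the
arithmetic mean of the two activation counts — which coincides with the Dice
coefficient. Exactly-*k* proportions are reported among voxels active in at
least one condition (so the five fractions sum to 1); the all-voxels
denominator is available by flag.

**Other conventions.** Voxel indices are 0-based with centres at
index × size; centre-of-mass is the unweighted mean of member voxel centres.
ROI contiguity is 6-connectivity (26 available). Multiple runs are fitted as
one concatenated GLM with per-run intercepts. Z conversion floors at the
quantile equivalent to p = 1 − 10&#8315;&#185;&#8310; to keep maps finite.

## Known limitations

* Calibration guarantees are asymptotic in the amount of data used for the
  noise ACF; single-run analyses are visibly anticonservative in the deep
  tail (see above).
* The two-regressor timing measurement is biased toward the basis timing at
  any single iteration; convergence of the iterated step has been verified
  on phantoms but carries no general proof.
* The generator omits motion, distortion and physiological noise entirely;
  no claim about robustness to them is made or tested.
* The anterior/posterior boundary is supplied (phantom ground truth, or a
  user label map); drawing it from overlap maps, done manually on flattened
  cortex in practice, is out of scope.
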