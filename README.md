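# somatomap

Single-subject somatotopic mapping of fingertip representations in primary
somatosensory cortex (S1) from high-field BOLD fMRI. The package is for
researchers who run event-related (ER) and traveling-wave (phase-encoding)
fingertip-stimulation experiments and want a tested, reproducible pipeline
for the question those designs answer together: **how specific is each patch
of S1 for one fingertip, and how much do adjacent fingertip activations
overlap?**

Everything can be exercised without scanner data: a synthetic-data module
generates somatotopic phantoms with known tuning, randomized ER paradigms,
cyclic localizer runs, autocorrelated noise and vein-like susceptibility
phase volumes, so every stage is validated against ground truth.

## The analysis in brief

* **Localizer**: per voxel, the DFT at the stimulation frequency of the
  combined forward + time-reversed-reverse runs gives amplitude, phase
  &#966; &#8712; [0, 2&#960;) and coherence
  C = A(f&#8320;) / &#8730;(&#931;<sub>f>0</sub> A(f)&#178;). Fingertip ROIs
  are connected gray-matter components with C > 0.25 inside phase bins of
  width 2&#960;/5; the ROI union dilated by 5 voxels is the analysis volume.
* **ER GLM**: y = X&#946; + &#949;, with two regressors per fingertip (1 s
  boxcar convolved with a double-gamma HRF, plus its orthogonalized temporal
  derivative). Two steps: OLS with canonical timing (6 s / 16 s
  times-to-peak), per-subject timing re-estimated from the fingertip ROIs,
  then GLS by prewhitening with a tile-wise (20 × 20 in-slice),
  Tukey-tapered, bias-corrected noise autocorrelation. One-sided t-tests of
  &#946;<sub>magnitude</sub> > 0 per fingertip.
* **Multiple testing**: least-squares estimate of the number of true nulls
  m&#8320;, adaptive step-down FWE (Holm), adaptive step-up FDR, Hommel
  adjustment for ROI-level tests, and Z = &#934;&#8315;&#185;(1 − p)
  conversion.
* **HRF deconvolution**: 13 time-shifted indicator regressors per fingertip
  (response at 0–12 TRs) fitted by OLS.
* **Overlap**: activation masks at FWE- or FDR-adjusted p < &#945;,
  per-voxel counts of activating fingers, exactly-k proportions across Z
  thresholds, and the adjacent-pair overlap ratio
  |A&#8745;B| / ((|A|+|B|)/2), tabulated for anterior ROIs, posterior ROIs
  and the analysis volume posterior to the ROIs.
* **Veins**: unwrap &#8594; high-pass &#8594; threshold &#8594; 2 mm
  spherical dilation of a susceptibility phase volume; activation can be
  stratified by 0.5 mm vein proximity.

## Worked example

```r
library(somatomap)
cfg <- study_config(seed = 42)        # the default synthetic world
res <- run_phantom_study(cfg)         # simulate + localizer + ER + report

res$tables$table1
#   positive_peak_s negative_peak_s voxels_analyzed
# 1            5.99          16.958            5400

res$tables$table2
#   finger n_voxels
#        1      780
#        2      810
#        3      640
#        4      803
#        5      749

print(res$tables$table4, digits = 3)
#      pair anterior_rois posterior_rois posterior_to_rois
# 1   D1&D2          64.5           84.2              81.5
# 2   D2&D3          60.3           81.0              81.1
# 3   D3&D4          60.5           83.1              78.9
# 4   D4&D5          64.7           85.6              82.6
# 5 Average          62.5           83.5              81.1
```

Reading the output: the estimated subject HRF peaks at 5.99 s with its
undershoot minimum at 16.96 s — the curve peaks of the canonical timing the
generator used (the curve minimum of a 16 s undershoot gamma falls at
16.97 s, see the methods vignette); 5400 voxels enter the corrected tests.
The five fingertip ROIs each contain several hundred voxels. The overlap
table shows the package's analogue of the anterior-to-posterior specificity
gradient: adjacent fingertips share ~62% of their activation (Dice, in
percent) in the narrowly tuned anterior compartment versus ~84% in the
broadly tuned posterior compartment — lower anteriorly in every pair, the
qualitative signature the analysis is designed to detect.

A command-line interface mirrors the stages:

```sh
Rscript -e 'somatomap::somatomap_cli()' simulate --out study_dir --seed 1
Rscript -e 'somatomap::somatomap_cli()' all      --out study_dir --seed 1
Rscript -e 'somatomap::somatomap_cli()' veins    --out study_dir
```

writing NIfTI volumes, tab-separated event tables and the four report
tables. A JSON file passed via `--config` overrides any `study_config()`
field.

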