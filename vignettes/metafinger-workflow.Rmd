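---
title: "From ambient-MS fingerprints to a diagnostic marker panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ambient-MS fingerprints to a diagnostic marker panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafinger)
```

## The problem

Ambient ionization mass spectrometry (conductive-polymer spray ionization,
desorption electrospray ionization) produces a metabolic fingerprint of a
clinical specimen — thousands of ion intensities over m/z 50–1,000 — in
seconds, from under a milligram of tissue or a microlitre of serum. Turning
those fingerprints into a diagnostic read-out for, say, triple-negative
breast cancer (TNBC) versus paired adjacent normal tissue (PNT), or TNBC
serum versus healthy donors (HD), requires a chain of statistical steps
that are individually standard but easy to get subtly wrong: mass binning,
normalization, multivariate feature ranking, multiplicity-corrected
univariate screening, metabolite annotation, sparse classifier training
and honest evaluation. `metafinger` implements that chain end to end, with
a synthetic cohort generator so every stage is testable against known
ground truth.

## The processing model

**Scan averaging and binning.** Each sampling point is measured as a short
series of continuous scans (ten by convention); the average spectrum is
built by clustering pooled peaks and dividing cluster totals by the scan
count, so a peak absent from a scan counts as zero. Mass bins are formed
globally by single-linkage clustering of all observed m/z values, starting
a new bin wherever the gap between neighbours exceeds twice the ±0.005 Da
tolerance. The gap rule was chosen over per-reference windows because it
is deterministic and independent of sample order — binning commutes with
shuffling the manifest, which the test suite asserts.

**Normalization and scaling.** Each sample is divided by its average total
ion current (the mean bin intensity; a sum-based divisor is available via
`tic = "sum"`), making fold changes invariant to per-sample signal scale.
The matrix is then `ln(x + ε)`-transformed and each bin is centred and
scaled to unit sample standard deviation (n − 1 denominator, the
conventional autoscaling choice; a two-sample bin therefore scales to
±1/√2, not ±1). ε defaults to half the smallest nonzero intensity — the
smallest offset that leaves observed peaks essentially untouched while
keeping the log defined at zeros, about which the underlying measurement
model is silent.

**PLS-DA and VIP.** Class separation is modelled by single-response PLS
(NIPALS) on the autoscaled matrix with the class coded 0/1 and centred.
Two latent components are the default — score plots are two-dimensional
and the VIP screen is insensitive to adding components that explain little
class variance — and the count is capped at `min(n − 1, p)`. Weight-vector
signs are fixed so the largest-magnitude entry is positive (NIPALS sign
indeterminacy). Variable importance in projection is accumulated over
components, weighted by each component's explained class sum of squares;
`mean(VIP²) = 1` is an algebraic identity the tests assert to 1e-10. The
cumulative form is the standard one; per-component variants exist in
commercial software but are not implemented.

**The marker cascade.** Ions are screened in a fixed order with strict
inequalities: VIP > 1.0, then Benjamini–Hochberg q < 0.05 from two-sided
t-tests, then fold change > 2.0 or < 0.5. The t-test runs on ln-scale
intensities (variance stabilization) while the fold change is the ratio of
linear-scale group means — the two scales answer different questions and
mixing them is deliberate. Welch's unequal-variance form is the default
because group variances are never verified equal; the pooled Student form
is one flag away. Each tissue sampling point is treated as an independent
sample, matching a design that models sampling points rather than
patients; `split_by_patient()` exists for patient-level held-out
evaluation. FDR is applied jointly across polarities by default.

**Annotation.** Candidate identities come from exact-mass matching of
singly charged adducts (positive: [M+H]+, [M+Na]+, [M+K]+, [M−H2O+H]+,
[M+2Na−H]+, [M+2K−H]+, [M+NH4]+; negative: [M−H]−, [M+Na−2H]−, [M+K−2H]−,
[M+Cl]−) within 5 ppm, restricted to metabolites with a reported human
presence, ties broken by the adduct priority order above. Adduct deltas
are computed from monoisotopic element masses with electron-mass
correction, not hard-coded. A first-order isotope-ratio check
(`n_C·0.0107/0.9893 + n_H·0.000115 + n_N·0.00364`) filters implausible
formulas. Without MS/MS fragmentation all identities remain putative; the
bundled table is a small editable TSV, not a live database query.

**The diagnostic panel.** The classifier is a lasso on the 0/1 class with
squared loss — the form built into common numeric environments and the
one whose scores the 0.62 operating threshold refers to — solved by cyclic
coordinate descent to a 1e-8 coefficient tolerance. The inner loop is
compiled (Rcpp): candidate marker panels are strongly correlated (spiked
markers share the group effect, r ≈ 0.95 in simulation), and correlated
designs push coordinate descent to thousands of sweeps at that tolerance.
A logistic variant is intentionally not provided; the squared-loss scores
are what the thresholding convention expects. Penalty selection uses
repeated stratified 9:1 train/held-out splits (ten by default) over a
50-point grid from `λ_max` down to `λ_max/1000`, scoring thresholded-score
accuracy; ties go to the larger penalty, i.e. the sparser panel. Plain
k-fold behaviour can be had by setting `split_ratio` accordingly. ROC
evaluation uses the midrank Mann–Whitney AUC (ties get half credit), a
2,000-replicate stratified bootstrap percentile CI, and the Youden-optimal
cut-off (ties resolved toward specificity) reported separately from the
fixed operating threshold, which is stored on the model as a given
constant.

**Serum tracking and quantitation.** The serum screen reuses the tissue
cascade verbatim — same thresholds, same code path. A tissue marker is
confirmed in serum when its serum q-value is significant, its direction
matches, and its serum fold change is itself beyond the 2.0/0.5 bounds.
Concentration estimates are single-point ratios against a spiked standard
(`c = c_std · I_sample / I_std` on normalized intensities); no background
subtraction of the endogenous level is attempted because the calibration
as described is a one-level comparison, and both intensities being
TIC-normalized cancels the sample's scale factor.

**Ion images.** Raster line scans map to pixels by line index and
`floor(t · v / w)` with the along-track pixel width defaulting to the
0.2 mm line spacing (square pixels at 0.2 mm/s and 1 scan/s; the true
scan rate during imaging is configurable because acquisition firmware
rarely reports it in exported peak lists). Pixel intensity is the summed
in-window signal, collisions average, unvisited pixels stay zero, and the
mass window is absolute (0.01 Da default) as is usual at imaging
resolution. The generator places scan times at pixel centres, so the
zero-noise round trip is exact — a property test, not a coincidence.

## What the synthetic generator does and does not emulate

`cohort_design()` defaults encode the study conditions the pipeline is
meant for: 40 patients × paired TNBC/PNT × 3 sampling points (240 tissue
points), 242 + 139 serum samples in alternating acquisition order, pooled
QC injections every 30 runs, 2,000 ions over m/z 50–1,000, and 30 spiked
markers at fourfold up- or down-regulation. Baseline abundances are
log-normal over three decades (metabolite classes span that dynamic
range); noise is multiplicative log-normal per scan (sd 0.25), per-sample
TIC factors have a 20% coefficient of variation, patients carry a shared
log-scale offset (sd 0.1), and a mild multiplicative drift
(1.0005 per run) accumulates with run order. Ion positions sit on a
0.025 Da grid with m/z jitter bounded at ±0.004 Da, so a true ion never
escapes its ±0.005 Da bin — bin identity is exact by construction. Where
the underlying intensity noise of ambient-MS fingerprints has not been
characterized, log-normal is a modelling assumption, not an empirical fit.

Not emulated: spray-stability excursions, in-source fragmentation,
correlated adduct/chimera structure between ions, batch changeovers, or
peak-shape effects (inputs are centroided by assumption). Passing tests
therefore demonstrate that the statistics do what they claim under a
clean multiplicative error model — they do not certify performance on
real instrument data, where annotation ambiguity and drift correction
dominate.

QC records are deterministic pooled profiles — the equal-volume mix of
the two group means, (1 + FC)/2 per marker ion — subject to drift only.
That makes the QC relative-standard-deviation report a pure read-out of
injected drift, which is what a pooled QC is for.

## Reproducibility and problem sizes

A single root seed fans out to named substreams (ion positions, baselines,
patients, samples, CV splits, bootstrap), so each simulated sample is
reproducible independently of generation order; identical seeds give
bit-identical cohorts, and the disk round trip of a peak matrix preserves
doubles exactly (17 significant digits plus a JSON sidecar).

The test suite exercises the full simulate → average → bin → normalize →
cascade → panel path at 60 + 60 samples × 2,000 ions with 3 scans per
sample, where the cascade recovers all 30 spiked markers with zero null
pass-through and the cross-validated panel is pure; the FDR-control check
runs 50 global-null replicates at 2,000 ions × 30 + 30 samples; the
permutation-null check runs 25 repeats of penalty selection on 60 × 10
data. These sizes were chosen as the smallest at which the statistical
claims are sharp (marker recovery saturates, null behaviour is stable
across replicates).

## Known limitations

* Annotation is exact-mass + isotope-ratio only; isomers are
  indistinguishable and all identifications are putative.
* The squared-loss lasso score is not a calibrated probability; the
  operating threshold is a convention carried with the model, not an
  estimate.
* The repeated-split penalty selection reports an accuracy that is
  selected over the grid and therefore optimistically biased by a few
  points under the null — the permutation test quantifies exactly this.
* No batch-effect correction is applied; drift is reported (Spearman
  correlation of QC bins with run order), not removed.
* Profile-mode data must be centroided upstream; mzML reading requires
  the optional mzR package, and the two-column CSV dialect is the
  reference input format. The package's functions are its interface; the
  acceptance script under `scripts/` is the scripted entry point.
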