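---
title: "Methods and design notes for idnano"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for idnano}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idnano)
```

This vignette is the package's account of its science: what each stage
computes, the assumptions behind it, which knobs matter, what the synthetic
data do and do not emulate, and the numerical choices that were genuinely
open.

## Optical-mapping conduction velocity

**Model.** A paced atrial beat sweeps a depolarization front across the
mapped field. The optical action potential at a pixel is a fast upstroke
(dye fluorescence falls on depolarization for di-4-ANEPPS-like dyes, so a
polarity flag of −1 is the default) followed by repolarization. Activation
time is defined as the time of the maximum first temporal derivative of the
polarity-corrected trace.

**Procedure.** Each trace is smoothed with a 5-point quadratic
(Savitzky–Golay) kernel — chosen because it preserves the position of the
dF/dt peak, unlike a moving average — and differentiated by central
differences. The derivative peak is localized to sub-frame precision with a
3-point parabola, which matters because 1 ms frames are coarse relative to
the precision of interest. Pixels are masked when the deflection amplitude
divided by the estimated noise SD falls below `snr_min` (default 5). The
residual of smoothing understates the noise by a known factor
(`1 − 2k₀ + Σk²` for the kernel weights), which is corrected so that the
SNR statistic is calibrated: pure-noise traces score ≈ 3–4 and are excluded
at the default threshold.

All unmasked activation times are then fitted, by least squares, to a
single global quadratic surface T(x, y) with x, y in mm (pixel centres,
origin top-left, x along columns) and T in ms. A windowed local-fit mode
would be a natural variant, but a single global fit is the default; the fit
degrades gracefully into a plane when the front is planar. The slowness
field is the analytic gradient of the fitted surface; velocity is
v = ∇T/|∇T|² (direction of propagation, magnitude 1/|∇T|), reported in
cm/s. Pixels with |∇T| below 10⁻³ ms/mm (near-simultaneous activation,
i.e. unphysically fast apparent propagation) are excluded and counted.

**Fast axis.** The fast axis is found by binning vector directions in 5°
bins and taking the bin of maximum mean speed, ties broken toward the bin
with more vectors; CV is the mean speed of vectors within ±15° of that
axis. At least 10 vectors are required in the wedge, otherwise the
estimate fails explicitly.

**Accuracy.** On noiseless planar waves the pipeline is exact to better
than 0.5%. On curved fronts the global quadratic is an approximation: for
the elliptical-wave generator (remote point stimulus, anisotropy 2:1) the
bias is about +2.5%, well within the ±5% recovery band used in testing.
The `"quadratic"` wave geometry generates a curved front whose
activation-time field is exactly quadratic (the paraxial limit of a
distant stimulus); on it the fitted gradient matches the analytic slowness
to better than 2% pixelwise, isolating detection error from fit-truncation
error.

## ECG P-wave and arrhythmia burden

**Beat detection.** The trace is band-passed (10–100 Hz, zero-phase
Butterworth) and peaks are taken above a locally adaptive threshold (45%
of the local envelope maximum was too strict next to large QRS complexes;
30% with a floor of 4 robust noise SDs detects the smaller atrial
deflections during arrhythmia while rejecting P and T waves) with a 40 ms
refractory period.

**P-wave duration.** Sinus beats (flanking intervals within 15% of the
median) are signal-averaged over a window preceding the R peak; the
isoelectric baseline and its SD come from the TP segment at the window
start; onset and offset are the crossings of baseline ± 2 SD around the P
peak, refined by linear interpolation between samples. Averaging ≥ 10
beats shrinks the baseline SD by √n, so the threshold bias on the measured
width is small and, importantly, nearly equal for different P durations —
the 12 vs 16 ms contrast is recovered as 4 ± 1 ms.

**Episodes and burden.** After the annotated end of the pacing train,
inter-deflection intervals are scanned. An episode is a maximal run whose
rolling mean interval (window 10) is shorter than the sinus interval
divided by 1.2, trimmed of sinus-scale edge intervals, that lasts ≥ 1 s
and whose interval coefficient of variation over the run exceeds 0.2. The
run-level CV (rather than a rolling CV) is deliberate: rolling CV in a
10-interval window has enough sampling noise to dip below threshold inside
a genuinely irregular episode and fragment it. The 1 s minimum for
"inducible" is a common rodent AF convention; no threshold is inherited
from elsewhere, and all thresholds are carried in the returned object.
Burden is total episode seconds × 3600 / observation seconds, using the
annotated observation window when present (an in vivo burden is quoted per
hour of total observation, not per post-pacing window).

## SMLM cluster enrichment

**Clustering.** Density-reachability clustering (DBSCAN semantics: a core
point has ≥ `min_pts` neighbours within `eps_nm`, including itself;
clusters are the density-connected sets; the rest is reported unclustered).
Defaults `eps_nm = 50`, `min_pts = 5` — about 2.5× the lateral
localization precision — are configuration values, not claims about any
published tool's internals. Before distance computation z is divided by
the axial/lateral precision ratio (2.5 at the 20/50 nm defaults) so the
neighbourhood is isotropic in precision units; all reported coordinates
and distances are raw nm.

**Proximity.** "Within 100 nm of a cluster" is measured from a target
molecule to the nearest *member molecule* of any reference cluster —
clusters are extended objects and shells grow from their edges, not their
centroids. The implementation is oracle-checked against O(n²) brute force.

**Enrichment ratio.** The ID region is defined reproducibly as the 3D
convex hull of all localizations (avoiding any manual ROI). The shell is
the union of 100 nm dilations of the reference clusters clipped to that
hull; its volume is estimated by seeded Monte-Carlo over the hull
(default 10⁵ accepted samples, relative SE < 1%). The ratio is
(targets in shell / shell volume) ÷ (targets outside / complement volume);
a zero outside-density is flagged `NA`, never reported as infinity. On
homogeneous Poisson input the ratio is 1 within sampling error (the hull
shaves corners of the field, worth about +5% at the default geometry —
inside the ±10% band used for the control).

**Histograms.** Each target cluster contributes one count at (centroid-to-
nearest-reference-edge distance, density or count or mass); totals equal
the number of in-range clusters and the distance marginal reproduces an
independently computed 1D histogram.

## OBS3D volumetric analysis

Intensities are normalized per channel per image to the channel maximum;
voxels ≥ `threshold_frac` (default 0.5 — the conventional full-width
half-max criterion for deconvolved data) are labeled as 26-connected
components; objects below 8 voxels are discarded as single-voxel-scale
noise at 25–50 nm sampling. Cluster mass is the normalized intensity
summed over the object. Two equivalent-sounding definitions circulate for
such masses ("volume × normalized intensity" vs "summed normalized
intensity"); they coincide when the first uses the object's mean
intensity, and the summed form is what is implemented. Mass is exactly
invariant to global intensity scaling; volume is invariant at fixed
threshold fraction. Near/far assignment for the mass enrichment ratio is
by whole object (centroid within 100 nm of the nearest reference voxel,
physical nm with anisotropic voxels): a cluster's mass is never split
across the boundary.

## TEM intermembrane distance

Distances are measured from trace A (first listed) to trace B: `n_samples`
points (default 120, comfortably above 100 measurements per micrograph)
are placed at equal arclength along A and the point-to-segment minimum
distance to B is recorded. Equal-arclength placement is a convention
chosen here; nothing in the source material prescribes the sampling rule.
Crossing traces are rejected with the crossing location. The measure is
directed (Hausdorff-like); for near-parallel membranes A→B and B→A agree
within sampling resolution. Pooling per site concatenates the raw samples,
so the pooled SE equals the direct computation on the concatenated data.

## Statistical decision tree

Continuous data pass through a Shapiro–Wilk gate at α = 0.05 per group
(groups with n < 3 cannot be tested and fail the gate, with a warning).
Gate passed: unpaired data go to single-factor ANOVA, paired data to the
Wilcoxon signed-rank test. Gate failed: Kruskal–Wallis (unpaired) or
Friedman (paired). Nominal data always go to Fisher's exact test
(two-sided, by summing hypergeometric probabilities ≤ the observed
table's; a zero margin returns p = 1, matched exactly against full
enumeration in the tests). The placement of a nonparametric paired test in
the normality-passed branch reproduces the source protocol as written; it
is unusual, so `parametric_paired = TRUE` switches to a paired t-test.
Multiplicity is handled as an adjusted alpha α' = 1 − (1 − α)^(1/m)
(not adjusted p values), which is decreasing in m and equals α/m to first
order. All tests are two-sided. Type-I error of every branch is verified
by simulation to sit in the 5 ± 2% band at nominal α = 0.05 (discrete
nonparametric tests are conservative at small n; the simulations use
n = 20 per group for the paired branches so the achievable levels are
close to nominal).

## The synthetic-data module

The generators encode the study conditions as defaults: optical maps at
1000 frames/s and 100 µm pixels with a logistic upstroke of 2 ms 10–90%
rise time (a murine atrial optical AP shape with a sharp derivative peak);
ECG at 1 kHz with a 450 bpm sinus rate (leaving a clean TP segment between
the previous T wave and the next P wave), 12 ms P waves and 40 ms PR;
localization scenes in a 3000 × 1500 × 400 nm ID volume with 20/50 nm
lateral/axial jitter and control-like fractions (59% of NaV1.5 within
100 nm of Cx43, 35% within N-cadherin shells); membrane pairs at 17/64 nm
(GJ-adjacent control/edema-like) and 27/63 nm (MJ-adjacent) spacings.
Where the conditions gave no value (optical SNR is never reported for such
recordings) a default of 20 was fixed once as representative of a good
preparation, and recovery is additionally exercised across an SNR grid.

Design points worth knowing:

- **Determinism.** Every generator routes randomness through one locally
  seeded RNG: same seed + preset gives bit-identical output, and the
  session RNG stream is untouched.
- **Controlled fractions are exact in the observed table.** Target
  molecules are drawn from a three-component mixture (GJ shell, MJ shell,
  elsewhere) with multinomial counts; localization jitter is applied
  during placement with a rejection step, so a molecule labeled "within
  the GJ shell" *is* within 100 nm of a reference localization in the
  emitted coordinates. Without the rejection step, jitter at the 20/50 nm
  scale would shuttle boundary molecules across the 100 nm shell and the
  preset fraction would no longer be the truth of the observable data.
  The per-molecule labels in the ground truth are therefore the exact
  geometric truth, and an independent brute-force count reproduces them.
- **Localizations are confined to the ID volume.** Jitter that would
  carry a molecule outside the field box is redrawn. This keeps the
  convex-hull ID region of the analysis consistent with the box geometry
  the ground-truth volumes refer to; without it the hull balloons past
  the box and biases density ratios upward by tens of percent.
- **Reference geometry.** GJ and MJ clusters are compact blobs placed on
  disjoint halves of the field with shell-width clearance, so "near GJ"
  and "near MJ" labels cannot be ambiguous.
- **Arrhythmia episodes.** Within an episode, atrial deflections run at
  twice the sinus rate with gamma-jittered intervals (CV 0.5) floored at
  a 50 ms atrial refractory period, and are anchored at both episode
  endpoints, so the nominal episode interval is exactly the span of the
  irregular activity. The refractory floor also keeps deflection spacing
  above the detector's 40 ms refractory, which is physiologically
  sensible and avoids undetectable doublets.
- **Rendering.** Voxel rendering integrates an anisotropic Gaussian over
  each voxel (per-axis normal CDF differences), so each interior molecule
  deposits unit intensity and totals are conserved to < 1%.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: no cable or monodomain electrophysiology (wave
kinematics are prescribed, not simulated), no fibrillatory re-entry, no
camera-specific noise or photobleaching, no drift or channel
mis-registration in localization data, no labeling inefficiency or
multiple blinking of fluorophores, no membrane segmentation from raw
micrographs. Recovery results certify the measurement chain, not the
biology upstream of it.

## Numerical choices and degenerate inputs

- Convex hulls, hull volumes and point-in-hull tests use an internal
  quickhull with a tolerance of 10⁻⁹ × the coordinate range; affinely
  degenerate clouds are reported as such (volume 0) rather than fitted.
  Clusters with fewer than 4 points carry volume 0 and undefined density
  and are excluded from density-based summaries.
- Sub-frame/sub-sample refinements (activation peaks, P-wave bounds) are
  3-point parabolic or linear interpolations, clamped to half a
  sample/frame so outliers cannot overshoot.
- Undefined ratios (zero outside-density, zero far mass, zero targets)
  return `NA` with a warning; they are never coerced to 0 or infinity.
- Empty inputs return empty, valid objects (empty cluster sets, all-zero
  renderings, empty reports); errors are reserved for contract violations
  (crossing membranes, rank-deficient fits, missing annotations).

## Problem sizes

The shipped tests and the acceptance script run, per invocation: 32 × 32
optical maps (about 60–90 frames) with 20 seeds per CV preset; 10⁴-molecule
point clouds with 10 + 10 reference clusters (20 seeds per fraction preset
in the test suite, 5 in the script); 10⁵ Monte-Carlo samples per
enrichment ratio; 8–60 s ECG traces; 120-sample membrane profiles; and
1000-replicate null simulations per statistical branch. These sizes keep
every stated recovery band stable across seeds while the whole suite runs
in a few minutes.

## Known limitations

- The global quadratic surface biases CV slightly upward on strongly
  curved fronts; a windowed local fit would remove this at the cost of a
  window-size parameter.
- The fast-axis search uses fixed 5° bins; with very few vectors the
  binned maximum is noisy (the estimator then errs toward requiring more
  data rather than guessing).
- The Monte-Carlo shell volume inherits the convex-hull ID definition; for
  strongly non-convex IDs (real en-face disks are roughly planar but
  irregular) the complement volume is overestimated and ratios are
  conservative.
- P-wave onset/offset by threshold crossing is biased low at poor SNR;
  the bias largely cancels in contrasts between conditions, which is what
  the downstream statistics consume.
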