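# idnano

Quantitative analysis of acute atrial conduction slowing and
intercalated-disk (ID) nanodomain remodeling, of the kind used to study how
inflammatory vascular leak (e.g. VEGF-induced edema) predisposes otherwise
normal hearts to atrial arrhythmias. The package is aimed at cardiac
electrophysiology and super-resolution imaging labs that need a tested,
scriptable version of this measurement chain:

- **Optical-mapping conduction velocity (CV).** Per-pixel activation time is
  the time of maximum dF/dt of the optical action potential (with sub-frame
  parabolic interpolation); activation times are fitted to a parabolic
  surface T(x, y) = a x² + b y² + c xy + d x + e y + f; the slowness field
  s = ∇T (ms/mm) is inverted to velocity v = s/|s|² (cm/s) and CV is the
  mean speed of vectors within ±15° of the fast axis of propagation.
- **ECG metrics.** P-wave duration from signal-averaged beats (onset/offset
  at baseline ± 2 SD crossings around the P deflection), and post-burst-
  pacing atrial arrhythmia calls: an episode is a ≥ 1 s run of
  inter-deflection intervals at > 1.2× the sinus rate with interval
  coefficient of variation > 0.2; burden is episode seconds per hour of
  observation.
- **SMLM (STORM-style) cluster enrichment.** Density-reachability clustering
  of 3D localization tables; percentage of target signal (NaV1.5, β1)
  within 100 nm of reference clusters (Cx43 gap junctions, N-cadherin
  mechanical junctions), measured to the cluster edge; density enrichment
  ratio = density inside the 100 nm shell ÷ density elsewhere in the ID
  (shell volumes by seeded Monte-Carlo over the convex hull of all
  localizations); bivariate cluster density/mass vs distance histograms.
- **OBS3D volumetric analysis.** 3D object segmentation of deconvolved
  stacks at half-max threshold, 26-connected components, cluster mass =
  normalized intensity summed over the object, and near/far (100 nm) mass
  enrichment ratios.
- **TEM ultrastructure.** Intermembrane distance profiles from digitized
  membrane trace pairs (equal-arclength sampling, point-to-segment
  distances), pooled per ID site.
- **Statistics.** The study's decision tree: Shapiro-Wilk normality gate,
  one-way ANOVA / Wilcoxon signed-rank on the normal branch,
  Kruskal-Wallis / Friedman otherwise, Fisher's exact test for nominal
  data, and the Šidák correction applied as an adjusted alpha,
  α' = 1 − (1 − α)^(1/m).

Because no raw data are deposited for studies of this kind, the package
ships a first-class **synthetic-data module**: propagating atrial action-
potential waves with set CV/anisotropy/SNR, murine ECG with parameterized
P-wave duration and insertable irregular episodes, three-channel ID point
clouds with controlled fractions of target signal within 100 nm of
reference clusters (and controlled density ratios), PSF-blurred voxel
renderings, and membrane trace pairs with analytic gap profiles. Every
generator returns the ground truth alongside the data, so the entire
pipeline is testable end to end.

## Worked example

```r
library(idnano)

# --- conduction velocity from a synthetic optical map (control-like: 21 cm/s)
g  <- gen_voltage_map(wave_preset(cv_cm_per_s = 21, snr = 20,
                                  geometry = "elliptical"), seed = 1)
map_conduction_velocity(g$map)
#> <cv_estimate> CV = 21.55 cm/s along 2.5 deg (+/-15 deg wedge, 281/1024 vectors)

# --- ID point cloud: % of NaV1.5 within 100 nm of Cx43 clusters
cloud <- gen_id_point_cloud(id_cloud_preset(), seed = 1)   # 59% / 35% preset
gj  <- cluster_localizations(cloud$table, "Cx43")
gj
#> <cluster_set> channel Cx43: 7 clusters from 500 localizations (37 unclustered); eps 50 nm, min_pts 5
nav <- cloud$table[cloud$table$channel == "NaV1.5", ]
fraction_within(nav, gj)        # 56.8 (ground truth of this draw: 57.9)

# --- TEM: VEGF-like intermembrane spacing
pair <- gen_membrane_pair(membrane_preset(mean_gap_nm = 64,
                                          gap_waviness_nm = 5), seed = 1)
intermembrane_distance(pair$pair)
#> <distance_profile> GJ-adjacent: 63.98 +/- 0.32 nm (mean +/- SE, n = 120)

# --- the statistical decision tree on a CV-style contrast
set.seed(1)
compare_groups(list(control = rnorm(10, 21, 1), vegf = rnorm(10, 10, 0.5)))
#> <group_comparison> one-way ANOVA: p = 2.156e-18 (alpha 0.05) -> significant; normality gate passed
```

The first number is the fast-axis CV in cm/s (the preset was 21); the
fraction is the percentage of ID-localized NaV1.5 within the 100 nm
perinexal shell around Cx43 clusters (preset 59%, realized 57.9% in this
draw); the distance profile is the mean ± SE intermembrane gap over 120
equal-arclength samples (preset 64 nm).

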