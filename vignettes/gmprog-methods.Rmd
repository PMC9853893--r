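---
title: "Methods: progressive grey-matter atrophy on the cortical skeleton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: progressive grey-matter atrophy on the cortical skeleton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the synthetic-data
generator, the numerical choices, and the limitations of `gmprog`. It is
the design record of the package; the README shows a worked run.

## Study design and measurement model

The pipeline targets a two-group, two-timepoint morphometry design:
healthy controls (HC) with one scan each and patients (AD) with paired
scans one year apart. Inputs are modulated, spatially normalized
grey-matter volume (GMV) maps — segmentation outputs scaled by the
Jacobian of the normalization so values preserve local tissue volume —
on one common grid. No resampling is implemented: volumes on mismatched
grids are a hard error, because silently resampling morphometry maps
changes their volume interpretation. Voxel indices are 1-based
throughout, the R convention.

GMV is measured on the **cortical skeleton**: the mean GM map over *all*
scans (HC + AD-T1 + AD-T2) is reduced to a one-voxel-thick medial
surface, and every subject's map is sampled at those voxels in a fixed
(sorted linear index) order. Sampling at the centre of the cortical
plate reduces partial-volume contamination and inter-subject
misalignment relative to whole-map voxelwise testing.

### Skeletonization

A voxel belongs to the skeleton when (i) the raw mean map exceeds
`gm_threshold` and (ii) it is a local maximum of the Gaussian-smoothed
mean map along the direction of strongest negative curvature — the unit
eigenvector of the local Hessian (central finite differences) belonging
to its most negative eigenvalue, with the comparison values obtained by
trilinear interpolation one voxel away on either side. On a plate-like
structure this direction is the through-thickness axis, so the criterion
selects the medial surface of the plate ("centre of the cortical
plate" semantics). Defaults: `gm_threshold = 0.2` and
`smoothing_sigma_mm = 2` — the customary grey-matter inclusion threshold
and a smoothing kernel matched to the default 2 mm voxels. A
`method = "thinning"` fallback applies the same ridge criterion to a
city-block chamfer distance transform of the thresholded mask (a
classical medial-axis construction) for maps whose intensity profile
carries no through-thickness gradient.

Per-subject values are sampled **directly** at skeleton voxels. The
alternative — projecting each subject's local maximum onto the skeleton
along the thickness direction, as tract-based skeleton pipelines do for
FA maps — is deliberately not implemented: the projection search rules
are underdetermined for GM maps, and direct sampling keeps the
measurement linear in the input (the skeleton samples of the mean map
equal the mean of the per-subject samples, a property the tests
exploit).

### Voxelwise statistics and regions

Group maps use the pooled-variance Student *t* (the convention of SPM-
style mass-univariate morphometry); the paired map tests within-subject
differences T2 − T1. Voxels with zero variance yield p = 1 with a
logged count rather than NaN, so downstream thresholding needs no
special cases. Two-tailed p values are adjusted with Benjamini–Hochberg
(`stats::p.adjust`); thresholding adjusted values at α reproduces the
classic step-up rejection set exactly, which the tests verify against a
brute-force step-up oracle on short p-vectors.

Significant voxels are grouped by 26-connectivity (corner-touching
voxels connect; the field rarely states its convention, and 26 is the
more inclusive choice) and clusters of ≤ `min_cluster_voxels` voxels are
dropped. The default 30 is read strictly: surviving clusters have at
least 31 voxels.

Three region categories are derived:

* **overlapped** — voxels significantly decreased in *both* AD-T1 vs HC
  and AD-T2 vs HC (intersection of thresholded decrease maps), then
  cluster-filtered: deficits present at both timepoints.
* **continuing** — by default (`rule = "worsening"`): voxels
  significantly decreased in AD-T2 vs HC *and* significantly declining
  in the paired map, minus voxels already labelled overlapped. The
  phrase "continuing decrease" is genuinely ambiguous in this
  literature; the alternative reading — significant at T2 but not at T1
  — is available as `rule = "t2_only"`. The default operationalizes "a
  deficit relative to controls that keeps worsening", which matches the
  reported property that such areas differ in all three group
  comparisons.
* **progressive** — clusters of the paired map (within-patient decline
  over the year).

The categories overlap by construction (a continuing voxel is also
paired-significant); `combine_region_sets()` produces a single label
image with precedence overlapped > continuing > progressive, in which
the categories are mutually disjoint. For downstream stages the
overlapped and continuing areas each enter as one seed (union of their
clusters), and progressive clusters enter individually; on synthetic
cohorts, progressive clusters are named after the planted region they
best overlap (Dice on the skeleton), a ground-truth lookup that stands
in for atlas labelling, which is out of scope.

### Brain–behaviour, SCN, cross-lagged effects, classification

Regional change scores are complete-case: MoCA change is missing unless
the score exists at both timepoints (the emulated design has 38 of 40
patients complete). Pearson r with a two-tailed p from the *t*
transform at n − 2 df; the tests check this p against a permutation p
on small samples.

An SCN edge is the across-subject Pearson correlation between two
regions' mean GMVs within one group. Group differences are tested by
permutation exactly as described in the source procedure: subjects
pooled, labels reassigned preserving group sizes, r_A − r_B recomputed
per permutation (default 10,000); the observed difference is
significant when outside the central 95% of the null, and an add-one
p value `(1 + #{|null| ≥ |obs|}) / (n_perm + 1)` is reported (unbiased,
never zero). **Caveat**: when the two regions also differ in *mean*
between groups, pooling raw values makes permuted pseudo-groups
mixtures, which induces positive correlation in both and concentrates
the null differences near zero — the test is then anti-conservative for
such edges. This is a property of the published scheme itself, not of
the implementation; calibration is therefore verified on cohorts
without mean differences, and edge results between strongly atrophic
regions should be read with this in mind.

The "causal SCN" is under-specified in its source: Granger causality
needs time series, but only two timepoints exist. The minimal
well-defined reading implemented here is the standard two-wave
cross-lagged coefficient — the standardized coefficient of x(T1) in
y(T2) ~ y(T1) + x(T1) across paired patients (only they have two
timepoints) — and the "10,000 permutations … compared with zeros" is
read as a subject-level bootstrap: resample subjects with replacement,
recompute the coefficient, report the distribution mean, central 95%
interval, and p = 2·min(frac ≤ 0, frac ≥ 0) in add-one form. Label
permutation is not meaningful here (there is no second group in the
regression), which is why the bootstrap reading was chosen; it is
isolated behind this module's interface.

Classification uses a linear SVM (cost C = 1, the LIBSVM default; the
source names no parameters) on exactly five features: mean GMV in the
overlapped areas, continuing areas, left STG, right STG, left caudate.
Leave-one-out cross-validation standardizes features on training rows
only (leakage-safe). For the within-subject AD-T1 vs AD-T2 contrast the
fold unit is the *subject* — both scans held out together — because
scan-level holdout leaks the twin scan's subject offset into training;
whether the original analysis did this is unstated, so the leakage-safe
variant is the default and scan-level folds remain available
(`paired = FALSE`).

Demographic tables are tested as published tables are: sex by 2×2
chi-squared with Yates continuity correction, continuous scores by
two-tailed Welch *t* (also computable directly from printed mean/SD/n
via `welch_from_summary()`, which is how the package reproduces
published p values of 0.81 and 0.49 from the demographics table).
Voxelwise maps deliberately use the pooled *t* while demographics use
Welch: the former is the morphometry convention, the latter is what
published demographic tables report.

## The synthetic cohort generator

The generator is a first-class module: its defaults *are* the study
conditions, and all downstream guarantees are statements about data it
produces.

**Geometry.** Default grid 48×48×24 voxels at 2 mm (a slab large enough
to skeletonize, small enough for seconds-scale runs; the ~1 mm
acquisition grid of real studies is not emulated). The background is a
"cortical slab": 5 voxels thick in z with a parabolic through-thickness
profile peaking at the medial plane, so the true skeleton is known
analytically and skeleton accuracy is testable. Five spherical regions
(radius 4 voxels, scaled down with the grid) sit on the medial plane:
`overlapped`, `continuing`, `STG_left`, `STG_right`, `caudate_left`.

**Intensity model.** At the medial plane, within region *r* for subject
*s* at timepoint *t*:

value = A·(1 − δ_{r,t}) + λ_{g,r}·f_s + b_{s,r} − [t = T2]·c_r·u_{s,r}

with A = 0.8 the region amplitude over the 0.4 slab, δ the planted
fractional atrophy (AD only), f_s ~ N(0,1) a per-subject factor whose
group-specific loadings λ plant inter-regional covariance, b_{s,r} a
subject×region intercept shared across timepoints (this is what makes
paired contrasts powerful — the pairing assumption), and c_r·u_{s,r} a
subject-specific extra T2 atrophy in progressive regions. Off-plane
values follow the slab profile; i.i.d. N(0, 0.06) voxel noise is added
everywhere and values clip at zero (modulated maps are non-negative;
on the slab the clip is never active in practice).

Default deltas (δ_T1, δ_T2): overlapped (0.25, 0.28) — present at both
timepoints, little further change; continuing (0.02, 0.18) — intact at
T1, clearly deficient and declining by T2; progressive regions
(0.02, 0.17) with intercept SD 0.20 and progression SD 0.05, so their
cross-sectional effect is diluted by between-subject variability while
the within-subject paired contrast remains strong (per-voxel paired
Cohen's d ≥ 1.2) — the classic longitudinal-design scenario. These
choices give each planted region a detection route matching its
category and put the feature-level separations in a regime where
patient-vs-control discrimination is near ceiling while T1-vs-T2
discrimination is genuinely hard, the published qualitative pattern.

**Planted covariance edge.** HC loadings λ = 0.31 on `STG_right` and
`caudate_left` (zero elsewhere, zero in AD) give an implied HC edge
correlation λ²/(λ² + σ_b²) ≈ 0.7 against ≈ 0 in AD on exactly one
edge; all other edges have equal (null) structure in both groups.

**Progression and behaviour.** The progression severity of
`STG_right`/`caudate_left` is one shared latent u; `STG_left` (and
`continuing`, c = 0.03) progress under their own latents. Every
progression latent is partially driven by the subject's *baseline*
overlapped-region intercept (coupling φ = 0.6, i.e. worse baseline
atrophy → faster decline), which plants the cross-lagged effect of
overlapped-at-T1 on each target's change. MoCA change is
−2.07 + 3.25·(ρ·(−u) + √(1−ρ²)·η) with ρ = `behavior_coupling` = 0.44,
so GMV change in the shared-latent regions correlates with MoCA change
at ≈ ρ (attenuated by ~3–5% by measurement noise and score rounding,
which the recovery tolerance absorbs), while `STG_left`'s correlation
is only ρ·φ² ≈ 0.16 — weak and typically non-significant, mirroring
the published asymmetry between the three progressive regions.

**Phenotypes.** Ages and CDR are exact inverse-CDF truncated normals at
the published group means/SDs/ranges; MMSE and MoCA are integer scores
from normals clamped to their observed ranges — clamping (rather than
rejection truncation) models the floor/ceiling behaviour of bounded
instruments and keeps sample means at their targets (rejection
truncation at the 30-point MMSE ceiling would shift the HC mean from
29.13 to ~28.6). Follow-up scores are baseline plus a modelled change,
keeping within-subject trajectories coherent. Sex counts are fixed
(22/18 AD, 27/18 HC — which is what makes the chi-squared p of 0.81
reproducible by construction). MoCA is missing at T2 for 2 of 40
patients and for 2 of 45 controls, matching the reported completion
counts; missingness is unrelated to any latent (MCAR). MMSE/MoCA/CDR
are conditionally independent given group and the progression latent;
their mutual correlation structure is not reported in this literature
and is deliberately not invented.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: anatomical geometry (a slab with
spherical regions, not a folded cortex), scanner and site effects,
segmentation/registration error, spatially correlated noise,
age/sex/TIV confounding (absent by construction, and accordingly no
covariates appear in the models), and attrition mechanisms other than
MCAR. The pipeline's *statistical* behaviour (calibration, power,
recovery, leakage-safety) is what the synthetic cohort certifies.

## Numerical choices and problem sizes

* Determinism: every stochastic stage takes an explicit seed
  (`cohort_spec(seed=)`, `seed_covnet`, `seed_causal`), and identical
  configs reproduce results bit-for-bit; permutation draws use label
  reassignment without replacement, bootstrap draws resample subjects
  with replacement.
* Add-one estimators for permutation and bootstrap p values (never
  exactly zero); bootstrap resamples that make the regression
  degenerate are redrawn.
* Zero-variance voxels: p = 1 with a warning count, not NaN.
  Degenerate inputs (empty threshold mask, zero-variance regions,
  collinear predictors at |r| > 0.999) raise classed errors.
* Edge-level multiple testing: none by default (edge tests are
  reported uncorrected, as is conventional for small seed sets);
  `fdr_bh()` can be applied to the edge table by the user.
* Test-suite problem sizes: module tests run the default design on a
  24×24×12 grid (with the cluster-extent threshold scaled to 10, since
  the planted discs hold ~29 skeleton voxels there); acceptance-style
  checks run one full 48×48×24 cohort, 250 null + 200 planted reduced
  cohorts for permutation calibration/power (1,000 permutations each),
  500 reduced simulations for coupling recovery, and 100 null cohorts
  for voxelwise FDR calibration. `scripts/acceptance.R` uses the full
  10,000 permutations/resamples for the single default-cohort run and
  150 reduced cohorts per calibration arm.

## Known limitations

* The skeleton is validated on slab geometry; on convoluted real
  cortex, ridge detection needs the smoothing scale to match plate
  thickness, and the thinness guarantee is empirical, not proven.
* Direct skeleton sampling (no per-subject projection) can be biased
  where a subject's plate centre is displaced from the cohort skeleton.
* The raw-pooling SCN permutation test is anti-conservative for edges
  between regions with large group mean differences (see above).
* The cross-lagged coefficient is a two-wave approximation to causal
  influence; with two timepoints it cannot distinguish directed effects
  from unmodelled common causes.
* CDR is generated as a continuous truncated normal; real CDR takes
  half-point values.
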