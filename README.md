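# gmprog

Progressive grey-matter atrophy analysis on the cortical skeleton.

## What this package is for

Longitudinal voxel-based morphometry (VBM) studies of Alzheimer's disease
ask where grey-matter volume (GMV) is reduced in patients, where the
deficit keeps worsening over time, and how regional decline relates to
cognitive decline. `gmprog` implements that full analysis as a reusable,
tested R pipeline for a two-group, two-timepoint design — healthy
controls (HC) scanned once, patients (AD) scanned at baseline (T1) and
one-year follow-up (T2):

1. **Skeleton-based GMV measurement.** The cohort-mean GM map is reduced
   to a one-voxel-thick medial surface (the *cortical skeleton*, the
   centre of the cortical plate, which alleviates partial-volume
   effects); every subject's modulated GM map is sampled on it.
2. **Voxelwise group statistics.** Two-tailed two-sample *t* maps (AD-T1
   vs HC, AD-T2 vs HC) and a paired *t* map (AD-T2 vs AD-T1), corrected
   with the Benjamini–Hochberg FDR procedure (q < 0.05) and a
   cluster-extent threshold (> 30 voxels, 26-connectivity).
3. **Region derivation.** *Overlapped* decrease areas (significant in
   both cross-sectional maps), *continuing* decrease areas (deficit at
   T2 that also worsens within subjects), and *progressive* regions
   (paired-map clusters).
4. **Brain–behaviour correlation.** Pearson correlation between regional
   GMV change (T2 − T1) and MoCA change across patients, with
   *p* from the *t* transform on *n* − 2 df.
5. **Structural covariance network (SCN).** An edge between regions is
   the across-subject Pearson correlation of their mean GMVs; group
   differences in edge strength are tested by permutation (labels
   reassigned preserving group sizes; significance when the observed
   r_A − r_B falls outside the central 95% of the permutation null).
6. **Cross-lagged ("causal SCN") effects.** For source x and target y,
   the standardized coefficient of x(T1) in the regression
   y(T2) ~ y(T1) + x(T1) — does the source's earlier state explain the
   target's later state beyond the target's own earlier state — with a
   subject-level bootstrap for stability and a two-tailed p against 0.
7. **Classification.** Linear SVM on the five region-group features
   (mean GMV in overlapped areas, continuing areas, left STG, right STG,
   left caudate) under leave-one-out cross-validation, with
   leakage-safe within-fold standardization and subject-level folds for
   the within-subject T1-vs-T2 contrast.

Because real cohorts of this kind (e.g. ADNI scans) cannot ship with a
package, the
first-class `synthetic_cohort` module generates a cohort with the same
design — 45 HC, 40 AD with paired scans, 38 with MoCA at both
timepoints — and *planted ground truth*: atrophy in named regions,
a group-dependent covariance edge, a coupled GMV–MoCA decline, and a
cross-lagged dependence of progression on baseline atrophy. Every stage
of the pipeline is validated by recovering what was planted.

## Worked example

```r
library(gmprog)

cfg <- pipeline_config(spec = cohort_spec(),      # default synthetic cohort
                       n_perm = 2000, n_resamples = 2000)
rep <- run_pipeline(cfg)
print(rep)
#> <gmprog_report> 125 scans, 2319 skeleton voxels
#>   total GMV means (mm^3): HC=9044, ADT1=8918, ADT2=8713
#>   regions: overlapped 1, continuing 1, progressive 4
#>   HC_vs_ADT1: accuracy 100.0%
#>   HC_vs_ADT2: accuracy 100.0%
#>   ADT1_vs_ADT2: accuracy 77.5%

rep$behavior
#>         region         r          p  n df
#> 1     STG_left 0.2249205 0.17457255 38 36
#> 2    STG_right 0.3700310 0.02221532 38 36
#> 3 caudate_left 0.3850444 0.01698011 38 36
```

Reading the output: total skeleton GMV is ordered HC > AD-T1 > AD-T2
(global atrophy that progresses over the year). The overlapped and
continuing areas and all three planted progressive regions are recovered
as clusters. GMV decline in the right STG and left caudate correlates
with MoCA decline (the planted coupling; the left STG deliberately does
not share the cognition-linked progression factor, so its correlation is
weak and non-significant). Discrimination of patients from controls is
near-perfect, while separating the two patient timepoints is much harder
(77.5%) — the expected pattern, since within-patient change over one
year is small relative to patient–control differences.

`summary(rep)` additionally prints the demographic tests (the sex
chi-squared gives p = 0.81 by construction of the fixed 22/18 vs 27/18
sex counts), the SCN edges flagged by the permutation test (the planted
right-STG ↔ left-caudate edge: covarying in HC, decoupled in AD), and
the cross-lagged effects of the overlapped areas at T1 on each target
region at T2. `write_report(rep, dir)` writes the stat maps and label
images as NIfTI plus a JSON/CSV bundle; `write_cohort()` /
`load_cohort()` round-trip the cohort itself through NIfTI + CSV.

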