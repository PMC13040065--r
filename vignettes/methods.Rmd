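---
title: "Methods: fetal brain morphometry, growth standards and the maturation index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fetal brain morphometry, growth standards and the maturation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbgrowth)
```

`fbgrowth` implements a complete desk-scale analysis pipeline for
second-trimester fetal brain growth from 3D segmentation label volumes:
image-derived phenotype (IDP) extraction, fractional-polynomial normative
growth standards, cross-site poolability statistics, and a deconfounded
random-forest maturation index. Because the scan data that motivated these
methods are access-restricted, the package ships a synthetic-data module
(cohort rosters, nested-sphere label phantoms and simulated IDP tables) whose
outputs have analytic or by-construction ground truth. This vignette records
the methodological choices and their rationale.

## Synthetic data: what it is and is not

Three generators cover the three kinds of input the pipeline needs.

**Cohort rosters** (`build_roster`) emit one record per enrolled fetus with
site, sex, exclusion flags and a longitudinal visit schedule (first visit
uniform on 14–18 weeks, subsequent visits five weeks apart with ±1 week
jitter). The generator is count-exact: each exclusion category hits its
configured total exactly, and fetuses outside the "scanned in 18–27 weeks"
quota have their in-window visits removed, emulating missed visits. Rosters
therefore reproduce a published exclusion cascade deterministically while the
identities of excluded fetuses remain random.

**Label phantoms** (`generate_phantom`) are nested digital spheres: a total
brain whose volume follows the reference total-brain-volume (TBV) growth
equation at the requested gestational age (GA), a cortical-plate shell of
fixed 2.5 mm thickness partitioned into five lobes by angular sectors about
the left–right axis, white matter inside, and eight non-overlapping interior
balls for the subcortical structures (the cavum septum sits on the
mid-sagittal plane so it survives hemisphere restriction). The idealisation
is deliberate: there is no gyrification, so every downstream geometric
measure has an analytic oracle — ball volume $\tfrac{4}{3}\pi r^3$, sphere
area $4\pi r^2$, shell depth $R-\rho$, slab and shell thickness. The phantoms
are *not* anatomically realistic and are not meant to be; they exist to
verify the measurement code, not to simulate anatomy.

**IDP tables** (`simulate_idp_table`) produce per-scan rows of all 28 IDPs
with known structure: each IDP is the reference TBV curve scaled by a
constant fraction, with Gaussian noise whose SD follows the reference
log-linear SD curve, plus configurable site, sex and hemisphere offsets in
GA-specific SD units. Three noise modes are provided: `"ga_varying"` (the
realistic default), `"constant"` (a pure random-intercept structure, used
when a homoscedastic estimator such as REML is being validated), and
`"none"` (deterministic, for exact round-trip tests). Because the generating
mean, SD and offsets are known, every downstream statistic — growth
coefficients, site variance fractions, standardised site differences — has a
known target.

## IDP extraction numerics

**Surface area.** Meshing the 0.5 iso-level of a raw binary mask
systematically overestimates the area of curved surfaces: edge-midpoint
vertices trace the staircase, not the underlying sphere (about +9% for
digital balls at the radii used here, independent of resolution). The mask
is therefore pre-smoothed with a small Gaussian (0.8 voxels) before
iso-surfacing, which places vertices at sub-voxel positions; sphere areas are
then within 1% of $4\pi r^2$, comfortably inside the 3% oracle bound. The
iso-surfacer is a marching-tetrahedra scheme (each cube split into six
tetrahedra) with welded vertices, which cannot produce the ambiguous
configurations of classic marching cubes; meshes on closed masks are
guaranteed watertight, and `mesh_euler` verifies topology (2 for a ball, 4
for the two boundaries of a hollow shell — note that a shell's area is the
*sum* of its outer and inner boundary areas).

**Cortical depth.** `depth_map` is an exact anisotropic Euclidean distance
transform (separable lower-envelope-of-parabolas algorithm) of the
total-brain mask, read out at the cortical-plate voxels. Exactness is tested
against brute-force nearest-background search on random masks.

**Cortical thickness.** `thickness_map` marches from each pial boundary
voxel along the trilinearly interpolated gradient of the exterior distance
field (step 0.25 voxels) until the nearest-voxel lookup enters white matter,
then adds a half-voxel pial-side correction. The march inherits the
half-step detection overshoot, so slab oracles are met within half a voxel.
Rays that leave the grid or stall on a gradient ridge return `NA` rather
than a fabricated value; the 10 mm cap truncates runaway rays. On closed
shells the distance-field ridge lies deep inside the white matter, so stalls
are rare; they matter only for open slab geometries with exposed side faces.

**Hemisphere restriction.** In the motivating acquisition only the distal
hemisphere (away from the probe) is reliably measurable. `restrict_to_distal`
demotes proximal structure labels to a generic tissue code instead of
deleting them, so the total-brain mask — and hence TBV and the depth
transform — stays bilateral, while structure-specific measures become
distal-only. The cavum septum, a midline structure, is exempt.

## Growth standards

Mean curves are degree-2 fractional polynomials (powers from
{−2, −1, −0.5, 0, 0.5, 1, 2, 3}, power 0 meaning $\log GA$, a repeated power
$p$ contributing $GA^p$ and $GA^p\log GA$), selected by residual sum of
squares. The SD is log-linear in GA. Fitting is staged: OLS mean fit,
log-SD fit on half-normal-corrected absolute residuals in integer-week bins,
one weighted mean refit with $1/SD(GA)^2$ weights (powers held fixed), and a
final SD refit. A joint GAMLSS-style estimation would also be defensible;
the staged scheme is declared, deterministic and fast.

Two caveats surfaced in testing are worth knowing. First, on a 9-week GA
window several power pairs are nearly collinear, so noisy data may select a
different pair than the generating one while fitting an almost identical
curve; coefficient-level recovery is therefore tested with the generating
powers forced (`fit_fp_mean(..., powers = )`), and the freely selected model
is tested at the curve level. Second, comparing pooled empirical tail
centiles per week against the smoothed centile at the bin-mean GA carries a
small bias from within-bin GA heterogeneity; the agreement bound for tails
is correspondingly looser than for the median.

Outlier exclusion (`exclude_outliers`) is a single pass removing values more
than 4 SD from their integer-week bin mean, all sites pooled; bins with
fewer than 3 rows are skipped with a warning.

## Site comparison

The standardised site difference (SSD) of a site in a 3-week window is the
mean z-score of its scans under the pooled growth standard minus the
window's pooled mean z-score. Note an algebraic consequence validated in the
tests: if one site carrying proportion $p$ of scans is offset by +0.5 SD,
its expected SSD is $0.5(1-p)$, because the pooled reference absorbs the
site's own contribution.

Variance components use `lme4::lmer` with sex and the pooled-model GA terms
as fixed effects and a Gaussian random site intercept, fitted by REML. The
motivating analysis described a nonparametric random-intercept distribution,
which is not reproducibly specified; the Gaussian REML substitute is
declared and validated by simulation. Two details matter for that
validation: REML's between-site variance matches the $n-1$ sample variance
of the injected site effects (not the population variance), and the GA
fixed-effect columns are unit-scaled internally for optimizer conditioning
(which leaves the variance components unchanged).

## Maturation index

Confounds (sex, site, hemisphere) are encoded as demeaned indicator columns
and removed from the standardised features by a single projection,
$\hat X = X - V V^{+} X$, equivalent to simultaneous per-column
residualisation (tested to 1e-8 against `lm`). GA itself is *not* removed:
it is the prediction target. For reporting, `variance_explained` gives the
marginal %VE of a confound and its unique %UVE beyond the other confounds
(the difference of the full and reduced projection energies); the two
coincide when confounds are orthogonal.

The age predictor is a random forest (100 trees, `mtry = ceiling(0.15 * 28)
= 5`) under subject-level 3-fold cross-validation: both scans of a fetus
fall in the same fold, and standardisation means/SDs, confound centering and
projection coefficients are estimated on each training split only and then
applied to its test split — the full preprocessing is inside the CV loop, so
there is no leakage of either fetuses or statistics. Reported metrics are
out-of-fold: MAE in days, Pearson r, ICC(2,1) (two-way absolute-agreement,
single measures) and per-scan brain-age deltas. Feature attribution uses
impurity importance plus held-out permutation importance; SHAP is
deliberately out of scope.

## Problem sizes and determinism

Everything runs on one CPU at desk scale: 160³ label grids (a full 28-IDP
extraction takes a few seconds), simulated tables of ~9,000 scans from 5,000
fetuses (growth fits in under a second, the forest in a few seconds). All
generators and model fits are deterministic given their seed arguments;
geometry is deterministic unconditionally.
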