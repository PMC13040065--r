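# fbgrowth

Normative fetal brain growth standards and a brain maturation index from 3D
segmentation label volumes, for the second trimester (18–27 gestational
weeks).

Automated segmentation of 3D fetal neurosonography produces label volumes
from which scalar image-derived phenotypes (IDPs) can be measured: structure
volumes, cortical plate surface area, distance-transform cortical depth,
gradient-projection cortical thickness, per-lobe summaries and Sylvian
fissure depth — 28 measures per scan. `fbgrowth` implements, end to end:

- **IDP extraction** from label volumes, including the preprocessing steps of
  isotropic resampling, centre cropping, min–max normalisation and
  restriction of structure labels to the distal (probe-far) hemisphere. The
  geometric kernels — an exact anisotropic Euclidean distance transform,
  a watertight marching-tetrahedra iso-surfacer and a gradient ray-marching
  thickness estimator — are implemented in C++ via Rcpp.
- **Normative growth standards**: degree-2 fractional-polynomial mean curves
  with a log-linear SD model, centiles and z-scores, gestational-age-specific
  4-SD outlier exclusion, and empirical-versus-smoothed centile checks.
- **Cross-site poolability**: standardised site differences in three 3-week
  windows against a ±0.5 SD bound, REML random-intercept variance
  components, and leave-one-site-out centile sensitivity.
- **A maturation index**: confound removal by pseudo-inverse projection
  (X̂ = X − VV⁺X), %VE/%UVE confound reporting, and a random-forest
  gestational-age predictor under subject-level 3-fold cross-validation with
  MAE/correlation/ICC metrics and per-scan brain-age deltas.
- **Synthetic data** with known ground truth, since the motivating scan data
  are access-restricted: count-exact cohort rosters with exclusion cascades,
  nested-sphere label phantoms anchored to the published total-brain-volume
  growth equation (every measure has an analytic oracle), and simulated IDP
  tables with configurable site/sex/hemisphere confounds.

See `vignettes/methods.Rmd` for the methodological choices and their
rationale.

## Worked example

```r
library(fbgrowth)

# a synthetic brain at 22 weeks: nested-sphere label phantom
ph <- generate_phantom(phantom_spec(ga_weeks = 22))
ph
#> label_volume 160x160x160, spacing 0.6x0.6x0.6 mm, hemisphere both

idps <- extract_all_idps(ph, meta = list(ga_weeks = 22))
round(unlist(idps[1, c("TBV", "CoPV", "CoPSA", "SFD", "ILT")]), 1)
#>      TBV     CoPV    CoPSA      SFD      ILT
#> 109183.7  25240.9  20558.4      1.3      2.7

# a simulated multi-site longitudinal IDP table (TBV in cm^3) and a
# normative growth standard fitted to it
tab <- simulate_idp_table(sim_table_config(n_fetuses = 1000, seed = 7))
model <- fit_growth_model(tab$ga_weeks, tab$TBV)
model
#> Fractional-polynomial growth model
#>   powers: (-2, 2)
#>   mean:   -227.919195 + 31026.580803*GA^-2 + 0.565584*GA^2
#>   log SD: -0.850638 + 0.157178*GA (exponentiate for SD)
#>   GA domain: [18, 27] weeks, n = 1766

round(predict_centile(model, c(20, 24), p = 0.5), 1)  # median curve, cm^3
#> [1]  75.9 151.7
round(zscore(model, 22, 120), 2)  # a 120 cm^3 brain at 22 weeks
#> [1] 0.74
```

Volumes extracted from label grids are in mm³ (voxel counts × voxel volume);
the simulated tables and the reference TBV equation are in cm³.

## Package layout

- `R/`, `src/` — the package: generators (`cohort.R`, `phantom.R`,
  `simulate_idps.R`), volume IO and preprocessing (`volume.R`), IDP
  extraction (`idp.R` + C++ kernels), growth standards (`fp_model.R`,
  `growth.R`), site comparison (`site.R`), maturation index
  (`maturation.R`).
- `tests/testthat/` — unit, property and oracle tests;
  `test-acceptance.R` holds one block per acceptance criterion.
- `analysis/`, `results/` — the numbered workflow drivers and their outputs.
- `inst/extdata/label_dictionary.json` — the integer label dictionary.
- `vignettes/methods.Rmd` — methods notes.
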