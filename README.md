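# crowdquant

Quantification toolkit for cell-crowding mechanotransduction assays in
breast epithelial cells.

When cells grow past confluence in a confined space, some — notably
high-grade DCIS (ductal carcinoma in situ) models — respond with a
pro-invasive program: mechanosensitive calcium channels such as TRPV4 are
inhibited and relocate to the plasma membrane, intracellular calcium
drops, cell volume shrinks, the cortex stiffens, and motility and
matrix-degrading invasion increase. Testing that chain experimentally
takes half a dozen quantitative assays, each with its own image- or
signal-analysis step. `crowdquant` implements those steps as one tested R
package, for analysts who want the measurements reproducible and for
methodologists who want every estimator verifiable against ground truth.

## What it computes

| Assay | Input | Estimator | Core quantity |
|---|---|---|---|
| Matrix-degradation invasion | gelatin + nuclear-stain images | Otsu dark-class mask + blob detection | invasive cell fraction = invaded / total nuclei |
| Line analysis | 3-channel line profile | half-maximum (FWHM) compartment windows | % protein in plasma membrane / cytosol / nucleus |
| Calcium reporter | Fluo-4 time lapse | pre-treatment baseline + windowed extremum | signed transient amplitude ΔCa |
| Single-cell motility | per-frame detections | greedy linking + weighted LS on msd(τ) = 4Dτ + (vτ)² | diffusivity *D*, directional speed *v* |
| Nanoindentation | force / deflection curves | joint (E, contact point, offset) Hertz fit, F = (4/3)·E/(1−ν²)·√R·δ^3/2 | Young's modulus *E* |
| Confocal volume | z-stack | 3D Otsu + largest component | cell volume (µm³) |
| Statistics layer | tables | fold-change filter, two-rater concordance + Wald CI, Mann-Whitney U, OLS scaling, PEG dose → osmolality | enrichment ranks, sensitivity/specificity, p-values, R² |

Every modality has a synthetic generator (`gen_*`) with known ground
truth, and `run_study()` composes the whole analysis graph on a labelled
condition sweep, deterministically for a given seed.

## Worked example

Simulate a crowded-condition invasion field with 59% true invaders,
quantify it, partition a simulated TRPV4 line profile, and score a
rater-call table with the high-grade-DCIS operating point:

```r
library(crowdquant)

sim  <- gen_invasion_field(n_cells = 100, invasive_fraction = 0.59, seed = 42)
mask <- segment_degradation(sim$gelatin)   # Otsu dark-class degradation mask
pts  <- detect_nuclei(sim$dapi)            # blob detection, sub-pixel centroids
invasive_fraction(mask, pts)
#> <invasion_result> 59 / 102 cells invaded (fraction 0.578)

lp <- gen_line_profile(0.15, 0.55, 0.30, seed = 42)  # PM/cytosol/nucleus truth
analyze_line_profile(lp$profile)
#> <localization_result> PM 14.5% / cytosol 55.5% / nucleus 30.1%

tab <- data.frame(
  roi_id = 1:82,
  grade  = c(rep("DCIS_high", 20),
             rep(c("normal", "benign", "ADH", "DCIS_low",
                   "DCIS_intermediate"), length.out = 62)),
  call   = c(rep("Y", 15), rep("N", 5), rep("N", 61), "Y"))
diagnostic_concordance(tab)
#> <diagnostic_result> sensitivity 0.75+-0.19 (20), specificity 0.98+-0.03 (62)
```

The invasion result reads: 102 nuclei detected (100 simulated, two noise
blobs), 59 on degraded matrix, fraction 0.578 against a truth of 0.59.
The line analysis recovers the 15/55/30 compartment split within a
point or two at default noise. The concordance table — 20 high-grade
ROIs with 15 positive calls, 62 lower-risk ROIs with 61 negative calls —
gives sensitivity 0.75 ± 0.19 and specificity 0.98 ± 0.03 (95% Wald
intervals).

The full synthetic study:

```r
st <- run_study(seed = 1)   # 5 conditions, every assay, ~15 s
st$scaling                  # cross-assay slopes and R²
```

See `vignettes/crowdquant-methods.Rmd` for the models, parameter
defaults, numerical choices and the limits of what the synthetic suite
demonstrates.

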