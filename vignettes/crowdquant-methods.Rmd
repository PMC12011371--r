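---
title: "Methods: models, estimators and design choices in crowdquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in crowdquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdquant)
```

# What the package measures

Cell crowding — growth past confluence in a confined space — can switch
certain breast epithelial cells (notably high-grade DCIS models) into a
pro-invasive state: mechanosensitive calcium channels such as TRPV4 are
inhibited and relocate to the plasma membrane, intracellular calcium falls,
cell volume shrinks, the cortex stiffens, and motility and matrix
degradation rise. `crowdquant` implements the quantification layer of such
a study: each assay modality (degradation fields, line profiles, calcium
traces, trajectories, indentation curves, z-stacks, rater tables) gets a
reader, an estimator and a synthetic generator with known ground truth, so
the whole analysis graph can be validated end to end without raw microscopy
data.

All images use 1-based `(row, col)` coordinates with the row axis pointing
down; physical units are micrometres, minutes, kPa and nN. Intensities are
relative (arbitrary units); every estimator is invariant to positive
rescaling of its input intensities, and nothing beyond the documented
background-subtraction steps models the camera.

# Invasion: masked-points quantification

The invasive cell fraction is the number of nuclei lying on degraded
(dark) gelatin regions divided by all detected nuclei.

* **Degradation mask.** The gelatin channel is smoothed (Gaussian,
  `smoothing_sigma = 2` px) and thresholded by Otsu's method on the
  range-normalized image, dark class = degraded. Range normalization makes
  the threshold — and hence the mask — invariant to affine intensity maps
  `a*I + b`, `a > 0`. Otsu splits *any* histogram, including pure noise, so
  a mask is only accepted when the two classes separate by at least
  `min_contrast = 4` pooled within-class standard deviations; otherwise the
  field is reported degradation-free. Components smaller than
  `min_patch_area_px = 25` px (about one nucleus blob) are removed as
  speckle.
* **Nucleus detection.** At low magnification nuclei are unresolved spots,
  so detection is blob finding, not segmentation: Gaussian smoothing at the
  blob scale (`detection_sigma = 2` px), local maxima above
  `rel_threshold = 0.15` of the image maximum, an exclusion radius
  (`min_separation_px = 5`) enforced greedily by descending intensity, and
  3×3 intensity-weighted centroid refinement. Two blobs closer than the
  exclusion radius deliberately count as one cell.
* **Counting rule.** A nucleus is invaded when its rounded position falls
  on a mask pixel; boundary pixels count as invaded. This makes the
  fraction deterministic and monotone non-decreasing under mask dilation.

The generator draws non-overlapping dark disks (radius 8 px, rejection
sampling with a retry cap), puts each invasive nucleus essentially at its
patch centre, and keeps nuclei at least 12 px apart so the "unbiased count
on non-overlapping nuclei" premise holds. On this design the pipeline
recovers true fractions over `{0, 0.25, 0.5, 0.75, 1}` with mean absolute
error well below 0.01 — real fields, with overlapping nuclei, partial
degradation and uneven illumination, will do worse; the synthetic result
bounds estimator error, not biology.

# Line analysis: compartment percentages

A line crossing one cell samples three channels: the protein of interest,
a membrane dye (double peak where the line crosses the plasma membrane
twice) and a nuclear dye (central plateau). After per-channel background
subtraction (mean of the outer 10% of samples at both line ends, negatives
clipped to zero):

* the two **plasma-membrane windows** are the full-width-at-half-maximum
  (FWHM) intervals of the two dominant membrane-dye peaks, each peak
  handled separately — the standard reading of a half-maximum window. Peaks are the two highest local maxima of a
  5-sample moving average, at least 10% of the line apart, ties broken
  toward the outermost candidates — a line crossing a cell meets the
  membrane at its extremes;
* the **nucleus window** is the nuclear dye's half-maximum interval;
* the **cytosol windows** are the two gaps in between.

The target channel is averaged per compartment — the two membrane windows
pooled at the *sample* level, likewise the two cytosol gaps (pooling
samples rather than averaging window means weights each sample equally) — and each mean is reported as
a percentage of the sum of the three means. Percentages therefore always
sum to 100 and are invariant to rescaling the target channel. No spectral
unmixing is attempted: if the nuclear dye bleeds into the target channel
that bias is carried through, as in the original procedure.

# Calcium traces: baseline and delta-Ca

A trace is the per-frame ROI mean minus a background-ROI mean. The
baseline is the mean of *all* pre-treatment frames (ten frames for the
standard 5-min lead-in at 30-s spacing); the response extremum is the
single-frame minimum (dip), maximum (spike), or larger absolute deviation
(`auto`, for blind batch runs) within `response_window_min = 5` min after
treatment, and `delta_ca = extremum - baseline`, signed. Smoothing before
the extremum search is available (`smooth_frames`) but off by default so a
noise-free step transient is recovered exactly; photobleaching detrending
is likewise opt-in because the traces this models are flat over the
measurement window. The generator uses an instantaneous step with
exponential recovery — the extraction never assumes that shape, only that
the extremum falls inside the response window. With the default noise
(sd 0.5 on baselines of hundreds of units) single-frame extremum picking
adds a max-of-noise bias below 1 intensity unit, so amplitudes from tens
to thousands are recovered within 3%.

# Motility: linking and the MSD decomposition

Nucleus detections are linked frame to frame greedily, shortest link
first, each detection and each open track used at most once per frame;
links longer than `max_disp_um` (per frame of elapsed gap) are forbidden,
up to `max_gap_frames` missed detections are bridged by linear
interpolation, and leftovers start new tracks. Greedy linking is
deterministic and adequate at the cell spacings this package targets
(tens of micrometres); it is *not* a globally optimal assignment, and the
configuration documents that limitation rather than hiding it.

Each track's time-averaged MSD over all ordered pairs is fitted, weighted
by pair counts, to

$$\mathrm{msd}(\tau) = 4 D \tau + (v\tau)^2,$$

the standard 2D diffusion-plus-drift decomposition consistent with
reporting a diffusivity `D` and a "directionality" speed `v`. The model is
linear in `(D, v^2)`, so the fit is a two-parameter weighted least squares
with no starting values; a negative component is clipped to zero and the
other refitted, with a flag. Only the first 25% of lags are used
(`max_lag_fraction`): long-lag time-averaged MSDs are high-variance. A
model-free `v_net` (net displacement over total time) is reported
alongside for comparison; the MSD-fit `v` is primary. Per-cell `v²`
estimates are right-skewed, so the median `v` across cells sits a few
percent below truth when diffusion dominates drift at the fitted lags —
visible in the recovery tests (medians within 15% for `D`, 20% for `v` at
`D = 0.5`, `v = 0.2`, 180 frames) and worth remembering when comparing
conditions with very different `D/v` ratios. Acquisition
length varies between protocols (tens of minutes to hours); duration is
simply a parameter here, with 180 one-minute frames as the tested default.

# Mechanics: Hertz fit and z-stack volume

Indentation force follows the spherical Hertz law
$$F(\delta) = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$
with `E` in kPa, `R` and `δ` in µm giving `F` in nN. Curves may carry
either calibrated force or cantilever deflection (`F = k d`; 0.24 N/m and
a 10-µm tip diameter are the defaults of the modelled instrument); with
deflection data the indentation is bending-corrected,
`δ = (z - z₀) - (F - F₀)/k`. `E`, the contact point `z₀` and a force
offset `F₀` are fitted jointly by Levenberg–Marquardt least squares —
joint fitting is more robust than heuristic contact detection at low
contrast, and the synthetic oracle verifies it: noise-free curves invert
to `E` within 0.1% across 0.5–5 kPa. The fit is then restricted to
`δ ≤ max_indent_um` (default 0.5 µm, 10% of the tip radius — a standard
small-strain criterion for staying in the elastic regime) and repeated. Poisson's
ratio defaults to 0.5 (incompressible cell) and is configurable; it only
rescales `E` through `1 - ν²`. Viscoelasticity, baseline tilt and
absolute comparison to reference moduli are out of scope — reference
raw curves are not available, so correctness is established on synthetic
curves only.

Cell volume is voxel counting: Otsu threshold on the range-normalized 3D
histogram, largest 6-connected 3D component retained (components below
`min_object_voxels` are debris), volume = voxel count × pixel² × z-step.
3D labelling is done slice-wise with a union-find merge because no
installed dependency labels 3D arrays. On ellipsoid phantoms the estimate
lands within 5% of `4/3 π a b c` at 0.5-µm sampling; voxelization error
is the dominant term only at coarser sampling (compare 1.0 µm vs 0.5 µm
to see the resolution trend — at 0.25 µm the residual is noise, not
discretization).

# Statistics layer

* **Fold-change enrichment**: `fold = crowded / max(control, floor)` with
  the floor defaulting to the smallest positive control abundance, so
  proteins undetected at control density get large finite fold changes
  (the regime that produces three-digit enrichment) instead of division
  by zero. Retention is strictly `> threshold` (default 5); ranking is by
  descending fold, ties broken alphabetically.
* **Diagnostic concordance**: positives are the chosen grade (default
  high-grade DCIS), negatives all lower grades; invasive-carcinoma ROIs
  are always excluded from the specificity denominator. Equivocal calls
  (rater disagreement) are excluded from numerator and denominator by
  default — the transparent choice, and it leaves a 15/20, 61/62 operating point
  intact when all non-positive calls are definite negatives — with `equivocal = "as_negative"` available. The
  95% interval is Wald, `z·sqrt(p(1-p)/n)`: at a 15/20 operating point it
  gives a half-width of 0.19, and 0.03 at 61/62 (Wilson is available
  behind a flag). Wald is anticonservative near p = 1 at
  small n; the package reports it for comparability, not because it is
  the best interval.
* **Mann–Whitney U**: `U` from rank sums with midranks; the p-value is
  exact when `n_a · n_b ≤ 400` with no ties, otherwise a tie- and
  continuity-corrected normal approximation, and the result records which
  was used. The exact path is checked against full permutation
  enumeration in the tests.
* **Scaling relations**: ordinary least squares with
  `R² = 1 - SS_res/SS_tot`, for cross-assay summary plots.
* **Dose helper**: PEG 300 percent (v/v) → osmolality, linear at
  37.2 mOsm/kg per percent (anchored at 2% = 74.4).

# The synthetic study and what passing it means

`run_study()` sweeps labelled conditions (defaults mimic a
control/inhibitor/hyperosmotic/crowded design, with plasma-membrane
fraction and motility rising while volume falls), runs every assay per
condition at desk scale (100-cell fields, 30 trajectories of 120 frames,
one z-stack and trace per condition; a five-condition study runs in a few
seconds) and fits the cross-metric scaling relations. Only *signs* and
monotone structure of those fits are asserted anywhere: the generator's
condition values are parameter choices, so any correlation strength the
sweep produces is designed rather than measured, and none is claimed as
an empirical result.

Generator noise levels are free parameters — no reference noise
statistics exist for these modalities — chosen so that recovery tolerances are meaningful
rather than trivially satisfied: gelatin noise sd 0.05 on a unit
background (5% contrast noise), line-profile noise sd 2 on peak-100
channels, calcium noise sd 0.5, force noise 0.05 nN on few-nN curves,
stack noise sd 0.05 on unit interiors. What the generators deliberately
omit: point-spread blurring in z, shot noise, uneven illumination,
overlapping nuclei, membrane ruffling, track crossings at high density,
instrument drift. Passing the synthetic suite therefore demonstrates
estimator correctness under the stated models, not robustness to every
artefact of real microscopy.

# Determinism

Every generator takes an explicit seed and draws from a child stream
keyed by the generator's name (`child_seed()`), so adding a generator
never shifts another's output; `run_study()` derives per-condition seeds
the same way and is bit-reproducible given (design, config, seed). RNG
state is restored after each call (`withr::with_seed`), so package
functions never perturb a user's session RNG.
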